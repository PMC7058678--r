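#' Ground-truth configuration for a synthetic hospital
#'
#' Defines a fully known parameterisation from which ward-stay record sets
#' and live snapshots can be generated, so that every downstream stage
#' (estimation, simulation, validation, decision support) can be tested
#' against a known truth. All distributional inputs are normalised to
#' empirical pmfs internally.
#'
#' @param wards Character vector of ward labels.
#' @param emergency_rate Poisson mean daily emergency admissions: a single
#'   number, a per-ward vector, or a ward x 7 matrix for weekday-specific
#'   rates. Ignored when `emergency_pmfs` is given.
#' @param emergency_pmfs Optional nested list `[[ward]][[weekday]]` of
#'   `empirical_pmf` daily-count distributions (empirical-table family).
#' @param wlos Ward length-of-stay specification: either
#'   `list(p =, max =)` for a truncated geometric applied everywhere, an
#'   `empirical_pmf` applied everywhere, or a nested list keyed by ward
#'   (and optionally type `"emergency"`/`"elective"`, and weekday index)
#'   of such specifications.
#' @param transitions `NULL` (every departure is a discharge), a single
#'   row-stochastic matrix over `c(wards, "discharge")` used for both
#'   admission types, or a list with one matrix per type.
#' @param elective_daily Planned elective admissions per day: `NULL`, a
#'   per-ward vector (same count every weekday), or a ward x 7 matrix.
#' @param nonattendance Elective non-attendance probability.
#' @param horizon Number of days of arrivals to generate.
#' @param start_date First day of the observation period (default
#'   2010-01-04, a Monday).
#' @return An object of class `ground_truth` holding normalised components
#'   `arrivals`, `wlos`, `transitions`, `elective_daily` plus the scalar
#'   settings.
#' @export
ground_truth_config <- function(wards, emergency_rate = 0,
                                emergency_pmfs = NULL,
                                wlos = list(p = 0.4, max = 30),
                                transitions = NULL, elective_daily = NULL,
                                nonattendance = 0, horizon = 364,
                                start_date = as.Date("2010-01-04")) {
  wards <- as.character(wards)
  W <- length(wards)
  stopifnot(W >= 1L, horizon >= 1L,
            nonattendance >= 0, nonattendance <= 1)
  types <- c("emergency", "elective")

  if (is.null(emergency_pmfs)) {
    rate <- emergency_rate
    if (is.matrix(rate)) {
      stopifnot(nrow(rate) == W, ncol(rate) == 7L)
    } else {
      rate <- matrix(rep(rate, length.out = W), nrow = W, ncol = 7L)
    }
    if (any(rate < 0)) stop("emergency_rate must be >= 0")
    arrivals <- lapply(seq_len(W), function(w)
      lapply(1:7, function(k) poisson_pmf(rate[w, k])))
  } else {
    arrivals <- lapply(wards, function(w) {
      if (length(emergency_pmfs[[w]]) != 7L)
        stop("emergency_pmfs for ward '", w, "' must have 7 weekday pmfs")
      emergency_pmfs[[w]]
    })
  }
  names(arrivals) <- wards

  as_wlos_pmf <- function(x) {
    if (inherits(x, "empirical_pmf")) return(x)
    if (is.list(x) && !is.null(x$p)) return(geometric_pmf(x$p, x$max))
    stop("wlos spec must be an empirical_pmf or list(p =, max =)")
  }
  lookup <- function(spec, w, ty, k) {
    node <- spec
    if (is.list(node) && w %in% names(node)) node <- node[[w]]
    if (is.list(node) && ty %in% names(node)) node <- node[[ty]]
    if (is.list(node) && is.null(node$p) && !inherits(node, "empirical_pmf") &&
        length(node) == 7L) node <- node[[k]]
    as_wlos_pmf(node)
  }
  wlos_n <- lapply(wards, function(w) {
    per_type <- lapply(types, function(ty)
      lapply(1:7, function(k) lookup(wlos, w, ty, k)))
    names(per_type) <- types
    per_type
  })
  names(wlos_n) <- wards
  if (any(vapply(wlos_n, function(ww) any(vapply(ww, function(tt)
    any(vapply(tt, function(p) min(p$support), 0L) < 1L), NA)), NA)))
    stop("ground-truth WLOS support must start at 1 midnight or more")

  if (is.null(transitions)) {
    m <- matrix(0, W, W + 1L, dimnames = list(wards, c(wards, "discharge")))
    m[, "discharge"] <- 1
    transitions <- list(emergency = m, elective = m)
  } else if (is.matrix(transitions)) {
    transitions <- list(emergency = transitions, elective = transitions)
  }

  if (!is.null(elective_daily)) {
    if (!is.matrix(elective_daily))
      elective_daily <- matrix(rep(elective_daily, length.out = W),
                               nrow = W, ncol = 7L)
    stopifnot(nrow(elective_daily) == W, ncol(elective_daily) == 7L,
              all(elective_daily >= 0))
    rownames(elective_daily) <- wards
  }

  cfg <- structure(list(wards = wards, arrivals = arrivals, wlos = wlos_n,
                        transitions = transitions,
                        elective_daily = elective_daily,
                        nonattendance = nonattendance,
                        horizon = as.integer(horizon),
                        start_date = as.Date(start_date)),
                   class = "ground_truth")
  truth_model(cfg)  # validates pmfs and transition rows
  cfg
}

#' Hospital model holding the exact ground-truth parameters
#'
#' @param config A `ground_truth` configuration.
#' @return A `hospital_model` whose components equal the generator's true
#'   distributions (no estimation error).
#' @export
truth_model <- function(config) {
  stopifnot(inherits(config, "ground_truth"))
  hospital_parameters(config$wards, config$arrivals, config$wlos,
                      config$transitions,
                      nonattendance = config$nonattendance)
}

# Elective schedule implied by the config's daily plan over `days`
# (0-based offsets from start_date).
config_schedule <- function(config, days) {
  if (is.null(config$elective_daily) || !length(days)) return(NULL)
  wd <- ((wday_index(config$start_date) - 1L + days) %% 7L) + 1L
  grid <- expand.grid(w = seq_along(config$wards), i = seq_along(days))
  cnt <- config$elective_daily[cbind(grid$w, wd[grid$i])]
  keep <- cnt > 0
  if (!any(keep)) return(NULL)
  elective_schedule(day = days[grid$i[keep]],
                    ward = config$wards[grid$w[keep]],
                    count = cnt[keep])
}

#' Generate ward-stay records from a known ground truth
#'
#' Draws emergency admissions per (day, ward) from the configured weekday
#' distributions and elective admissions from the daily plan (with
#' independent non-attendance thinning), then follows every patient
#' through length-of-stay and transition draws until discharge. Arrivals
#' are generated for `config$horizon` days; chains run to completion, so
#' all generated stays are closed and the stay invariants hold by
#' construction.
#'
#' @param config A `ground_truth` configuration.
#' @param seed Integer seed; identical seeds give identical record sets.
#' @return List with `stays` (a `ward_stays` data frame) and `config`.
#' @export
generate_records <- function(config, seed) {
  stopifnot(inherits(config, "ground_truth"))
  set.seed(seed)
  W <- length(config$wards)
  H <- config$horizon
  start_wd <- wday_index(config$start_date)
  wd_of <- function(t) ((start_wd - 1L + t) %% 7L) + 1L
  types <- c("emergency", "elective")
  arr <- lapply(seq_len(W * 7L), function(k)
    .compile_pmf(config$arrivals[[((k - 1L) %/% 7L) + 1L]][[((k - 1L) %% 7L) + 1L]]))
  wl <- vector("list", W * 14L)
  for (w in seq_len(W)) for (ty in 1:2) for (k in 1:7)
    wl[[(w - 1L) * 14L + (ty - 1L) * 7L + k]] <-
      .compile_pmf(config$wlos[[w]][[types[ty]]][[k]])
  trans <- lapply(types, function(ty)
    t(apply(config$transitions[[ty]], 1L, cumsum)))

  # emergency arrivals
  dv <- rep(0:(H - 1L), each = W)
  wv <- rep.int(seq_len(W), H)
  u <- stats::runif(length(dv))
  key <- (wv - 1L) * 7L + wd_of(dv)
  cnt <- integer(length(dv))
  for (k in unique(key)) {
    i <- key == k
    cnt[i] <- .samp(arr[[k]], u[i])
  }
  em_w <- rep.int(wv, cnt); em_d <- rep.int(dv, cnt)

  # elective arrivals
  sched <- config_schedule(config, 0:(H - 1L))
  el_w <- integer(0); el_d <- integer(0)
  if (!is.null(sched)) {
    keep <- if (config$nonattendance > 0)
      stats::runif(nrow(sched)) >= config$nonattendance else TRUE
    el_w <- match(sched$ward, config$wards)[keep]
    el_d <- sched$day[keep]
  }

  pw <- c(em_w, el_w)
  pt <- c(rep.int(1L, length(em_w)), rep.int(2L, length(el_w)))
  pd <- c(em_d, el_d)
  n <- length(pw)
  if (n == 0L) {
    empty <- ward_stays(data.frame(
      patient_id = character(0), ward = character(0),
      admission_type = character(0), arrival_date = as.Date(character(0)),
      departure_date = as.Date(character(0)),
      hospital_admission_date = as.Date(character(0)),
      stringsAsFactors = FALSE))
    return(list(stays = empty, config = config))
  }
  pid <- seq_len(n)
  had <- pd  # hospital admission day per patient

  sw <- list(); st <- list(); sa <- list(); sd <- list(); sp <- list()
  cw <- pw; ct <- pt; cd <- pd; cp <- pid
  round <- 0L
  while (length(cw)) {
    round <- round + 1L
    if (round > 1000L) stop("generator chain did not terminate")
    u <- stats::runif(length(cw))
    key <- (cw - 1L) * 14L + (ct - 1L) * 7L + wd_of(cd)
    los <- integer(length(cw))
    for (k in unique(key)) {
      i <- key == k
      los[i] <- .samp(wl[[k]], u[i])
    }
    dep <- cd + los
    sw[[round]] <- cw; st[[round]] <- ct; sa[[round]] <- cd
    sd[[round]] <- dep; sp[[round]] <- cp
    u <- stats::runif(length(cw))
    dest <- integer(length(cw))
    key <- (ct - 1L) * W + cw
    for (k in unique(key)) {
      i <- key == k
      ty <- ((k - 1L) %/% W) + 1L
      w <- ((k - 1L) %% W) + 1L
      dd <- findInterval(u[i], trans[[ty]][w, ]) + 1L
      dd[dd > W + 1L] <- W + 1L
      dest[i] <- dd
    }
    keep <- dest != W + 1L
    cw <- dest[keep]; ct <- ct[keep]; cd <- dep[keep]; cp <- cp[keep]
  }

  sw <- unlist(sw); st <- unlist(st); sa <- unlist(sa)
  sd <- unlist(sd); sp <- unlist(sp)
  ord <- order(sp, sa)
  stays <- ward_stays(data.frame(
    patient_id = sprintf("P%06d", sp[ord]),
    ward = config$wards[sw[ord]],
    admission_type = types[st[ord]],
    arrival_date = config$start_date + sa[ord],
    departure_date = config$start_date + sd[ord],
    hospital_admission_date = config$start_date + had[sp[ord]],
    stringsAsFactors = FALSE))
  list(stays = stays, config = config)
}

#' Generate a live bed-state snapshot with known ground truth
#'
#' Runs the generator for `warmup_days` (plus the capture day) so the ward
#' population approaches stationarity, then captures the resident
#' population at the capture midnight. Because the generator knows every
#' patient's future, the snapshot carries each resident's true remaining
#' length-of-stay in `known_remaining` - hidden from the plain simulator
#' but available as an oracle and as the d = 1 information source.
#'
#' @param config A `ground_truth` configuration.
#' @param warmup_days Days to run before capture; should be at least the
#'   maximum WLOS support so the initial transient has washed out.
#' @param seed Integer seed.
#' @return List with `snapshot` (a `system_snapshot`), `stays` (the
#'   generated records), `capture_date` and `config`.
#' @export
generate_snapshot <- function(config, warmup_days, seed) {
  stopifnot(inherits(config, "ground_truth"), warmup_days >= 0)
  max_sup <- max(unlist(lapply(config$wlos, function(ww)
    lapply(ww, function(tt) lapply(tt, function(p) max(p$support))))))
  if (warmup_days < max_sup)
    warning("warmup_days (", warmup_days,
            ") is below the maximum WLOS support (", max_sup,
            "); the captured state may not be stationary")
  cfg <- config
  cfg$horizon <- as.integer(warmup_days + 1L)
  rec <- generate_records(cfg, seed)
  capture_date <- config$start_date + warmup_days
  snap <- capture_snapshot(rec$stays, capture_date)
  list(snapshot = snap, stays = rec$stays, capture_date = capture_date,
       config = config)
}

#' Serialise and restore a ground-truth configuration
#' @param config A `ground_truth`.
#' @param path File path (JSON).
#' @return `write_ground_truth` returns `path` invisibly;
#'   `read_ground_truth` returns the `ground_truth`.
#' @export
write_ground_truth <- function(config, path) {
  stopifnot(inherits(config, "ground_truth"))
  payload <- list(
    format = "wardsim-ground-truth-1",
    wards = config$wards,
    horizon = config$horizon,
    start_date = format(config$start_date, "%Y-%m-%d"),
    nonattendance = config$nonattendance,
    arrivals = lapply(config$arrivals, function(ww) lapply(ww, pmf_to_list)),
    wlos = lapply(config$wlos, function(ww)
      lapply(ww, function(tt) lapply(tt, pmf_to_list))),
    transitions = lapply(config$transitions, function(m)
      list(rows = rownames(m), cols = colnames(m), values = as.vector(t(m)))),
    elective_daily = if (is.null(config$elective_daily)) NULL
    else as.vector(t(config$elective_daily))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (is.null(x$format) || x$format != "wardsim-ground-truth-1")
    stop("read_ground_truth: not a wardsim ground-truth file: ", path)
  wards <- unlist(x$wards)
  arrivals <- lapply(x$arrivals, function(ww) lapply(ww, pmf_from_list))
  wlos <- lapply(x$wlos, function(ww)
    lapply(ww, function(tt) lapply(tt, pmf_from_list)))
  transitions <- lapply(x$transitions, function(tm)
    matrix(unlist(tm$values), nrow = length(tm$rows), byrow = TRUE,
           dimnames = list(unlist(tm$rows), unlist(tm$cols))))
  elective_daily <- if (is.null(x$elective_daily)) NULL
  else matrix(unlist(x$elective_daily), nrow = length(wards), ncol = 7L,
              byrow = TRUE, dimnames = list(wards, NULL))
  ground_truth_config(wards, emergency_pmfs = arrivals, wlos = wlos,
                      transitions = transitions,
                      elective_daily = elective_daily,
                      nonattendance = x$nonattendance,
                      horizon = x$horizon, start_date = x$start_date)
}
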