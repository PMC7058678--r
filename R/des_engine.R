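#' Elective admission schedule
#'
#' The elective admissions are the model's decision variables: a planned
#' (day, ward) for each elective patient in the planning horizon. Days are
#' 0-based offsets from the simulation start. The schedule is stored with
#' one row per planned patient; `true_los` carries the clinician-known
#' length-of-stay when available (used by the estimated-discharge
#' information mechanism) and is `NA` otherwise.
#'
#' @param day Integer day offsets (>= 0), one per planned patient, or one
#'   per (day, ward) group when `count` is given.
#' @param ward Ward labels aligned with `day`.
#' @param count Optional planned counts per (day, ward) row; expanded to one
#'   row per patient.
#' @param true_los Optional known lengths-of-stay per patient (only valid
#'   when `count` is absent).
#' @param horizon Optional planning-horizon length recorded as an attribute.
#' @return An `elective_schedule` data frame with columns `day`, `ward`,
#'   `true_los`.
#' @export
elective_schedule <- function(day = integer(), ward = character(),
                              count = NULL, true_los = NULL,
                              horizon = NULL) {
  day <- as.integer(day)
  ward <- as.character(ward)
  if (length(ward) == 1L && length(day) > 1L)
    ward <- rep.int(ward, length(day))
  stopifnot(length(day) == length(ward), all(day >= 0L))
  if (!is.null(count)) {
    if (!is.null(true_los))
      stop("elective_schedule: give either count or true_los, not both")
    count <- as.integer(count)
    stopifnot(length(count) == length(day), all(count >= 0L))
    day <- rep.int(day, count)
    ward <- rep.int(ward, count)
  }
  out <- data.frame(day = day, ward = ward,
                    true_los = if (is.null(true_los)) NA_integer_
                    else as.integer(true_los),
                    stringsAsFactors = FALSE)
  if (any(!is.na(out$true_los) & out$true_los < 1L))
    stop("elective_schedule: true_los must be >= 1")
  attr(out, "horizon") <- horizon
  class(out) <- c("elective_schedule", "data.frame")
  out
}

#' Read and write elective schedules
#'
#' CSV with columns day, ward, count (aggregated form).
#' @param path File path.
#' @return `read_schedule` returns an `elective_schedule`;
#'   `write_schedule` returns `path` invisibly.
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  elective_schedule(df$day, df$ward, count = df$count)
}

#' @rdname read_schedule
#' @param schedule An `elective_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  agg <- stats::aggregate(list(count = rep(1L, nrow(schedule))),
                          by = list(day = schedule$day, ward = schedule$ward),
                          FUN = sum)
  agg <- agg[order(agg$day, agg$ward), , drop = FALSE]
  utils::write.csv(agg, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# fast inverse-transform sampler on a precompiled (support, cdf) pair
.samp <- function(tab, u) {
  idx <- findInterval(u, tab$cdf) + 1L
  idx[idx > length(tab$cdf)] <- length(tab$cdf)
  tab$support[idx]
}
.compile_pmf <- function(pmf) list(support = pmf$support,
                                   cdf = cumsum(pmf$prob))

# Build the per-run static tables: flat pmf lookup lists, cumulative
# transition rows, integer-coded schedule and residents.
.sim_prep <- function(model, schedule, snapshot, horizon, start, d) {
  W <- length(model$wards)
  types <- c("emergency", "elective")
  if (!is.null(snapshot) && !is.null(attr(snapshot, "capture_date"))) {
    start_date <- attr(snapshot, "capture_date")
    start_wd <- wday_index(start_date)
  } else if (inherits(start, "Date") ||
             (is.character(start) && grepl("^\\d{4}-", start))) {
    start_date <- as.Date(start)
    start_wd <- wday_index(start_date)
  } else {
    start_date <- as.Date(NA)
    start_wd <- if (is.null(start)) 1L else parse_weekday(start)
  }
  arr <- vector("list", W * 7L)
  wl <- vector("list", W * 14L)
  for (w in seq_len(W)) {
    ww <- model$wards[w]
    for (k in 1:7) {
      arr[[(w - 1L) * 7L + k]] <- .compile_pmf(model$arrivals[[ww]][[k]])
      for (ty in 1:2)
        wl[[(w - 1L) * 14L + (ty - 1L) * 7L + k]] <-
          .compile_pmf(model$wlos[[ww]][[types[ty]]][[k]])
    }
  }
  trans <- lapply(types, function(ty)
    t(apply(model$transitions[[ty]], 1L, cumsum)))
  names(trans) <- types

  map_ward <- function(x, what) {
    id <- match(x, model$wards)
    if (anyNA(id) && !is.null(model$aggregation)) {
      alt <- unname(model$aggregation[x[is.na(id)]])
      id[is.na(id)] <- match(alt, model$wards)
    }
    if (anyNA(id))
      stop(what, " references unknown ward(s): ",
           paste(unique(x[is.na(id)]), collapse = ", "))
    id
  }

  el <- NULL
  if (!is.null(schedule) && nrow(schedule)) {
    if (any(schedule$day < 0L | schedule$day >= horizon))
      stop("schedule days must lie within the horizon")
    el <- data.frame(day = schedule$day,
                     ward = map_ward(schedule$ward, "schedule"),
                     true_los = schedule$true_los)
    if (!is.null(d) && d > 0 && anyNA(el$true_los))
      stop("d > 0 but schedule rows without true_los: rows ",
           paste(utils::head(which(is.na(el$true_los)), 10L), collapse = ", "))
  }

  res <- NULL
  if (!is.null(snapshot) && nrow(snapshot)) {
    res <- data.frame(ward = map_ward(snapshot$ward, "snapshot"),
                      type = match(snapshot$admission_type, types),
                      wd = snapshot$arrival_weekday,
                      s = snapshot$elapsed,
                      known = snapshot$known_remaining)
    if (!is.null(d) && d > 0 && anyNA(res$known))
      stop("d > 0 but snapshot residents without known_remaining: ",
           paste(utils::head(snapshot$patient_id[is.na(res$known)], 10L),
                 collapse = ", "))
    # A resident counted in the midnight-t0 census has T >= s + 1, so the
    # remaining stay (including the guaranteed initiation midnight) is
    # 1 + R with R drawn conditional on elapsed time s + 1. This keeps the
    # initiation-day census equal to the loaded state and makes an s = 0
    # resident distributionally identical to a fresh admission.
    key <- paste(res$ward, res$type, res$wd, res$s)
    ukey <- unique(key)
    cond <- lapply(ukey, function(k) {
      i <- match(k, key)
      F_T <- model$wlos[[model$wards[res$ward[i]]]][[types[res$type[i]]]][[res$wd[i]]]
      .compile_pmf(conditional_cdf(F_T, res$s[i] + 1L)$pmf)
    })
    res$cond_id <- match(key, ukey)
    attr(res, "cond") <- cond
  }

  list(W = W, wards = model$wards, horizon = as.integer(horizon),
       start_wd = start_wd, start_date = start_date,
       arr = arr, wl = wl, trans = trans,
       nonatt = model$nonattendance, d = d,
       electives = el, residents = res,
       has_snapshot = !is.null(snapshot))
}

# One replication. Random-number discipline: draws are positional per
# patient, so that runs sharing a base seed are coupled patient-by-patient
# across scenario variants (common random numbers). Consumption order:
# (1) emergency arrival counts day-major/ward-minor, (2) elective
# non-attendance thinning in schedule order (only when the non-attendance
# probability is positive), (3) information Bernoullis (residents then
# electives, only when the mechanism is active), then (4) chain rounds
# over all patients in creation order (residents, emergencies, attended
# electives). Each round consumes exactly two uniforms per active patient
# - a length-of-stay slot and a destination slot - whether or not the
# patient needs them, so appending patients or presetting their
# lengths-of-stay never shifts another patient's draws.
.sim_one <- function(prep, seed) {
  set.seed(seed)
  W <- prep$W; H <- prep$horizon
  info <- !is.null(prep$d)
  wd_of <- function(t) ((prep$start_wd - 1L + t) %% 7L) + 1L

  # (1) emergency arrivals
  days <- if (prep$has_snapshot) seq_len(H - 1L) else seq_len(H) - 1L
  if (length(days)) {
    dv <- rep(days, each = W)
    wv <- rep.int(seq_len(W), length(days))
    u <- stats::runif(length(dv))
    key <- (wv - 1L) * 7L + wd_of(dv)
    cnt <- integer(length(dv))
    for (k in unique(key)) {
      i <- key == k
      cnt[i] <- .samp(prep$arr[[k]], u[i])
    }
    nz <- cnt > 0L
    em_w <- rep.int(wv[nz], cnt[nz])
    em_d <- rep.int(dv[nz], cnt[nz])
  } else {
    em_w <- integer(0); em_d <- integer(0)
  }

  # (2) elective thinning
  el <- prep$electives
  if (!is.null(el) && nrow(el) && prep$nonatt > 0) {
    u <- stats::runif(nrow(el))
    el <- el[u >= prep$nonatt, , drop = FALSE]
  }

  # (3) information Bernoullis (residents then electives)
  res <- prep$residents
  n_res <- if (is.null(res)) 0L else nrow(res)
  n_el <- if (is.null(el)) 0L else nrow(el)
  res_truth <- rep(FALSE, n_res)
  el_truth <- rep(FALSE, n_el)
  if (info) {
    if (n_res) res_truth <- stats::runif(n_res) < prep$d
    if (n_el) el_truth <- stats::runif(n_el) < prep$d
  }

  # patient assembly in canonical creation order; preset lengths-of-stay
  # are truth values under the information mechanism, NA otherwise;
  # residents carry a conditional-distribution id used in their first stay
  pw <- integer(0); pt <- integer(0); pd <- integer(0)
  pl <- integer(0); pc <- integer(0)
  if (n_res) {
    pw <- c(pw, res$ward); pt <- c(pt, res$type)
    pd <- c(pd, rep.int(0L, n_res))
    pl <- c(pl, ifelse(res_truth, res$known, NA_integer_))
    pc <- c(pc, res$cond_id)
  }
  if (length(em_w)) {
    pw <- c(pw, em_w); pt <- c(pt, rep.int(1L, length(em_w)))
    pd <- c(pd, em_d); pl <- c(pl, rep.int(NA_integer_, length(em_w)))
    pc <- c(pc, rep.int(NA_integer_, length(em_w)))
  }
  if (n_el) {
    pw <- c(pw, el$ward); pt <- c(pt, rep.int(2L, n_el))
    pd <- c(pd, el$day)
    pl <- c(pl, as.integer(ifelse(el_truth, el$true_los, NA_integer_)))
    pc <- c(pc, rep.int(NA_integer_, n_el))
  }
  n_adm <- length(pw)
  n_dis <- 0L
  cond <- if (n_res) attr(prep$residents, "cond") else NULL

  # (4) chain rounds, two positional uniforms per active patient
  sw <- list(); st <- list(); sa <- list(); sd <- list()
  cw <- pw; ct <- pt; cd <- pd; cl <- pl; cc <- pc
  round <- 0L
  while (length(cw)) {
    round <- round + 1L
    if (round > 400L) stop("simulation chain did not terminate")
    n <- length(cw)
    u <- stats::runif(2L * n)
    u_los <- u[seq.int(1L, by = 2L, length.out = n)]
    u_dest <- u[seq.int(2L, by = 2L, length.out = n)]
    need <- is.na(cl)
    res_i <- need & !is.na(cc)
    if (any(res_i)) {
      # resident first stay: guaranteed initiation midnight plus a draw
      # from the conditional remaining-LOS distribution
      for (k in unique(cc[res_i])) {
        i <- res_i & cc == k
        cl[i] <- .samp(cond[[k]], u_los[i]) + 1L
      }
    }
    fresh <- need & is.na(cc)
    if (any(fresh)) {
      key <- integer(n)
      key[fresh] <- (cw[fresh] - 1L) * 14L + (ct[fresh] - 1L) * 7L +
        wd_of(cd[fresh])
      for (k in unique(key[fresh])) {
        i <- fresh & key == k
        cl[i] <- .samp(prep$wl[[k]], u_los[i])
      }
    }
    dep <- cd + cl
    sw[[round]] <- cw; st[[round]] <- ct; sa[[round]] <- cd
    sd[[round]] <- dep
    cont <- dep <= H - 1L
    if (!any(cont)) break
    dw <- cw[cont]; dt <- ct[cont]; dday <- dep[cont]
    du <- u_dest[cont]
    dest <- integer(sum(cont))
    key <- (dt - 1L) * W + dw
    for (k in unique(key)) {
      i <- key == k
      ty <- ((k - 1L) %/% W) + 1L
      w <- ((k - 1L) %% W) + 1L
      row <- prep$trans[[ty]][w, ]
      dd <- findInterval(du[i], row) + 1L
      dd[dd > W + 1L] <- W + 1L
      dest[i] <- dd
    }
    disch <- dest == W + 1L
    n_dis <- n_dis + sum(disch)
    keep <- !disch
    cw <- dest[keep]; ct <- dt[keep]; cd <- dday[keep]
    cl <- rep.int(NA_integer_, sum(keep))
    cc <- rep.int(NA_integer_, sum(keep))
  }

  sw <- unlist(sw); st <- unlist(st)
  sa <- unlist(sa); sd <- unlist(sd)
  census <- array(0L, dim = c(W, H, 2L))
  lo <- pmax(sa, 0L)
  hi <- pmin(sd - 1L, H - 1L)
  len <- pmax(hi - lo + 1L, 0L)
  if (any(len > 0L)) {
    i <- rep.int(seq_along(len), len)
    day <- sequence(len) - 1L + lo[i]
    lin <- sw[i] + day * W + (st[i] - 1L) * W * H
    census <- census + array(tabulate(lin, nbins = W * H * 2L),
                             dim = c(W, H, 2L))
  }
  list(census = census, admissions = n_adm, discharges = n_dis)
}

#' Simulate replicated midnight-census trajectories
#'
#' Runs the discrete-time, infinite-server ward-network simulation: each
#' day, emergency arrivals per ward are drawn from the fitted
#' (ward, weekday) daily-count distribution; elective arrivals follow the
#' schedule (with independent non-attendance thinning); each arriving
#' patient draws a ward length-of-stay from the (ward, type,
#' arrival-weekday) distribution; when a stay ends a destination is drawn
#' from the transition matrix - discharge removes the patient, a ward
#' destination starts a new stay with a fresh conditional draw. Occupancy
#' is never capped (capacities are reporting-only). When a
#' `system_snapshot` is supplied the simulation is re-initialised from it:
#' residents enter with remaining length-of-stay drawn from their
#' conditional distribution (or their known value under the
#' information mechanism), and fresh arrivals are generated from day 1.
#'
#' @param object A fitted `hospital_model`.
#' @param nsim Number of replications (100 is the package's validation
#'   default; decision-support summaries conventionally use 400).
#' @param seed Base seed; replication streams are derived from it, so two
#'   calls sharing a base seed are coupled by common random numbers.
#' @param horizon Number of simulated days.
#' @param schedule An `elective_schedule`, or `NULL`.
#' @param snapshot A `system_snapshot`, or `NULL` to start empty.
#' @param start Start date (`Date` / "YYYY-MM-DD") or weekday ("MON"..),
#'   used to align weekday-specific distributions; ignored when the
#'   snapshot carries a capture date.
#' @param d Probability that a patient's known length-of-stay is used
#'   instead of a sampled one (estimated-discharge-information mechanism).
#'   `NULL` (the default) disables the mechanism entirely; a numeric value
#'   (including 0) activates it, requiring truth values when `d > 0` and
#'   keeping random draws aligned across a grid of d values that share a
#'   base seed.
#' @param ... Unused.
#' @return An object of class `hospital_sim`: list with `census` (integer
#'   array ward x day x type x replication), `wards`, `horizon`, `nsim`,
#'   `seed`, `start_date`, `start_wd`, `initialized`, and `ledger` (per
#'   replication: admissions, discharges, final census).
#' @export
simulate.hospital_model <- function(object, nsim = 100, seed = NULL,
                                    horizon = NULL, schedule = NULL,
                                    snapshot = NULL, start = NULL, d = NULL,
                                    ...) {
  if (is.null(horizon) || horizon < 1L) stop("simulate: horizon >= 1 required")
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  prep <- .sim_prep(object, schedule, snapshot, horizon, start, d)
  set.seed(seed)
  rep_seeds <- sample.int(2147483646L, nsim)
  W <- prep$W; H <- prep$horizon
  census <- array(0L, dim = c(W, H, 2L, nsim),
                  dimnames = list(object$wards, NULL,
                                  c("emergency", "elective"), NULL))
  adm <- integer(nsim); dis <- integer(nsim)
  for (r in seq_len(nsim)) {
    one <- .sim_one(prep, rep_seeds[r])
    census[, , , r] <- one$census
    adm[r] <- one$admissions
    dis[r] <- one$discharges
  }
  fin <- apply(census[, H, , , drop = FALSE], 4L, sum)
  structure(list(census = census, wards = object$wards, horizon = H,
                 nsim = nsim, seed = seed, start_date = prep$start_date,
                 start_wd = prep$start_wd,
                 initialized = prep$has_snapshot, d = d,
                 ledger = data.frame(rep = seq_len(nsim), admissions = adm,
                                     discharges = dis, final_census = fin)),
            class = "hospital_sim")
}

#' Construct a simulation-result object from a census array
#'
#' Mainly for composing results by hand (e.g. worked examples and tests of
#' the reporting layer).
#'
#' @param census Integer array ward x day x type x replication, with ward
#'   dimnames; a ward x day matrix or ward x day x type array is promoted.
#' @param start Start weekday or date.
#' @param initialized Whether day 1 is a re-initialisation day.
#' @return A `hospital_sim` object.
#' @export
hospital_sim <- function(census, start = "MON", initialized = FALSE) {
  if (is.matrix(census)) {
    a <- array(0L, dim = c(dim(census), 2L, 1L))
    a[, , 1L, 1L] <- census
    dimnames(a) <- list(rownames(census), NULL,
                        c("emergency", "elective"), NULL)
    census <- a
  } else if (length(dim(census)) == 3L) {
    a <- array(census, dim = c(dim(census), 1L))
    dimnames(a) <- c(dimnames(census)[1:3], list(NULL))
    census <- a
  }
  stopifnot(length(dim(census)) == 4L, !is.null(dimnames(census)[[1L]]))
  start_date <- if (inherits(start, "Date") ||
                    (is.character(start) && grepl("^\\d{4}-", start)))
    as.Date(start) else as.Date(NA)
  start_wd <- if (!is.na(start_date)) wday_index(start_date)
  else parse_weekday(start)
  structure(list(census = census, wards = dimnames(census)[[1L]],
                 horizon = dim(census)[2L], nsim = dim(census)[4L],
                 seed = NA_integer_, start_date = start_date,
                 start_wd = start_wd, initialized = initialized, d = NULL,
                 ledger = NULL),
            class = "hospital_sim")
}

# ward x day x rep totals (types summed)
sim_totals <- function(sim) {
  out <- sim$census[, , 1L, , drop = FALSE] +
    sim$census[, , 2L, , drop = FALSE]
  array(out, dim = dim(sim$census)[c(1L, 2L, 4L)],
        dimnames = list(sim$wards, NULL, NULL))
}

#' @export
print.hospital_sim <- function(x, ...) {
  cat(sprintf(
    "hospital simulation: %d ward(s), %d day(s), %d replication(s)%s\n",
    length(x$wards), x$horizon, x$nsim,
    if (x$initialized) ", snapshot-initialised" else ""))
  tot <- sim_totals(x)
  cat("mean midnight occupancy by ward:\n")
  print(round(apply(tot, 1L, mean), 2))
  invisible(x)
}

#' Summarise a simulation as per-ward-day occupancy quantiles
#'
#' @param object A `hospital_sim`.
#' @param probs Quantile levels for the prediction band (default 5th and
#'   95th percentiles, the 90% band).
#' @param ... Unused.
#' @return Data frame: ward, day, mean, and one column per quantile.
#' @export
summary.hospital_sim <- function(object, probs = c(0.05, 0.95), ...) {
  tot <- sim_totals(object)
  out <- expand.grid(ward = object$wards,
                     day = seq_len(object$horizon) - 1L,
                     stringsAsFactors = FALSE)
  out$mean <- as.vector(apply(tot, c(1L, 2L), mean))
  qs <- apply(tot, c(1L, 2L), stats::quantile, probs = probs, type = 7)
  for (i in seq_along(probs))
    out[[sprintf("q%02d", round(100 * probs[i]))]] <-
      as.vector(qs[i, , ])
  class(out) <- c("summary.hospital_sim", "data.frame")
  out
}

#' Write per-replication census and a summary file
#' @param sim A `hospital_sim`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  grid <- expand.grid(ward = sim$wards, day = seq_len(sim$horizon) - 1L,
                      admission_type = c("emergency", "elective"),
                      rep = seq_len(sim$nsim), stringsAsFactors = FALSE)
  grid$count <- as.integer(sim$census)
  utils::write.csv(grid, file.path(dir, "census_long.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(summary(sim), file.path(dir, "census_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
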