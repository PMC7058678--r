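#' Select individually modelled wards by occupancy coverage
#'
#' Wards are ranked by mean midnight occupancy (descending, ties broken by
#' ward label); the smallest prefix whose cumulative share of total mean
#' occupancy reaches `coverage` is modelled individually and every other
#' ward is aggregated into the pseudo-ward `"Other"`.
#'
#' @param census A `census_trajectory`.
#' @param coverage Fraction of average occupancy to capture individually
#'   (default 0.9).
#' @return List with `modelled` (ward labels, in rank order, including
#'   `"Other"` when non-empty) and `map` (named character vector from every
#'   census ward to its modelled label).
#' @export
select_wards <- function(census, coverage = 0.9) {
  stopifnot(inherits(census, "census_trajectory"))
  if (length(census$dates) == 0L) stop("select_wards: empty census")
  stopifnot(coverage > 0, coverage <= 1)
  means <- rowMeans(census_totals(census))
  if (sum(means) <= 0) stop("select_wards: census has zero total occupancy")
  ord <- order(-means, names(means))
  share <- cumsum(means[ord]) / sum(means)
  k <- which(share >= coverage - 1e-12)[1L]
  modelled <- names(means)[ord][seq_len(k)]
  map <- stats::setNames(
    ifelse(names(means) %in% modelled, names(means), "Other"),
    names(means))
  list(modelled = if (k < length(means)) c(modelled, "Other") else modelled,
       map = map)
}

apply_aggregation <- function(stays, map) {
  unknown <- setdiff(unique(stays$ward), names(map))
  if (length(unknown))
    stop("aggregation map does not cover ward(s): ",
         paste(unknown, collapse = ", "))
  stays$ward <- unname(map[stays$ward])
  stays
}

#' Estimate weekday-specific emergency arrival distributions
#'
#' For each (modelled ward, weekday), the empirical pmf of the daily count
#' of emergency hospital admissions arriving at that ward on days of that
#' weekday, with zero-arrival days included. A hospital admission is a stay
#' whose arrival date equals the spell's hospital admission date; transfers
#' into a ward are generated by the transition model, not the arrival model.
#'
#' @param stays A `ward_stays` data frame.
#' @param map Aggregation map from [select_wards()].
#' @return Nested list `arrivals[[ward]][[weekday 1..7]]` of
#'   `empirical_pmf` objects over daily counts.
#' @export
estimate_arrivals <- function(stays, map) {
  s <- apply_aggregation(stays, map)
  wards <- unique(unname(map))
  # observation window: the span of hospital-admission days (trailing
  # transfer-only days carry no arrival information)
  is_adm <- s$arrival_date == s$hospital_admission_date
  days <- seq(min(s$arrival_date[is_adm]), max(s$arrival_date[is_adm]),
              by = "day")
  wd <- wday_index(days)
  adm <- s[s$admission_type == "emergency" & is_adm, , drop = FALSE]
  out <- list()
  for (w in wards) {
    aw <- adm[adm$ward == w, , drop = FALSE]
    daily <- tabulate(match(aw$arrival_date, days), nbins = length(days))
    out[[w]] <- lapply(1:7, function(k) pmf_from_samples(daily[wd == k]))
  }
  out
}

#' Estimate ward length-of-stay distributions
#'
#' Empirical pmfs of ward length-of-stay (midnights), stratified by
#' (ward, admission type, weekday of arrival at that ward). Strata with no
#' closed stays fall back along the pooling ladder
#' (ward, type, weekday) -> (ward, type) -> (ward) -> global; the first
#' non-empty level supplies the pmf.
#'
#' @inheritParams estimate_arrivals
#' @return Nested list `wlos[[ward]][[type]][[weekday]]` of `empirical_pmf`
#'   objects, with a `"pooling"` attribute (data frame of the level used
#'   per stratum) on the outer list.
#' @export
estimate_wlos <- function(stays, map) {
  s <- apply_aggregation(stays, map)
  s <- s[!is.na(s$departure_date), , drop = FALSE]
  wards <- unique(unname(map))
  types <- c("emergency", "elective")
  los <- wlos_midnights(s)
  wd <- wday_index(s$arrival_date)
  global <- if (nrow(s)) pmf_from_samples(los) else NULL
  out <- list()
  pool <- list()
  for (w in wards) {
    in_w <- s$ward == w
    if (!any(in_w))
      stop("estimate_wlos: ward '", w, "' has no closed stays in any stratum")
    ward_pmf <- pmf_from_samples(los[in_w])
    out[[w]] <- list()
    for (ty in types) {
      in_wt <- in_w & s$admission_type == ty
      wt_pmf <- if (any(in_wt)) pmf_from_samples(los[in_wt]) else NULL
      out[[w]][[ty]] <- vector("list", 7L)
      for (k in 1:7) {
        in_wtk <- in_wt & wd == k
        if (any(in_wtk)) {
          out[[w]][[ty]][[k]] <- pmf_from_samples(los[in_wtk])
          lev <- "ward_type_weekday"
        } else if (!is.null(wt_pmf)) {
          out[[w]][[ty]][[k]] <- wt_pmf
          lev <- "ward_type"
        } else {
          out[[w]][[ty]][[k]] <- ward_pmf
          lev <- "ward"
        }
        pool[[length(pool) + 1L]] <- data.frame(
          ward = w, type = ty, weekday = WDAY_NAMES[k], level = lev,
          stringsAsFactors = FALSE)
      }
    }
  }
  attr(out, "pooling") <- do.call(rbind, pool)
  out
}

#' Estimate ward transition probabilities
#'
#' For each admission type, the row-stochastic matrix of transition
#' probabilities from each ward to every other ward or to discharge:
#' the proportion of departures from ward i whose next ward stay starts at
#' ward j on the departure day (a contiguous transfer), with all other
#' departures counted as discharge. Wards with no observed departures
#' default to a point mass on discharge.
#'
#' @inheritParams estimate_arrivals
#' @return List with one matrix per admission type; rows are modelled
#'   wards, columns are modelled wards plus `"discharge"`.
#' @export
estimate_transitions <- function(stays, map) {
  s <- apply_aggregation(stays, map)
  s <- s[!is.na(s$departure_date), , drop = FALSE]
  wards <- unique(unname(map))
  types <- c("emergency", "elective")
  ord <- order(s$patient_id, as.integer(s$arrival_date),
               as.integer(s$departure_date))
  s <- s[ord, , drop = FALSE]
  n <- nrow(s)
  dest <- rep("discharge", n)
  if (n > 1L) {
    nxt_same <- s$patient_id[-1L] == s$patient_id[-n]
    contiguous <- nxt_same &
      as.integer(s$arrival_date[-1L]) == as.integer(s$departure_date[-n])
    dest[-n][contiguous] <- s$ward[-1L][contiguous]
  }
  out <- list()
  for (ty in types) {
    m <- matrix(0, nrow = length(wards), ncol = length(wards) + 1L,
                dimnames = list(wards, c(wards, "discharge")))
    sel <- s$admission_type == ty
    tab <- table(factor(s$ward[sel], levels = wards),
                 factor(dest[sel], levels = c(wards, "discharge")))
    m[] <- as.numeric(tab)
    tot <- rowSums(m)
    for (i in seq_along(wards)) {
      if (tot[i] > 0) m[i, ] <- m[i, ] / tot[i]
      else m[i, "discharge"] <- 1
    }
    out[[ty]] <- m
  }
  out
}

#' Assemble a hospital occupancy model from components
#'
#' Low-level constructor used by [hospital_model()] and by the synthetic
#' ground truth; validates the component invariants.
#'
#' @param wards Character vector of modelled wards.
#' @param arrivals Nested list `[[ward]][[weekday]]` of `empirical_pmf`
#'   daily emergency admission counts.
#' @param wlos Nested list `[[ward]][[type]][[weekday]]` of `empirical_pmf`
#'   ward length-of-stay distributions.
#' @param transitions List per admission type of row-stochastic matrices
#'   over `c(wards, "discharge")`.
#' @param nonattendance Probability that a scheduled elective patient does
#'   not attend (default 0).
#' @param aggregation Optional named map raw ward -> modelled ward.
#' @return An object of class `hospital_model`.
#' @export
hospital_parameters <- function(wards, arrivals, wlos, transitions,
                                nonattendance = 0, aggregation = NULL) {
  stopifnot(length(wards) >= 1L, !anyDuplicated(wards))
  stopifnot(nonattendance >= 0, nonattendance <= 1)
  types <- c("emergency", "elective")
  for (w in wards) {
    if (is.null(arrivals[[w]]) || length(arrivals[[w]]) != 7L)
      stop("arrivals for ward '", w, "' must have 7 weekday pmfs")
    for (ty in types)
      if (is.null(wlos[[w]][[ty]]) || length(wlos[[w]][[ty]]) != 7L)
        stop("wlos for ward '", w, "', type '", ty,
             "' must have 7 weekday pmfs")
  }
  for (ty in types) {
    m <- transitions[[ty]]
    if (!is.matrix(m) || !identical(rownames(m), wards) ||
        !identical(colnames(m), c(wards, "discharge")))
      stop("transition matrix for '", ty,
           "' must have rows = wards, cols = wards + discharge")
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9))
      stop("transition rows for '", ty, "' must be non-negative and sum to 1")
  }
  structure(list(wards = wards, arrivals = arrivals[wards],
                 wlos = wlos[wards], transitions = transitions[types],
                 nonattendance = nonattendance,
                 aggregation = aggregation, call = NULL,
                 nobs = NA_integer_),
            class = "hospital_model")
}

#' Fit the ward-network occupancy model to ward-stay records
#'
#' The package's central fitting function. From ward-stay records it
#' derives the midnight census, selects the wards that make up `coverage`
#' of average occupancy (aggregating the rest into `"Other"`), and
#' estimates all simulator inputs: weekday-specific empirical daily
#' emergency-admission distributions, empirical ward length-of-stay (WLOS)
#' distributions per (ward, admission type, weekday of ward arrival), and
#' per-type ward transition matrices. The fitted object is the input of
#' [simulate.hospital_model()] and of the validation and decision-support
#' layers.
#'
#' @param stays A `ward_stays` data frame (see [read_ward_stays()]).
#' @param coverage Occupancy share modelled individually (default 0.9).
#' @param nonattendance Elective non-attendance probability (default 0; the
#'   records do not identify non-attenders, so this is supplied, not
#'   estimated).
#' @return An object of class `hospital_model`.
#' @examples
#' cfg <- ground_truth_config(wards = "A", emergency_rate = 2,
#'                            wlos = list(p = 0.5, max = 20), horizon = 120)
#' rec <- generate_records(cfg, seed = 1)
#' fit <- hospital_model(rec$stays, coverage = 1)
#' fit
#' @export
hospital_model <- function(stays, coverage = 0.9, nonattendance = 0) {
  stopifnot(inherits(stays, "ward_stays") || is.data.frame(stays))
  stays <- ward_stays(stays)
  census <- derive_census(stays)
  sel <- select_wards(census, coverage)
  arrivals <- estimate_arrivals(stays, sel$map)
  wlos <- estimate_wlos(stays, sel$map)
  transitions <- estimate_transitions(stays, sel$map)
  # estimators index wards in map order; align with the rank order of
  # sel$modelled expected by the constructor
  transitions <- lapply(transitions, function(m)
    m[sel$modelled, c(sel$modelled, "discharge"), drop = FALSE])
  obj <- hospital_parameters(sel$modelled, arrivals, wlos, transitions,
                             nonattendance = nonattendance,
                             aggregation = sel$map)
  obj$call <- match.call()
  obj$nobs <- nrow(stays)
  obj$pooling <- attr(wlos, "pooling")
  obj
}

#' @export
print.hospital_model <- function(x, ...) {
  cat("Hospital ward-network occupancy model\n")
  if (!is.null(x$call)) cat("  call:", deparse(x$call), "\n")
  cat(sprintf("  %d modelled ward(s): %s\n", length(x$wards),
              paste(x$wards, collapse = ", ")))
  if (!is.na(x$nobs)) cat(sprintf("  fitted to %d ward stays\n", x$nobs))
  lam <- vapply(x$wards, function(w)
    mean(vapply(x$arrivals[[w]], pmf_mean, 0)), 0)
  cat("  mean daily emergency admissions by ward:\n")
  print(round(lam, 2))
  cat(sprintf("  elective non-attendance probability: %.3f\n",
              x$nonattendance))
  invisible(x)
}

#' @export
summary.hospital_model <- function(object, ...) {
  lam <- t(vapply(object$wards, function(w)
    vapply(object$arrivals[[w]], pmf_mean, 0), numeric(7)))
  colnames(lam) <- WDAY_NAMES
  los <- t(vapply(object$wards, function(w) {
    m <- vapply(c("emergency", "elective"), function(ty)
      mean(vapply(object$wlos[[w]][[ty]], pmf_mean, 0)), 0)
    m
  }, numeric(2)))
  out <- list(wards = object$wards, arrival_means = lam, wlos_means = los,
              transitions = object$transitions,
              nonattendance = object$nonattendance,
              pooling = object$pooling)
  class(out) <- "summary.hospital_model"
  out
}

#' @export
print.summary.hospital_model <- function(x, ...) {
  cat("Mean daily emergency admissions (ward x weekday):\n")
  print(round(x$arrival_means, 2))
  cat("\nMean ward length-of-stay in midnights (ward x type):\n")
  print(round(x$wlos_means, 2))
  cat("\nTransition matrices:\n")
  for (ty in names(x$transitions)) {
    cat(" ", ty, "\n")
    print(round(x$transitions[[ty]], 3))
  }
  if (!is.null(x$pooling)) {
    n_pool <- sum(x$pooling$level != "ward_type_weekday")
    cat(sprintf("\n%d of %d WLOS strata used a pooled fallback level\n",
                n_pool, nrow(x$pooling)))
  }
  invisible(x)
}

#' @export
coef.hospital_model <- function(object, ...) object$transitions

pmf_to_list <- function(pmf)
  list(support = pmf$support, prob = pmf$prob, n = pmf$n)
pmf_from_list <- function(x)
  empirical_pmf(x$support, x$prob, if (is.null(x$n)) NA_integer_ else x$n)

#' Serialise and restore a fitted hospital model
#'
#' The model is written as a single structured JSON parameter file with
#' embedded pmf tables, at full floating-point precision so the round trip
#' is exact.
#'
#' @param model A `hospital_model`.
#' @param path File path.
#' @return `write_parameters` returns `path` invisibly; `read_parameters`
#'   returns the `hospital_model`.
#' @export
write_parameters <- function(model, path) {
  stopifnot(inherits(model, "hospital_model"))
  types <- c("emergency", "elective")
  payload <- list(
    format = "wardsim-parameters-1",
    wards = model$wards,
    nonattendance = model$nonattendance,
    aggregation = as.list(model$aggregation),
    arrivals = lapply(model$arrivals, function(ww)
      lapply(ww, pmf_to_list)),
    wlos = lapply(model$wlos, function(ww)
      lapply(ww, function(tt) lapply(tt, pmf_to_list))),
    transitions = lapply(model$transitions, function(m)
      list(rows = rownames(m), cols = colnames(m),
           values = as.vector(t(m))))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  if (is.null(x$format) || x$format != "wardsim-parameters-1")
    stop("read_parameters: not a wardsim parameter file: ", path)
  wards <- unlist(x$wards)
  arrivals <- lapply(x$arrivals, function(ww) lapply(ww, pmf_from_list))
  wlos <- lapply(x$wlos, function(ww)
    lapply(ww, function(tt) lapply(tt, pmf_from_list)))
  transitions <- lapply(x$transitions, function(tm) {
    m <- matrix(unlist(tm$values), nrow = length(tm$rows), byrow = TRUE,
                dimnames = list(unlist(tm$rows), unlist(tm$cols)))
    m
  })
  agg <- if (length(x$aggregation))
    stats::setNames(unlist(x$aggregation), names(x$aggregation)) else NULL
  hospital_parameters(wards, arrivals, wlos, transitions,
                      nonattendance = x$nonattendance, aggregation = agg)
}
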