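#' Ward capacity configuration
#'
#' Bed capacities are reporting-only: the infinite-server dynamics never
#' cap occupancy, and capacities exist solely to express exceedance risk
#' and bed-midnights over capacity.
#'
#' @param beds Named integer vector of maximum beds per ward, or a data
#'   frame with columns `ward` and `beds`.
#' @param warning_fraction Occupancy fraction defining the early-warning
#'   threshold (default 0.9).
#' @return An object of class `capacity_config`.
#' @export
capacity_config <- function(beds, warning_fraction = 0.9) {
  if (is.data.frame(beds))
    beds <- stats::setNames(as.integer(beds$beds), beds$ward)
  stopifnot(length(beds) >= 1L, !is.null(names(beds)),
            all(beds >= 1L), warning_fraction > 0, warning_fraction <= 1)
  structure(list(beds = beds, warning_fraction = warning_fraction),
            class = "capacity_config")
}

#' Capacity early-warning report
#'
#' Per (ward, day): the probability (replication fraction) that midnight
#' occupancy exceeds the warning threshold (`warning_fraction` x capacity,
#' strict comparison) and the probability that it exceeds the ward's
#' maximum capacity. Bed-midnights over capacity (BMOC) is, per
#' replication, the total number of beds in excess of each ward's
#' capacity summed over wards and the midnights of the planning horizon;
#' the reported BMOC is its mean over replications. When the simulation
#' was initialised from a snapshot the initiation day is excluded (its
#' occupancy is the loaded state, not a prediction).
#'
#' @param result A `hospital_sim`.
#' @param caps A `capacity_config` covering every simulated ward.
#' @return An object of class `warning_report`: `table` (ward, day,
#'   p_threshold, p_capacity), `bmoc` (mean over replications),
#'   `bmoc_reps`, `nsim`, `days_used`.
#' @export
warning_report <- function(result, caps) {
  stopifnot(inherits(result, "hospital_sim"),
            inherits(caps, "capacity_config"))
  miss <- setdiff(result$wards, names(caps$beds))
  if (length(miss))
    stop("no capacity configured for ward(s): ",
         paste(miss, collapse = ", "))
  tot <- sim_totals(result)                     # ward x day x rep
  days <- seq_len(result$horizon)
  if (result$initialized && result$horizon > 1L) days <- days[-1L]
  cap <- caps$beds[result$wards]
  warn <- caps$warning_fraction * cap
  rows <- list()
  for (w in seq_along(result$wards)) {
    occ <- tot[w, days, , drop = FALSE]
    p_thr <- apply(occ > warn[w], 2L, mean)
    p_cap <- apply(occ > cap[w], 2L, mean)
    rows[[w]] <- data.frame(ward = result$wards[w], day = days - 1L,
                            p_threshold = as.vector(p_thr),
                            p_capacity = as.vector(p_cap),
                            stringsAsFactors = FALSE)
  }
  over <- pmax(sweep(tot[, days, , drop = FALSE], 1L, cap, "-"), 0)
  bmoc_reps <- apply(over, 3L, sum)
  structure(list(table = do.call(rbind, rows), bmoc = mean(bmoc_reps),
                 bmoc_reps = bmoc_reps, nsim = result$nsim,
                 days_used = days - 1L),
            class = "warning_report")
}

#' @export
print.warning_report <- function(x, ...) {
  cat(sprintf("capacity early-warning report (%d replications)\n", x$nsim))
  cat(sprintf("bed-midnights over capacity (BMOC): %.2f\n", x$bmoc))
  worst <- x$table[order(-x$table$p_capacity), ]
  cat("highest exceedance probabilities:\n")
  print(utils::head(worst, 5L), row.names = FALSE)
  invisible(x)
}

#' Compare elective schedules under common random numbers
#'
#' Simulates every candidate schedule from the same snapshot with the same
#' base seed, so the replication streams are identical across schedules
#' and differences in the reports are attributable to the schedules alone.
#' The first schedule is the reference.
#'
#' @param model A fitted `hospital_model`.
#' @param snapshot A `system_snapshot` (the initiation state).
#' @param schedules Named list of `elective_schedule` objects sharing the
#'   planning horizon.
#' @param caps A `capacity_config`.
#' @param horizon Planning-horizon length in days.
#' @param n_reps Replications (default 400).
#' @param seed Base seed shared by all schedules.
#' @return List with `reports` (one `warning_report` per schedule) and
#'   `comparison` (data frame of BMOC, mean capacity-exceedance
#'   probability, and deltas versus the reference).
#' @export
compare_schedules <- function(model, snapshot, schedules, caps, horizon,
                              n_reps = 400L, seed = 1L) {
  stopifnot(is.list(schedules), length(schedules) >= 1L,
            !is.null(names(schedules)))
  hors <- unique(unlist(lapply(schedules, function(s) {
    h <- attr(s, "horizon")
    if (is.null(h)) NA_integer_ else h
  })))
  hors <- hors[!is.na(hors)]
  if (length(hors) > 1L)
    stop("schedules declare inconsistent horizons: ",
         paste(hors, collapse = ", "))
  reports <- lapply(schedules, function(s)
    warning_report(simulate(model, nsim = n_reps, seed = seed,
                            horizon = horizon, schedule = s,
                            snapshot = snapshot), caps))
  bmoc <- vapply(reports, function(r) r$bmoc, 0)
  p_cap <- vapply(reports, function(r) mean(r$table$p_capacity), 0)
  comparison <- data.frame(schedule = names(schedules), bmoc = bmoc,
                           mean_p_capacity = p_cap,
                           bmoc_delta = bmoc - bmoc[1L],
                           p_capacity_delta = p_cap - p_cap[1L],
                           stringsAsFactors = FALSE)
  rownames(comparison) <- NULL
  list(reports = reports, comparison = comparison)
}

#' Value of estimated discharge-date information
#'
#' Quantifies how knowing patients' lengths-of-stay sharpens short-term
#' occupancy forecasts. The parameter d is the probability that a
#' clinician's length-of-stay estimate is correct: per patient and
#' replication an independent Bernoulli(d) decides whether the patient's
#' true (remaining) length-of-stay is used or a fresh draw from the
#' applicable conditional empirical distribution is taken. Truth must be
#' available for every snapshot resident (`known_remaining`) and every
#' scheduled elective (`true_los`); emergency patients arriving during the
#' horizon never have truth and are always sampled. For each d the
#' standard deviation of midnight occupancy across replications is
#' computed per (ward, day) and averaged by weekday.
#'
#' @param model A fitted `hospital_model`.
#' @param snapshot A `system_snapshot` whose residents carry
#'   `known_remaining`.
#' @param schedule An `elective_schedule` with `true_los` per patient (or
#'   `NULL` for no electives).
#' @param d_grid Values of d to evaluate (default 0, 0.25, 0.5, 0.75, 1).
#' @param horizon Planning-horizon length in days.
#' @param n_reps Replications per d (default 400).
#' @param seed Base seed, shared across the d grid (matched streams).
#' @return Data frame with columns d, ward, weekday, sd (the standard
#'   deviation of midnight occupancy averaged over days of that weekday).
#' @export
edd_experiment <- function(model, snapshot, schedule = NULL,
                           d_grid = c(0, 0.25, 0.5, 0.75, 1),
                           horizon = 7L, n_reps = 400L, seed = 1L) {
  stopifnot(all(d_grid >= 0), all(d_grid <= 1))
  rows <- list()
  for (d in d_grid) {
    sim <- simulate(model, nsim = n_reps, seed = seed, horizon = horizon,
                    schedule = schedule, snapshot = snapshot, d = d)
    tot <- sim_totals(sim)
    sds <- apply(tot, c(1L, 2L), stats::sd)     # ward x day
    wd <- ((sim$start_wd - 1L + seq_len(horizon) - 1L) %% 7L) + 1L
    for (w in seq_along(sim$wards)) {
      by_wd <- tapply(sds[w, ], wd, mean)
      rows[[length(rows) + 1L]] <- data.frame(
        d = d, ward = sim$wards[w],
        weekday = WDAY_NAMES[as.integer(names(by_wd))],
        sd = as.vector(by_wd), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
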