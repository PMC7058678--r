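#' Observed h-step occupancy-change samples
#'
#' The validation statistic is the h-step change in midnight occupancy,
#' Delta_(t,h) = M_t - M_(t+h); for an N-day series there are N - h such
#' values at each horizon offset h. Comparing the full empirical
#' distributions of these changes between observed data and re-initialised
#' simulation output accounts for the time-from-initialisation dependence
#' that makes a re-initialised stochastic simulation non-stationary.
#'
#' @param census A `census_trajectory`.
#' @param ward A ward label, or `"total"` for the all-ward series.
#' @param H Maximum horizon offset (must be below the series length).
#' @return An object of class `delta_samples`: list with `deltas` (one
#'   integer vector per h = 1..H), `H`, `ward`, `source`.
#' @export
observed_deltas <- function(census, ward = "total", H = 6L) {
  stopifnot(inherits(census, "census_trajectory"))
  tot <- census_totals(census)
  series <- if (identical(ward, "total")) colSums(tot)
  else {
    if (!ward %in% census$wards) stop("unknown ward: ", ward)
    tot[ward, ]
  }
  N <- length(series)
  if (H >= N) stop("observed_deltas: H must be smaller than the series length")
  deltas <- lapply(seq_len(H), function(h)
    as.integer(series[seq_len(N - h)] - series[seq_len(N - h) + h]))
  structure(list(deltas = deltas, H = as.integer(H), ward = ward,
                 source = "observed"), class = "delta_samples")
}

#' @export
print.delta_samples <- function(x, ...) {
  cat(sprintf("%s Delta samples, ward %s, h = 1..%d (sizes: %s)\n",
              x$source, x$ward, x$H,
              paste(vapply(x$deltas, length, 0L), collapse = ", ")))
  invisible(x)
}

# Shared machinery for the symbiotic validation loops: re-initialise the
# simulation from the records at every initiation date of the chosen
# weekday, simulate the planning horizon, and return per window the
# observed ward totals and the replicated simulated ward totals.
# The elective schedule inside each window is read retrospectively from
# the records (observed elective hospital admissions).
reinit_windows <- function(model, stays, init_weekday = "MON", H = 6L,
                           n_reps = 100L, seed = 1L, max_points = Inf,
                           from = NULL, to = NULL) {
  init_weekday <- parse_weekday(init_weekday)
  census <- derive_census(stays)
  agg_map <- model$aggregation
  if (is.null(agg_map)) {
    agg_map <- stats::setNames(census$wards, census$wards)
    unknown <- setdiff(census$wards, model$wards)
    if (length(unknown))
      stop("records contain wards outside the model: ",
           paste(unknown, collapse = ", "))
  }
  # observed ward totals on the model's ward set
  tot_raw <- census_totals(census)
  tot <- matrix(0L, nrow = length(model$wards), ncol = ncol(tot_raw),
                dimnames = list(model$wards, NULL))
  for (w in census$wards)
    tot[agg_map[[w]], ] <- tot[agg_map[[w]], ] + tot_raw[w, ]

  dates <- census$dates
  idx <- which(wday_index(dates) == init_weekday &
                 seq_along(dates) + H <= length(dates))
  if (!is.null(from)) idx <- idx[dates[idx] >= as.Date(from)]
  if (!is.null(to)) idx <- idx[dates[idx] <= as.Date(to)]
  if (!length(idx)) stop("no initiation points of that weekday in range")
  if (length(idx) > max_points)  # spread the points across the record
    idx <- idx[unique(round(seq(1L, length(idx), length.out = max_points)))]

  el <- stays[stays$admission_type == "elective" &
                stays$arrival_date == stays$hospital_admission_date, ,
              drop = FALSE]
  set.seed(seed)
  pt_seeds <- sample.int(2147483646L, length(idx))
  windows <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    t0 <- dates[idx[j]]
    snap <- capture_snapshot(stays, t0)
    in_win <- el$arrival_date > t0 & el$arrival_date <= t0 + H
    sched <- NULL
    if (any(in_win)) {
      ew <- el[in_win, , drop = FALSE]
      sched <- elective_schedule(day = as.integer(ew$arrival_date - t0),
                                 ward = unname(agg_map[ew$ward]))
    }
    sim <- simulate(model, nsim = n_reps, seed = pt_seeds[j],
                    horizon = H + 1L, schedule = sched, snapshot = snap)
    windows[[j]] <- list(
      date = t0,
      obs = tot[, idx[j] + 0:H, drop = FALSE],
      sim = sim_totals(sim))
  }
  list(windows = windows, wards = model$wards, H = as.integer(H),
       n_reps = as.integer(n_reps))
}

#' Simulated h-step occupancy-change samples from weekly re-initialisation
#'
#' For every initiation date of the chosen weekday in the records, the
#' simulation is re-initialised from the captured bed state and run over
#' the planning horizon; the change samples Delta = M_(t0) - M-hat_(t0+h)
#' are pooled over initiation points and replications, per h. M_(t0) is
#' the shared observed starting value, so at h = 0 the simulated and
#' observed values coincide by construction (the collapse property of a
#' symbiotic simulation).
#'
#' @param model A fitted `hospital_model`.
#' @param stays Ward-stay records of the physical system.
#' @param init_weekday Re-initialisation weekday (default Monday).
#' @param H Planning-horizon length in days (default 6).
#' @param n_reps Replications per initiation point (default 100).
#' @param seed Base seed.
#' @param max_points Cap on the number of initiation points (default all).
#' @param from,to Optional date bounds on the initiation points (e.g. to
#'   keep a synthetic record set's warm-up transient out of the windows).
#' @return Named list, one `delta_samples` (source "simulated") per ward.
#' @export
simulated_deltas <- function(model, stays, init_weekday = "MON", H = 6L,
                             n_reps = 100L, seed = 1L, max_points = Inf,
                             from = NULL, to = NULL) {
  rw <- reinit_windows(model, stays, init_weekday, H, n_reps, seed,
                       max_points, from, to)
  out <- lapply(seq_along(rw$wards), function(w) {
    deltas <- lapply(seq_len(H), function(h)
      as.integer(unlist(lapply(rw$windows, function(win)
        win$obs[w, 1L] - win$sim[w, h + 1L, ]))))
    structure(list(deltas = deltas, H = as.integer(H), ward = rw$wards[w],
                   source = "simulated"), class = "delta_samples")
  })
  names(out) <- rw$wards
  # aggregate all-ward series as well (the hospital-level view)
  out$total <- structure(list(
    deltas = lapply(seq_len(H), function(h)
      as.integer(unlist(lapply(rw$windows, function(win)
        sum(win$obs[, 1L]) - colSums(win$sim[, h + 1L, , drop = FALSE]))))),
    H = as.integer(H), ward = "total", source = "simulated"),
    class = "delta_samples")
  out
}

#' Probability-probability comparison of change distributions
#'
#' Evaluates the empirical CDFs of the simulated (x axis) and observed
#' (y axis) Delta samples at the union of their distinct values, per
#' horizon offset h. Coordinates near the identity line indicate similar
#' distributions; the maximum absolute deviation from the identity is
#' reported as a numeric summary (an extension of the visual assessment,
#' not a test statistic with a reference distribution).
#'
#' @param observed A `delta_samples` from [observed_deltas()].
#' @param simulated A `delta_samples` for the same ward from
#'   [simulated_deltas()].
#' @return An object of class `pp_result`: `table` (data frame with h,
#'   delta, F_sim, F_obs) and `max_dev` (named per h).
#' @export
pp_plot <- function(observed, simulated) {
  stopifnot(inherits(observed, "delta_samples"),
            inherits(simulated, "delta_samples"))
  H <- min(observed$H, simulated$H)
  rows <- vector("list", H)
  max_dev <- numeric(H)
  for (h in seq_len(H)) {
    o <- observed$deltas[[h]]
    s <- simulated$deltas[[h]]
    if (!length(o) || !length(s)) stop("empty Delta sample at h = ", h)
    grid <- sort(unique(c(o, s)))
    F_obs <- stats::ecdf(o)(grid)
    F_sim <- stats::ecdf(s)(grid)
    rows[[h]] <- data.frame(h = h, delta = grid, F_sim = F_sim,
                            F_obs = F_obs)
    max_dev[h] <- max(abs(F_obs - F_sim))
  }
  structure(list(table = do.call(rbind, rows),
                 max_dev = stats::setNames(max_dev, paste0("h", seq_len(H))),
                 ward = observed$ward),
            class = "pp_result")
}

#' @export
print.pp_result <- function(x, ...) {
  cat(sprintf("P-P comparison of Delta distributions, ward %s\n", x$ward))
  cat("max |F_obs - F_sim| by horizon offset:\n")
  print(round(x$max_dev, 4))
  invisible(x)
}

#' @export
plot.pp_result <- function(x, ...) {
  H <- length(x$max_dev)
  op <- graphics::par(mfrow = grDevices::n2mfrow(H), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (h in seq_len(H)) {
    d <- x$table[x$table$h == h, ]
    plot(d$F_sim, d$F_obs, xlim = c(0, 1), ylim = c(0, 1), pch = 20,
         xlab = "F simulation", ylab = "F physical system",
         main = sprintf("%s, h = %d", x$ward, h), ...)
    graphics::abline(0, 1, col = "grey50")
  }
  invisible(x)
}

#' Prediction-interval coverage of the re-initialised simulation
#'
#' Per ward and day of each planning horizon, the central `level` interval
#' is taken from the replication percentiles of simulated occupancy
#' (order-statistic quantiles with linear interpolation; observations
#' equal to an interval endpoint count as covered). Coverage is the
#' fraction of observed midnight occupancies inside their interval,
#' pooled over non-initiation days.
#'
#' @inheritParams simulated_deltas
#' @param level Central probability of the interval (default 0.90).
#' @return List with `coverage` (pooled fraction), `by_ward`, `n` (number
#'   of pooled ward-days) and `level`.
#' @export
interval_coverage <- function(model, stays, init_weekday = "MON", H = 6L,
                              n_reps = 100L, level = 0.90, seed = 1L,
                              max_points = Inf, from = NULL, to = NULL) {
  rw <- reinit_windows(model, stays, init_weekday, H, n_reps, seed,
                       max_points, from, to)
  alpha <- (1 - level) / 2
  hit <- 0L; tot <- 0L
  by_ward <- stats::setNames(numeric(length(rw$wards)), rw$wards)
  nw <- stats::setNames(integer(length(rw$wards)), rw$wards)
  for (win in rw$windows) {
    for (w in seq_along(rw$wards)) {
      for (h in seq_len(rw$H)) {
        qs <- stats::quantile(win$sim[w, h + 1L, ], c(alpha, 1 - alpha),
                              type = 7, names = FALSE)
        ok <- win$obs[w, h + 1L] >= qs[1L] & win$obs[w, h + 1L] <= qs[2L]
        hit <- hit + ok; tot <- tot + 1L
        by_ward[w] <- by_ward[w] + ok; nw[w] <- nw[w] + 1L
      }
    }
  }
  list(coverage = as.numeric(hit) / tot, by_ward = by_ward / nw, n = tot,
       level = level)
}

#' Weekday mean-occupancy comparison (black-box check)
#'
#' Compares, per weekday and admission type, the observed mean midnight
#' occupancy (all wards combined) against a two-tailed interval derived
#' from the simulation: the central `level` quantiles of the
#' per-replication weekday means, which is the prediction interval for the
#' mean of an observation period of the simulated length.
#'
#' @param observed A `census_trajectory` of the physical system.
#' @param result A `hospital_sim` covering at least one full week.
#' @param level Interval level (default 0.90).
#' @return Data frame with weekday, admission type, observed mean,
#'   simulated mean, interval bounds, and an `inside` flag.
#' @export
compare_weekday_means <- function(observed, result, level = 0.90) {
  stopifnot(inherits(observed, "census_trajectory"),
            inherits(result, "hospital_sim"))
  obs_wd <- wday_index(observed$dates)
  sim_wd <- ((result$start_wd - 1L + seq_len(result$horizon) - 1L) %% 7L) + 1L
  if (length(unique(obs_wd)) < 7L || length(unique(sim_wd)) < 7L)
    stop("both series must cover at least one full week")
  alpha <- (1 - level) / 2
  types <- c("emergency", "elective")
  rows <- list()
  for (k in 1:7) {
    for (ty in 1:2) {
      obs_series <- colSums(observed$counts[, obs_wd == k, ty, drop = FALSE])
      o_mean <- mean(obs_series)
      sim_slice <- result$census[, sim_wd == k, ty, , drop = FALSE]
      rep_means <- apply(sim_slice, 4L, function(x)
        mean(colSums(matrix(x, nrow = dim(sim_slice)[1L]))))
      qs <- stats::quantile(rep_means, c(alpha, 1 - alpha), type = 7,
                            names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        weekday = WDAY_NAMES[k], admission_type = types[ty],
        observed = o_mean, simulated = mean(rep_means),
        lower = qs[1L], upper = qs[2L],
        inside = o_mean >= qs[1L] & o_mean <= qs[2L],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a validation report (P-P coordinates, coverage, weekday means)
#'
#' @param model A fitted `hospital_model`.
#' @param stays Ward-stay records.
#' @param dir Output directory.
#' @inheritParams simulated_deltas
#' @return The directory, invisibly.
#' @export
write_validation_report <- function(model, stays, dir, init_weekday = "MON",
                                    H = 6L, n_reps = 100L, seed = 1L,
                                    max_points = Inf) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  census <- derive_census(stays)
  sim_ds <- simulated_deltas(model, stays, init_weekday, H, n_reps, seed,
                             max_points)
  pp_rows <- list()
  for (w in names(sim_ds)) {
    if (w %in% c(census$wards, "total")) {
      obs_ds <- observed_deltas(census, w, H)
      pp <- pp_plot(obs_ds, sim_ds[[w]])
      tab <- pp$table
      tab$ward <- w
      pp_rows[[w]] <- tab
    }
  }
  utils::write.csv(do.call(rbind, pp_rows), file.path(dir, "pp_coords.csv"),
                   row.names = FALSE, quote = FALSE)
  cov <- interval_coverage(model, stays, init_weekday, H, n_reps,
                           seed = seed, max_points = max_points)
  utils::write.csv(data.frame(ward = c(names(cov$by_ward), "pooled"),
                              coverage = c(cov$by_ward, cov$coverage)),
                   file.path(dir, "coverage.csv"), row.names = FALSE,
                   quote = FALSE)
  # weekday-mean black-box table: one long run re-initialised at the first
  # usable initiation date, with the observed elective schedule
  t0 <- census$dates[which(wday_index(census$dates) ==
                             parse_weekday(init_weekday))[1L]]
  span <- as.integer(census$dates[length(census$dates)] - t0) + 1L
  if (span >= 14L) {
    snap <- capture_snapshot(stays, t0)
    el <- stays[stays$admission_type == "elective" &
                  stays$arrival_date == stays$hospital_admission_date &
                  stays$arrival_date > t0 &
                  stays$arrival_date <= t0 + span - 1L, , drop = FALSE]
    sched <- if (nrow(el)) {
      agg <- if (!is.null(model$aggregation)) model$aggregation else
        stats::setNames(census$wards, census$wards)
      elective_schedule(day = as.integer(el$arrival_date - t0),
                        ward = unname(agg[el$ward]))
    }
    sim <- simulate(model, nsim = n_reps, seed = seed, horizon = span,
                    snapshot = snap, schedule = sched)
    cmp <- compare_weekday_means(window_census(census, t0, NULL), sim)
    utils::write.csv(cmp, file.path(dir, "weekday_means.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
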