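test_that("observed change samples follow the definition M_t - M_(t+h)", {
  cen <- mk_census(matrix(c(5L, 7L, 4L), nrow = 1,
                          dimnames = list("A", NULL)))
  ds <- observed_deltas(cen, "A", H = 2)
  expect_equal(sort(ds$deltas[[1]]), c(-2L, 3L))
  expect_equal(ds$deltas[[2]], 1L)
  const <- mk_census(matrix(3L, 1, 10, dimnames = list("A", NULL)))
  dc <- observed_deltas(const, "A", H = 4)
  expect_true(all(unlist(dc$deltas) == 0L))
  expect_equal(vapply(dc$deltas, length, 0L), 10L - (1:4))
  expect_error(observed_deltas(const, "A", H = 10), "smaller")
})

test_that("reversing a series negates its change multisets", {
  set.seed(5)
  mat <- matrix(rpois(40, 6), nrow = 1, dimnames = list("A", NULL))
  fwd <- observed_deltas(mk_census(mat), "A", H = 3)
  rev_ <- observed_deltas(mk_census(mat[, 40:1, drop = FALSE]), "A", H = 3)
  for (h in 1:3)
    expect_equal(sort(fwd$deltas[[h]]), sort(-rev_$deltas[[h]]))
})

test_that("P-P coordinates follow hand-computed ECDFs", {
  mk_ds <- function(x, src) structure(
    list(deltas = list(as.integer(x)), H = 1L, ward = "A", source = src),
    class = "delta_samples")
  # identical multisets lie on the identity
  same <- pp_plot(mk_ds(c(0, 1, 1), "observed"), mk_ds(c(1, 0, 1), "simulated"))
  expect_equal(unname(same$max_dev), 0)
  expect_equal(same$table$F_sim, same$table$F_obs)
  # worked example: observed {0,0,1}, simulated {0,1,1}
  pp <- pp_plot(mk_ds(c(0, 0, 1), "observed"), mk_ds(c(0, 1, 1), "simulated"))
  expect_equal(pp$table$delta, c(0L, 1L))
  expect_equal(pp$table$F_sim, c(1 / 3, 1))
  expect_equal(pp$table$F_obs, c(2 / 3, 1))
  expect_equal(unname(pp$max_dev), 1 / 3, tolerance = 1e-12)
  # permutation invariance
  pp2 <- pp_plot(mk_ds(c(1, 0, 0), "observed"), mk_ds(c(1, 1, 0), "simulated"))
  expect_equal(pp2$table, pp$table)
})

test_that("a lower-variance vertical sample bends around the median", {
  mk_ds <- function(x, src) structure(
    list(deltas = list(as.integer(x)), H = 1L, ward = "A", source = src),
    class = "delta_samples")
  obs <- rep(c(-1L, 0L, 1L), c(10, 80, 10))   # narrow, median 0
  sim <- rep(c(-3L, 0L, 3L), c(30, 40, 30))   # wide, median 0
  pp <- pp_plot(mk_ds(obs, "observed"), mk_ds(sim, "simulated"))
  below <- pp$table$delta < 0
  above <- pp$table$delta >= 1
  expect_true(all(pp$table$F_obs[below] <= pp$table$F_sim[below]))
  expect_true(any(pp$table$F_obs[below] < pp$table$F_sim[below]))
  expect_true(all(pp$table$F_obs[above] >= pp$table$F_sim[above]))
})

test_that("a deterministic model reproduces its records exactly", {
  # every spell: arrive Sunday, stay exactly 4 midnights; model has
  # point-mass WLOS and no arrivals, so every window is deterministic
  arrs <- seq(6, 62, by = 7)  # Sundays (day offsets from Monday d0)
  stays <- mk_stays(paste0("P", seq_along(arrs)), "A", arr = arrs,
                    dep = arrs + 4)
  model <- toy_model(wlos_pmf = point_pmf(4L))
  sim_ds <- simulated_deltas(model, stays, "MON", H = 5, n_reps = 3,
                             seed = 2)
  cen <- derive_census(stays)
  # simulated Delta values are deterministic: every replication agrees
  for (h in 1:5)
    expect_equal(length(unique(sim_ds$A$deltas[[h]])), 1L)
  # and equal the observed Delta at the initiation points
  mondays <- which(wday_index(cen$dates) == 1 &
                     seq_along(cen$dates) + 5 <= length(cen$dates))
  series <- cen$counts["A", , 1] + cen$counts["A", , 2]
  for (h in 1:5) {
    obs_at_init <- series[mondays] - series[mondays + h]
    expect_equal(sort(unique(sim_ds$A$deltas[[h]])),
                 sort(unique(as.integer(obs_at_init))))
  }
  # pooled sample size is (#initiation points) x n_reps
  expect_equal(length(sim_ds$A$deltas[[1]]), length(mondays) * 3L)
  # interval coverage is exact for a perfect deterministic model
  cov <- interval_coverage(model, stays, "MON", H = 5, n_reps = 3, seed = 2)
  expect_equal(cov$coverage, 1)
})

test_that("weekday mean comparison flags its own trajectory as inside", {
  set.seed(9)
  mat <- matrix(rpois(28, 10), nrow = 1, dimnames = list("A", NULL))
  cen <- mk_census(mat)                       # starts on a Monday
  counts <- array(0L, dim = c(1, 28, 2, 2),
                  dimnames = list("A", NULL, c("emergency", "elective"), NULL))
  counts[1, , 1, 1] <- mat
  counts[1, , 1, 2] <- mat
  sim <- hospital_sim(counts, start = "MON")
  cmp <- compare_weekday_means(cen, sim)
  expect_true(all(cmp$inside))
  expect_equal(cmp$observed, cmp$simulated)
  # constant series at a different level falls outside
  cen2 <- mk_census(matrix(20L, 1, 28, dimnames = list("A", NULL)))
  cmp2 <- compare_weekday_means(cen2, sim)
  expect_false(any(cmp2$inside[cmp2$admission_type == "emergency"]))
})

test_that("weekday mean intervals cover a correctly specified system", {
  cfg <- small_truth(horizon = 224)
  rec <- generate_records(cfg, seed = 40)
  capture <- d0 + 84
  snap <- capture_snapshot(rec$stays, capture)
  fit <- truth_model(cfg)
  el <- rec$stays[rec$stays$admission_type == "elective" &
                    rec$stays$arrival_date ==
                      rec$stays$hospital_admission_date, ]
  in_win <- el$arrival_date > capture & el$arrival_date <= capture + 139
  sched <- elective_schedule(
    day = as.integer(el$arrival_date[in_win] - capture),
    ward = el$ward[in_win])
  sim <- simulate(fit, nsim = 60, seed = 41, horizon = 140,
                  snapshot = snap, schedule = sched)
  # held-out replications of the same process stand in for the physical
  # system: their weekday means must fall inside the simulation's 90%
  # intervals at roughly the nominal rate
  held <- simulate(fit, nsim = 4, seed = 43, horizon = 140,
                   snapshot = snap, schedule = sched)
  inside <- vapply(1:4, function(r) {
    obs_cen <- structure(list(
      counts = held$census[, , , r],
      dates = seq(capture, by = "day", length.out = 140),
      wards = held$wards), class = "census_trajectory")
    mean(compare_weekday_means(obs_cen, sim)$inside)
  }, 0)
  expect_gte(mean(inside), 0.75)
  # the generated records themselves are a draw from the same process;
  # their weekday means should mostly fall inside too, though a single
  # 140-day path can drift
  obs_cen <- window_census(derive_census(rec$stays), capture, capture + 139)
  expect_gte(mean(compare_weekday_means(obs_cen, sim)$inside), 0.5)
})
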