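test_that("BMOC arithmetic on a hand-built trajectory", {
  occ <- matrix(c(12L, 9L, 11L), nrow = 1, dimnames = list("A", NULL))
  sim <- hospital_sim(occ)
  caps <- capacity_config(c(A = 10))
  rep_ <- warning_report(sim, caps)
  expect_equal(rep_$bmoc, 3)                # 2 + 0 + 1
  expect_equal(rep_$table$p_capacity, c(1, 0, 1))
  expect_equal(rep_$table$p_threshold, c(1, 0, 1))  # threshold 9: 12,9,11 -> 9 not > 9
})

test_that("BMOC is the mean over replications and zero when under capacity", {
  counts <- array(0L, dim = c(1, 3, 2, 2),
                  dimnames = list("A", NULL, c("emergency", "elective"), NULL))
  counts[1, , 1, 1] <- c(12L, 9L, 11L)   # BMOC 3
  counts[1, , 1, 2] <- c(11L, 9L, 9L)    # BMOC 1
  sim <- hospital_sim(counts)
  rep_ <- warning_report(sim, capacity_config(c(A = 10)))
  expect_equal(rep_$bmoc, 2)
  expect_equal(sort(rep_$bmoc_reps), c(1, 3))

  low <- hospital_sim(matrix(c(3L, 4L, 2L), 1, dimnames = list("A", NULL)))
  rl <- warning_report(low, capacity_config(c(A = 10)))
  expect_equal(rl$bmoc, 0)
  expect_true(all(rl$table$p_threshold == 0))
  expect_error(warning_report(low, capacity_config(c(B = 5))), "capacity")
})

test_that("exceedance probability is non-increasing in the threshold", {
  cfg <- small_truth(horizon = 50)
  fit <- truth_model(cfg)
  snapg <- generate_snapshot(cfg, warmup_days = 40, seed = 10)
  sim <- simulate(fit, nsim = 60, seed = 11, horizon = 7,
                  snapshot = snapg$snapshot)
  rep_ <- warning_report(sim, capacity_config(c(A = 12, B = 10)))
  expect_true(all(rep_$table$p_capacity <= rep_$table$p_threshold))
  # initiation day excluded
  expect_false(0 %in% rep_$table$day)
  expect_equal(rep_$days_used, 1:6)
})

test_that("common random numbers couple schedule comparisons", {
  cfg <- small_truth(horizon = 50)
  fit <- truth_model(cfg)
  snapg <- generate_snapshot(cfg, warmup_days = 40, seed = 20)
  caps <- capacity_config(c(A = 14, B = 11))
  sched <- elective_schedule(day = c(1, 2, 3, 4), ward = c("A", "A", "B", "A"),
                             horizon = 7)
  same <- compare_schedules(fit, snapg$snapshot,
                            list(obs = sched, again = sched), caps,
                            horizon = 7, n_reps = 50, seed = 21)
  expect_identical(same$reports$obs$table, same$reports$again$table)
  expect_equal(same$comparison$bmoc_delta, c(0, 0))

  # cancelling a patient can never increase BMOC under coupled streams
  # (the cancelled patient is the last schedule row, so shared draws align)
  cancel <- elective_schedule(day = c(1, 2, 3), ward = c("A", "A", "B"),
                              horizon = 7)
  cmp <- compare_schedules(fit, snapg$snapshot,
                           list(obs = sched, cancel = cancel), caps,
                           horizon = 7, n_reps = 50, seed = 21)
  expect_lte(cmp$comparison$bmoc_delta[2], 0)

  # postponement keeps the number of planned admissions unchanged
  postpone <- elective_schedule(day = c(1, 2, 4, 4), ward = c("A", "A", "B", "A"),
                                horizon = 7)
  expect_equal(nrow(postpone), nrow(sched))
  expect_error(compare_schedules(
    fit, snapg$snapshot,
    list(a = sched, b = elective_schedule(day = 1, ward = "A", horizon = 5)),
    caps, horizon = 7, n_reps = 10, seed = 1), "horizon")
})

test_that("full information removes all sampling variance (d = 1)", {
  model <- toy_model(wlos_pmf = geometric_pmf(0.4, 15))
  snap <- system_snapshot(data.frame(
    patient_id = sprintf("R%02d", 1:24), ward = "A",
    admission_type = rep(c("emergency", "elective"), 12),
    arrival_weekday = rep(1:6, 4), elapsed = rep(0:5, 4),
    known_remaining = rep(c(1L, 3L, 2L, 5L, 4L, 2L), 4)),
    capture_date = d0)
  sched <- elective_schedule(day = c(1, 2, 4), ward = "A",
                             true_los = c(2L, 4L, 1L))
  res <- edd_experiment(model, snap, sched, d_grid = c(0, 1),
                        horizon = 7, n_reps = 80, seed = 30)
  expect_true(all(res$sd[res$d == 1] == 0))
  expect_true(any(res$sd[res$d == 0] > 0))
})

test_that("d = 0 with the mechanism active matches the plain run in law", {
  model <- toy_model(wlos_pmf = geometric_pmf(0.4, 15))
  snap <- system_snapshot(data.frame(
    patient_id = sprintf("R%02d", 1:20), ward = "A",
    admission_type = "emergency", arrival_weekday = 1L,
    elapsed = rep(0:4, 4), known_remaining = rep(2L, 20)),
    capture_date = d0)
  plain <- simulate(model, nsim = 400, seed = 31, horizon = 6,
                    snapshot = snap)
  info0 <- simulate(model, nsim = 400, seed = 32, horizon = 6,
                    snapshot = snap, d = 0)
  m1 <- apply(sim_means <- plain$census["A", , , ], 1, sum) / 400
  m2 <- apply(info0$census["A", , , ], 1, sum) / 400
  expect_lt(max(abs(m1 - m2)), 1.2)  # ~4 se of a 20-resident day count
})

test_that("truth requirements are enforced when d > 0", {
  model <- toy_model()
  snap_missing <- system_snapshot(data.frame(
    patient_id = "R1", ward = "A", admission_type = "emergency",
    arrival_weekday = 1L, elapsed = 2L, known_remaining = NA_integer_),
    capture_date = d0)
  expect_error(simulate(model, nsim = 2, seed = 1, horizon = 3,
                        snapshot = snap_missing, d = 0.5), "R1")
  sched_missing <- elective_schedule(day = 1L, ward = "A")
  expect_error(simulate(model, nsim = 2, seed = 1, horizon = 3,
                        schedule = sched_missing, d = 0.5), "true_los")
})
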