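test_that("capture_snapshot lists residents with elapsed time", {
  stays <- ward_stays(rbind(
    mk_stays("P1", "A", arr = 0, dep = 10),        # resident, s = 4
    mk_stays("P2", "A", arr = 1, dep = 3),         # departed before capture
    mk_stays("P3", "B", "elective", arr = 4, dep = 9)))  # arrived today
  snap <- capture_snapshot(stays, d0 + 4)
  expect_equal(nrow(snap), 2L)
  expect_equal(snap$elapsed[snap$patient_id == "P1"], 4L)
  expect_equal(snap$elapsed[snap$patient_id == "P3"], 0L)
  expect_equal(snap$arrival_weekday[snap$patient_id == "P3"],
               wday_index(d0 + 4))
  expect_equal(snap$known_remaining[snap$patient_id == "P1"], 6L)
  expect_false("P2" %in% snap$patient_id)
})

test_that("snapshot resident counts equal the census at the capture date", {
  cfg <- small_truth(horizon = 70)
  stays <- generate_records(cfg, seed = 3)$stays
  cen <- derive_census(stays)
  for (off in c(20L, 35L)) {
    snap <- capture_snapshot(stays, cen$dates[off])
    expect_equal(nrow(snap), sum(cen$counts[, off, ]))
  }
})

test_that("snapshot files round-trip", {
  snap <- system_snapshot(data.frame(
    patient_id = c("R1", "R2"), ward = c("A", "B"),
    admission_type = c("emergency", "elective"),
    arrival_weekday = c("MON", "THU"), elapsed = c(3L, 0L),
    known_remaining = c(2L, NA)), capture_date = d0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_snapshot(snap, path)
  back <- read_snapshot(path, capture_date = d0)
  expect_equal(as.data.frame(back), as.data.frame(snap))
  expect_equal(attr(back, "capture_date"), d0)
})

test_that("conditional distribution at s = 0 is the unconditional one", {
  F_T <- empirical_pmf(c(1L, 2L, 5L), c(0.2, 0.5, 0.3))
  cond <- conditional_cdf(F_T, 0)
  expect_equal(cond$pmf$support, F_T$support)
  expect_equal(cond$pmf$prob, F_T$prob)
})

test_that("worked conditional example: elapsed 2 of {1:.5, 2:.3, 3:.2}", {
  F_T <- empirical_pmf(1:3, c(0.5, 0.3, 0.2))
  cond <- conditional_cdf(F_T, 2)
  expect_equal(cond$pmf$support, c(0L, 1L))
  expect_equal(cond$pmf$prob, c(0.6, 0.4))
  # rejection-sampling oracle
  set.seed(7)
  T_draws <- sample(1:3, 2e5, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  kept <- T_draws[T_draws >= 2] - 2L
  expect_lt(abs(mean(kept == 0) - 0.6), 0.01)
})

test_that("conditional pmf equals direct ratio arithmetic exactly", {
  set.seed(42)
  for (rep in 1:10) {
    k <- sample(3:7, 1)
    supp <- sort(sample(0:14, k))
    pr <- runif(k, 0.5, 1.5); pr <- pr / sum(pr)
    F_T <- empirical_pmf(supp, pr)
    for (s in 0:max(supp)) {
      cond <- conditional_cdf(F_T, s)
      tail_i <- supp >= s
      expect_equal(cond$pmf$prob,
                   pr[tail_i] / sum(pr[tail_i]), tolerance = 1e-12)
      expect_equal(cond$pmf$support, supp[tail_i] - s)
      expect_equal(sum(cond$pmf$prob), 1, tolerance = 1e-12)
    }
  }
})

test_that("elapsed times beyond the support are clamped, not fatal", {
  F_T <- empirical_pmf(1:3, c(0.5, 0.3, 0.2))
  cond <- conditional_cdf(F_T, 10)
  expect_true(cond$clamped)
  expect_equal(cond$s_used, 3L)
  expect_equal(cond$pmf$support, 0L)
  expect_equal(cond$pmf$prob, 1)
})

test_that("sample_remaining is an inverse-transform draw over r", {
  F_T <- empirical_pmf(1:3, c(0.5, 0.3, 0.2))
  cond <- conditional_cdf(F_T, 2)
  expect_equal(sample_remaining(conditional_cdf(point_pmf(5L), 3), runif(5)),
               rep(2L, 5))
  set.seed(11)
  r <- sample_remaining(cond, runif(1e5))
  expect_lt(abs(mean(r == 0) - 0.6), 0.005)
  expect_true(all(r <= max(F_T$support) - 2L))
})

test_that("memoryless WLOS needs no conditioning (geometric case)", {
  # geometric on {0, 1, ...}: the remaining distribution is the same at
  # every elapsed time
  p <- 0.5
  F_T <- geometric_pmf(p, 200, start = 0L, renormalize = FALSE)
  base <- conditional_cdf(F_T, 0)$pmf
  for (s in 1:5) {
    cond <- conditional_cdf(F_T, s)$pmf
    m <- seq_len(50)
    expect_equal(cond$prob[m], base$prob[m], tolerance = 1e-12)
    expect_equal(cond$support[m], base$support[m])
  }
})

test_that("re-initialising with elapsed 0 equals admitting fresh that day", {
  # run A: snapshot of 6 elective residents with s = 0, empty schedule;
  # run B: empty snapshot + 6 scheduled electives on day 0. Same seeds
  # must give bit-identical trajectories.
  model <- toy_model(wlos_pmf = empirical_pmf(1:4, c(0.4, 0.3, 0.2, 0.1)))
  snapA <- system_snapshot(data.frame(
    patient_id = paste0("R", 1:6), ward = "A",
    admission_type = "elective", arrival_weekday = wday_index(d0),
    elapsed = 0L, known_remaining = NA_integer_), capture_date = d0)
  snap0 <- system_snapshot(data.frame(
    patient_id = character(0), ward = character(0),
    admission_type = character(0), arrival_weekday = integer(0),
    elapsed = integer(0), known_remaining = integer(0)), capture_date = d0)
  schedB <- elective_schedule(day = rep(0L, 6), ward = "A")
  simA <- simulate(model, nsim = 20, seed = 99, horizon = 8, snapshot = snapA)
  simB <- simulate(model, nsim = 20, seed = 99, horizon = 8,
                   snapshot = snap0, schedule = schedB)
  expect_identical(simA$census, simB$census)
})

test_that("age-mixed conditional distributions stay proper", {
  set.seed(3)
  for (rep in 1:5) {
    k <- sample(3:6, 1)
    supp <- sort(sample(1:12, k))
    pr <- runif(k, 0.5, 1.5); pr <- pr / sum(pr)
    F_T <- empirical_pmf(supp, pr)
    # stationary age distribution of a renewal process: P(age = s)
    # proportional to P(T > s)
    ages <- 0:(max(supp) - 1L)
    w <- vapply(ages, function(s) sum(pr[supp > s]), 0)
    w <- w / sum(w)
    mix_total <- sum(vapply(seq_along(ages), function(i)
      w[i] * sum(conditional_cdf(F_T, ages[i])$pmf$prob), 0))
    expect_equal(mix_total, 1, tolerance = 1e-12)
  }
})
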