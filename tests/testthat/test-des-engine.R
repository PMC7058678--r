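test_that("no arrivals, no schedule, no snapshot gives an all-zero census", {
  model <- toy_model()
  sim <- simulate(model, nsim = 10, seed = 1, horizon = 14, start = "MON")
  expect_true(all(sim$census == 0L))
  expect_true(all(sim$ledger$admissions == 0L))
})

test_that("a degenerate deterministic scenario traces exactly", {
  # one elective on day 0, WLOS point mass 3, guaranteed attendance:
  # occupancy 1 on days 0, 1, 2 and 0 afterwards, in every replication
  model <- toy_model(wlos_pmf = point_pmf(3L))
  sched <- elective_schedule(day = 0L, ward = "A")
  sim <- simulate(model, nsim = 25, seed = 2, horizon = 6, start = "MON",
                  schedule = sched)
  for (r in seq_len(sim$nsim)) {
    expect_equal(unname(sim$census["A", , "elective", r]),
                 c(1L, 1L, 1L, 0L, 0L, 0L))
  }
  expect_true(all(sim$census[, , "emergency", ] == 0L))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- small_truth(horizon = 60)
  fit <- truth_model(cfg)
  sched <- elective_schedule(day = c(1, 3), ward = c("A", "B"))
  s1 <- simulate(fit, nsim = 15, seed = 77, horizon = 21, start = "TUE",
                 schedule = sched)
  s2 <- simulate(fit, nsim = 15, seed = 77, horizon = 21, start = "TUE",
                 schedule = sched)
  expect_identical(s1$census, s2$census)
  s3 <- simulate(fit, nsim = 15, seed = 78, horizon = 21, start = "TUE",
                 schedule = sched)
  expect_false(identical(s1$census, s3$census))
})

test_that("patient ledger balances: admissions - discharges = final census", {
  cfg <- small_truth(horizon = 60)
  fit <- truth_model(cfg)
  snapg <- generate_snapshot(cfg, warmup_days = 40, seed = 5)
  sim <- simulate(fit, nsim = 30, seed = 6, horizon = 14,
                  snapshot = snapg$snapshot,
                  schedule = elective_schedule(day = c(2, 2, 5),
                                               ward = c("A", "A", "B")))
  expect_equal(sim$ledger$admissions - sim$ledger$discharges,
               sim$ledger$final_census)
  expect_true(all(sim$census >= 0L))
})

test_that("added electives increase occupancy pathwise under shared seeds", {
  model <- toy_model(arrival_pmf = poisson_pmf(1.5),
                     wlos_pmf = empirical_pmf(1:5, rep(0.2, 5)))
  base <- elective_schedule(day = c(1, 2), ward = "A")
  extra <- elective_schedule(day = c(1, 2, 3, 3), ward = "A")  # base + day-3 pair
  sA <- simulate(model, nsim = 40, seed = 13, horizon = 10, start = "MON",
                 schedule = base)
  sB <- simulate(model, nsim = 40, seed = 13, horizon = 10, start = "MON",
                 schedule = extra)
  totA <- apply(sA$census, c(2, 4), sum)
  totB <- apply(sB$census, c(2, 4), sum)
  expect_true(all(totB >= totA))
  expect_equal(totA[1:3, ], totB[1:3, ])  # identical before the extras arrive
})

test_that("two-ward short-horizon census matches exhaustive enumeration", {
  # ward 1: Bernoulli(0.5) arrival each day, WLOS {1:.6, 2:.4},
  # transfer to ward 2 w.p. 0.3 on departure; ward 2: no arrivals, WLOS 1.
  arr1 <- empirical_pmf(0:1, c(0.5, 0.5))
  model <- toy_model2(arr1, point_pmf(0L),
                      wlos1 = empirical_pmf(1:2, c(0.6, 0.4)),
                      wlos2 = point_pmf(1L), p12 = 0.3)
  # exact law of (M1_w1, M1_w2) at day 1 by enumeration over the outcome
  # lattice: day-0 arrival A, day-1 arrival B, A's LOS, A's destination
  probs <- list()
  add <- function(key, p) probs[[key]] <<- (probs[[key]] %||% 0) + p
  for (A in 0:1) for (B in 0:1) for (L in 1:2) for (tr in 0:1) {
    p <- dbinom(A, 1, 0.5) * dbinom(B, 1, 0.5) *
      c(0.6, 0.4)[L] * c(0.7, 0.3)[tr + 1]
    m1_w1 <- B + (A == 1 && L == 2)
    m1_w2 <- as.integer(A == 1 && L == 1 && tr == 1)
    add(paste(m1_w1, m1_w2), p)
  }
  sim <- simulate(model, nsim = 4000, seed = 91, horizon = 2, start = "MON")
  key_sim <- paste(sim$census["W1", 2, "emergency", ],
                   sim$census["W2", 2, "emergency", ])
  for (key in names(probs)) {
    phat <- mean(key_sim == key)
    tol <- 3 * sqrt(probs[[key]] * (1 - probs[[key]]) / 4000) + 1e-9
    expect_lt(abs(phat - probs[[key]]), tol)
  }
  # day-0 marginal: occupancy 1 iff an arrival occurred
  expect_lt(abs(mean(sim$census["W1", 1, "emergency", ]) - 0.5),
            3 * sqrt(0.25 / 4000))
})

test_that("stationary occupancy approaches the infinite-server closed form", {
  # Poisson(2) arrivals, geometric(0.5) WLOS: stationary occupancy is
  # Poisson with mean 2/0.5 = 4
  model <- toy_model(arrival_pmf = poisson_pmf(2),
                     wlos_pmf = geometric_pmf(0.5, 30))
  sim <- simulate(model, nsim = 300, seed = 3, horizon = 60, start = "WED")
  expect_lt(abs(sum(sim$census["A", 60, , ]) / 300 - 4), 3 * sqrt(4 / 300))
})

test_that("elective non-attendance thins the schedule", {
  model <- toy_model(wlos_pmf = point_pmf(1L), nonattendance = 0.4)
  sched <- elective_schedule(day = rep(0L, 50), ward = "A")
  sim <- simulate(model, nsim = 200, seed = 8, horizon = 2, start = "MON",
                  schedule = sched)
  attended <- sim$census["A", 1, "elective", ]
  expect_lt(abs(mean(attended) - 30), 3 * sqrt(50 * 0.6 * 0.4 / 200) + 0.5)
})

test_that("schedules referencing unknown wards fail before any sampling", {
  model <- toy_model()
  bad <- elective_schedule(day = 0L, ward = "Z")
  expect_error(simulate(model, nsim = 2, seed = 1, horizon = 3,
                        schedule = bad, start = "MON"), "unknown ward")
})
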