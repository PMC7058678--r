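# Shared fixtures: everything is built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

d0 <- as.Date("2010-01-04")  # a Monday

# quick ward-stay builder; dates given as integer day offsets from d0
mk_stays <- function(patient, ward, type = "emergency", arr, dep = NULL,
                     had = NULL) {
  n <- length(arr)
  if (is.null(dep)) dep <- rep(NA_integer_, n)
  if (is.null(had)) had <- arr
  ward_stays(data.frame(
    patient_id = rep_len(patient, n), ward = rep_len(ward, n),
    admission_type = rep_len(type, n),
    arrival_date = d0 + arr,
    departure_date = d0 + ifelse(is.na(dep), NA, dep),
    hospital_admission_date = d0 + had,
    stringsAsFactors = FALSE))
}

point_pmf <- function(k) empirical_pmf(k, 1)

# one-row transition matrix helpers
trans1 <- function(ward = "A", p_self = 0) {
  m <- matrix(c(p_self, 1 - p_self), 1, 2,
              dimnames = list(ward, c(ward, "discharge")))
  list(emergency = m, elective = m)
}

# single-ward model with identical pmfs across types/weekdays
toy_model <- function(arrival_pmf = point_pmf(0L),
                      wlos_pmf = geometric_pmf(0.5, 20),
                      ward = "A", nonattendance = 0) {
  hospital_parameters(
    wards = ward,
    arrivals = stats::setNames(list(rep(list(arrival_pmf), 7)), ward),
    wlos = stats::setNames(list(list(
      emergency = rep(list(wlos_pmf), 7),
      elective = rep(list(wlos_pmf), 7))), ward),
    transitions = trans1(ward),
    nonattendance = nonattendance)
}

# two-ward model with per-ward arrival/wlos pmfs and transfer probability
# p12 from ward 1 to ward 2 (ward 2 always discharges)
toy_model2 <- function(arr1, arr2, wlos1, wlos2, p12 = 0) {
  wards <- c("W1", "W2")
  tm <- matrix(c(0, p12, 1 - p12,
                 0, 0, 1), 2, 3, byrow = TRUE,
               dimnames = list(wards, c(wards, "discharge")))
  hospital_parameters(
    wards = wards,
    arrivals = list(W1 = rep(list(arr1), 7), W2 = rep(list(arr2), 7)),
    wlos = list(
      W1 = list(emergency = rep(list(wlos1), 7),
                elective = rep(list(wlos1), 7)),
      W2 = list(emergency = rep(list(wlos2), 7),
                elective = rep(list(wlos2), 7))),
    transitions = list(emergency = tm, elective = tm))
}

# census trajectory built directly from a ward x day matrix of totals
# (all counts filed under emergency)
mk_census <- function(mat, start = d0) {
  wards <- rownames(mat)
  counts <- array(0L, dim = c(nrow(mat), ncol(mat), 2L),
                  dimnames = list(wards, NULL, c("emergency", "elective")))
  counts[, , 1L] <- as.integer(mat)
  structure(list(counts = counts,
                 dates = seq(start, by = "day", length.out = ncol(mat)),
                 wards = wards),
            class = "census_trajectory")
}

# Synthetic hospital for the Delta-Method self-validation. Weekday-constant
# rates: the method pools observed changes over all start days but
# simulated changes over Monday initiations, so its identity-line premise
# presumes the change distribution is start-day invariant. Long records
# (220 weeks) keep the observed ECDFs precise; only the first 50 Mondays
# are used as initiation points.
delta_world <- function() {
  tm <- matrix(c(0.00, 0.08, 0.04, 0.88,
                 0.06, 0.00, 0.03, 0.91,
                 0.08, 0.00, 0.00, 0.92), 3, 4, byrow = TRUE,
               dimnames = list(c("A", "B", "C"),
                               c("A", "B", "C", "discharge")))
  ground_truth_config(
    wards = c("A", "B", "C"),
    emergency_rate = c(10, 7, 4),
    wlos = list(A = list(p = 0.5, max = 30), B = list(p = 0.45, max = 30),
                C = list(p = 0.4, max = 30)),
    transitions = tm,
    elective_daily = matrix(c(rep(2, 7), rep(1, 7), rep(0, 7)),
                            3, 7, byrow = TRUE),
    horizon = 1540)
}

# Same-mean, half-variance transform of a length-of-stay pmf: support
# points are pulled toward the mean by 1/sqrt(2) and re-aggregated.
shrink_pmf_variance <- function(pmf) {
  mu <- pmf_mean(pmf)
  new_supp <- pmax(1L, as.integer(round(mu + (pmf$support - mu) / sqrt(2))))
  agg <- tapply(pmf$prob, new_supp, sum)
  empirical_pmf(as.integer(names(agg)), as.numeric(agg) / sum(agg))
}

# moderate synthetic hospital used by several integration tests
small_truth <- function(horizon = 140) {
  ground_truth_config(
    wards = c("A", "B"),
    emergency_rate = matrix(c(rep(5, 5), 3.5, 3.5,
                              rep(3, 5), 2.0, 2.0), 2, 7, byrow = TRUE),
    wlos = list(A = list(p = 0.45, max = 20), B = list(p = 0.35, max = 25)),
    transitions = matrix(c(0.04, 0.10, 0.86,
                           0.06, 0.03, 0.91), 2, 3, byrow = TRUE,
                         dimnames = list(c("A", "B"),
                                         c("A", "B", "discharge"))),
    elective_daily = matrix(c(rep(2, 5), 0, 0, rep(1, 5), 0, 0),
                            2, 7, byrow = TRUE),
    horizon = horizon)
}
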