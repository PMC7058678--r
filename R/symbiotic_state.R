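#' System snapshot: the live bed state of the hospital
#'
#' A `system_snapshot` is a data frame with one row per resident patient at
#' the capture midnight: `patient_id`, `ward`, `admission_type`,
#' `arrival_weekday` (1 = Monday .. 7 = Sunday, the weekday of arrival at
#' the current ward), `elapsed` (midnights already spent on the current
#' ward, >= 0) and `known_remaining` (the true remaining ward
#' length-of-stay when available, `NA` otherwise; used by the
#' estimated-discharge-information mechanism).
#'
#' @param df Data frame with the columns above (`arrival_weekday` may use
#'   MON..SUN names).
#' @param capture_date Optional `Date` recorded as an attribute.
#' @return A validated `system_snapshot` data frame.
#' @export
system_snapshot <- function(df, capture_date = NULL) {
  req <- c("patient_id", "ward", "admission_type", "arrival_weekday",
           "elapsed")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("system_snapshot: missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(
    patient_id = as.character(df$patient_id),
    ward = as.character(df$ward),
    admission_type = as.character(df$admission_type),
    arrival_weekday = parse_weekday(df$arrival_weekday),
    elapsed = as.integer(df$elapsed),
    known_remaining = if ("known_remaining" %in% names(df))
      as.integer(df$known_remaining) else NA_integer_,
    stringsAsFactors = FALSE
  )
  if (any(out$elapsed < 0L)) stop("system_snapshot: negative elapsed time")
  if (any(!is.na(out$known_remaining) & out$known_remaining < 1L))
    stop("system_snapshot: known_remaining must be >= 1 when present")
  if (any(!out$admission_type %in% c("emergency", "elective")))
    stop("system_snapshot: bad admission_type")
  attr(out, "capture_date") <- if (is.null(capture_date)) NULL
  else as.Date(capture_date)
  class(out) <- c("system_snapshot", "data.frame")
  out
}

#' Capture the system state from ward-stay records
#'
#' One resident entry per patient with a ward stay open at the midnight of
#' `date` (arrival <= date < departure). Elapsed time is `date` minus the
#' arrival at the current ward; the conditioning weekday is the weekday of
#' arrival at that ward.
#'
#' @param stays A `ward_stays` data frame.
#' @param date Capture date.
#' @return A `system_snapshot` with attribute `capture_date`.
#' @export
capture_snapshot <- function(stays, date) {
  date <- as.Date(date)
  open <- stays$arrival_date <= date &
    (is.na(stays$departure_date) | stays$departure_date > date)
  open <- open & !same_day_spell(stays)
  s <- stays[open, , drop = FALSE]
  system_snapshot(data.frame(
    patient_id = s$patient_id, ward = s$ward,
    admission_type = s$admission_type,
    arrival_weekday = wday_index(s$arrival_date),
    elapsed = as.integer(date - s$arrival_date),
    known_remaining = ifelse(is.na(s$departure_date), NA_integer_,
                             as.integer(s$departure_date - date)),
    stringsAsFactors = FALSE), capture_date = date)
}

#' Read and write snapshot files
#'
#' CSV with columns patient_id, ward, admission_type, arrival_weekday
#' (MON..SUN), elapsed_midnights, known_remaining (blank = unknown).
#'
#' @param path File path.
#' @param capture_date Optional capture date to attach on read.
#' @return `read_snapshot` returns a `system_snapshot`; `write_snapshot`
#'   returns `path` invisibly.
#' @export
read_snapshot <- function(path, capture_date = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("elapsed_midnights" %in% names(df)) df$elapsed <- df$elapsed_midnights
  system_snapshot(df, capture_date = capture_date)
}

#' @rdname read_snapshot
#' @param snapshot A `system_snapshot`.
#' @export
write_snapshot <- function(snapshot, path) {
  df <- data.frame(patient_id = snapshot$patient_id, ward = snapshot$ward,
                   admission_type = snapshot$admission_type,
                   arrival_weekday = WDAY_NAMES[snapshot$arrival_weekday],
                   elapsed_midnights = snapshot$elapsed,
                   known_remaining = ifelse(is.na(snapshot$known_remaining),
                                            "", snapshot$known_remaining))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Conditional remaining length-of-stay distribution
#'
#' Given the marginal length-of-stay distribution F_T and a patient's
#' elapsed time s on the ward, the remaining time R = T - s has CDF
#' F_R(r, s) = (F_T(s + r) - F_T(s - 1)) / (1 - F_T(s - 1)), with the
#' convention F_T(-1) = 0 so that s = 0 reduces to the unconditional
#' distribution. If the elapsed time exceeds the empirical support
#' (a long-stayer unseen in the training data), s is clamped down to the
#' largest supported elapsed time so the patient stays in-system.
#'
#' @param F_T An `empirical_pmf` of total ward length-of-stay.
#' @param s Elapsed midnights on the ward (integer >= 0).
#' @return An object of class `conditional_cdf`: list with `pmf` (an
#'   `empirical_pmf` over remaining midnights r >= 0), `s` (requested),
#'   `s_used` (after clamping) and `clamped`.
#' @export
conditional_cdf <- function(F_T, s) {
  stopifnot(inherits(F_T, "empirical_pmf"), s >= 0)
  s <- as.integer(s)
  s_used <- min(s, max(F_T$support))
  denom <- 1 - pmf_cdf(F_T, s_used - 1L)
  # clamp further if rounding left no mass at s_used (cannot happen for a
  # valid pmf unless trailing zero-probability atoms exist)
  while (denom <= 0 && s_used > min(F_T$support)) {
    s_used <- s_used - 1L
    denom <- 1 - pmf_cdf(F_T, s_used - 1L)
  }
  if (denom <= 0) stop("conditional_cdf: no probability mass at any s")
  keep <- F_T$support >= s_used
  r <- F_T$support[keep] - s_used
  # pmf from the CDF-difference formula: increments of F_R(r, s)
  FR <- (pmf_cdf(F_T, s_used + r) - pmf_cdf(F_T, s_used - 1L)) / denom
  pr <- diff(c(0, FR))
  pr[length(pr)] <- pr[length(pr)] + (1 - sum(pr))  # absorb fp residue
  structure(list(pmf = empirical_pmf(r, pr, n = F_T$n), s = s,
                 s_used = s_used, clamped = s_used < s),
            class = "conditional_cdf")
}

#' Inverse-transform draw of remaining length-of-stay
#'
#' @param cond A `conditional_cdf`.
#' @param u Uniform(0,1) draws.
#' @return Integer remaining midnights, r >= 0; r = 0 means the patient
#'   departs at the next midnight boundary.
#' @export
sample_remaining <- function(cond, u) {
  stopifnot(inherits(cond, "conditional_cdf"))
  sample_pmf(cond$pmf, u)
}

#' @export
print.conditional_cdf <- function(x, ...) {
  cat(sprintf("conditional remaining-LOS distribution at s = %d%s\n", x$s,
              if (x$clamped) sprintf(" (clamped to %d)", x$s_used) else ""))
  print(x$pmf)
  invisible(x)
}
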