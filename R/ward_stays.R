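#' @keywords internal
"_PACKAGE"

# Weekday convention used throughout: integer 1..7 = Monday..Sunday.
WDAY_NAMES <- c("MON", "TUE", "WED", "THU", "FRI", "SAT", "SUN")

#' Weekday index of a date (Monday = 1 ... Sunday = 7)
#' @param date A `Date` vector.
#' @return Integer vector in 1..7.
#' @export
wday_index <- function(date) {
  ((as.integer(as.Date(date)) + 3L) %% 7L) + 1L  # 1970-01-01 was a Thursday
}

parse_weekday <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    stopifnot(all(x >= 1L & x <= 7L))
    return(x)
  }
  i <- match(toupper(substr(x, 1L, 3L)), WDAY_NAMES)
  if (anyNA(i)) stop("unknown weekday name: ", paste(x[is.na(i)], collapse = ", "))
  i
}

#' Ward-stay records
#'
#' A `ward_stays` object is a data frame with one row per contiguous
#' occupancy of one ward by one patient: `patient_id`, `ward`,
#' `admission_type` ("emergency" or "elective"), `arrival_date`,
#' `departure_date` (`NA` = still resident) and `hospital_admission_date`
#' (the first arrival of the spell). Dates are at day granularity; a stay
#' is the half-open interval [arrival, departure), so a patient is present
#' at the midnight of day t when arrival <= t < departure.
#'
#' @param df A data frame with the columns above (dates as `Date` or
#'   ISO-8601 strings).
#' @return A validated `ward_stays` data frame.
#' @export
ward_stays <- function(df) {
  req <- c("patient_id", "ward", "admission_type", "arrival_date",
           "departure_date", "hospital_admission_date")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("ward_stays: missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(
    patient_id = as.character(df$patient_id),
    ward = as.character(df$ward),
    admission_type = as.character(df$admission_type),
    arrival_date = as.Date(df$arrival_date),
    departure_date = as.Date(df$departure_date),
    hospital_admission_date = as.Date(df$hospital_admission_date),
    stringsAsFactors = FALSE
  )
  bad_type <- !out$admission_type %in% c("emergency", "elective")
  if (any(bad_type))
    stop("ward_stays: admission_type must be 'emergency' or 'elective' (rows ",
         paste(utils::head(which(bad_type), 5L), collapse = ", "), ")")
  bad <- !is.na(out$departure_date) & out$departure_date < out$arrival_date
  if (any(bad))
    stop("ward_stays: departure before arrival (rows ",
         paste(utils::head(which(bad), 5L), collapse = ", "), ")")
  class(out) <- c("ward_stays", "data.frame")
  out
}

#' Read ward-stay records from CSV
#'
#' Reads the package's ward-stay dialect: header with columns `patient_id`,
#' `ward`, `admission_type`, `arrival_date`, `departure_date` (ISO-8601,
#' empty = still resident) and `hospital_admission_date`. A column-name
#' mapping can adapt other extracts. Rows violating the stay invariants
#' (departure before arrival, unparseable dates) are rejected and counted
#' rather than aborting the read.
#'
#' @param path CSV file path.
#' @param dialect Optional named character vector mapping required names to
#'   the file's column names, e.g. `c(patient_id = "PatId")`.
#' @return A `ward_stays` data frame; attribute `rejected` holds the number
#'   of rejected rows and attribute `rejected_rows` their row numbers.
#' @export
read_ward_stays <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("read_ward_stays: no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  req <- c("patient_id", "ward", "admission_type", "arrival_date",
           "departure_date", "hospital_admission_date")
  for (col in req) {
    src <- if (!is.null(dialect) && col %in% names(dialect)) dialect[[col]] else col
    if (!src %in% names(raw))
      stop("read_ward_stays: required column '", src, "' not found in ", path)
    raw[[col]] <- raw[[src]]
  }
  parse_date <- function(x) as.Date(ifelse(x == "", NA, x), format = "%Y-%m-%d")
  arr <- parse_date(raw$arrival_date)
  dep <- parse_date(raw$departure_date)
  had <- parse_date(raw$hospital_admission_date)
  bad <- is.na(arr) | is.na(had) |
    (raw$departure_date != "" & is.na(dep)) |
    (!is.na(dep) & dep < arr) |
    !raw$admission_type %in% c("emergency", "elective")
  if (any(bad))
    message(sum(bad), " ward-stay row(s) rejected: ",
            paste(utils::head(which(bad), 10L), collapse = ", "))
  out <- ward_stays(data.frame(
    patient_id = raw$patient_id[!bad], ward = raw$ward[!bad],
    admission_type = raw$admission_type[!bad],
    arrival_date = arr[!bad], departure_date = dep[!bad],
    hospital_admission_date = had[!bad], stringsAsFactors = FALSE))
  attr(out, "rejected") <- sum(bad)
  attr(out, "rejected_rows") <- which(bad)
  out
}

#' Write ward-stay records to CSV
#' @param stays A `ward_stays` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ward_stays <- function(stays, path) {
  df <- as.data.frame(stays)
  for (col in c("arrival_date", "departure_date", "hospital_admission_date"))
    df[[col]] <- ifelse(is.na(df[[col]]), "", format(df[[col]], "%Y-%m-%d"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Ward length-of-stay in midnights
#'
#' The number of midnights a closed stay spans: departure - arrival in
#' days. A same-day stay has 0 midnights.
#'
#' @param stays A `ward_stays` data frame (all stays must be closed).
#' @return Integer vector of midnight counts, one per stay.
#' @export
wlos_midnights <- function(stays) {
  if (any(is.na(stays$departure_date)))
    stop("wlos_midnights: open stay (no departure date); ",
         "elapsed time for residents belongs in the system snapshot")
  as.integer(stays$departure_date - stays$arrival_date)
}

# Spell-level same-day exclusion: identify patients whose entire hospital
# spell is admitted and discharged on the same calendar day. Returns a
# logical vector over stays (TRUE = stay belongs to an excluded spell).
same_day_spell <- function(stays) {
  key <- paste(stays$patient_id, stays$hospital_admission_date)
  open <- tapply(is.na(stays$departure_date), key, any)
  last <- tapply(as.integer(stays$departure_date), key, function(x)
    if (all(is.na(x))) NA_integer_ else max(x, na.rm = TRUE))
  had <- tapply(as.integer(stays$hospital_admission_date), key, `[`, 1L)
  excl <- !open & !is.na(last) & last == had
  unname(excl[key])
}

#' Midnight bed census from ward-stay records
#'
#' Counts, for every (ward, day, admission type), the patients present at
#' that midnight: arrival <= t < departure, with open stays counted
#' through the end of the range. Patients whose entire hospital spell is
#' admitted and discharged on the same calendar day are excluded (the
#' exclusion is applied at spell level so that intra-day transfer segments
#' of multi-day spells are kept).
#'
#' @param stays A `ward_stays` data frame.
#' @param from,to First and last day of the census range (`Date`); default
#'   to the range spanned by the records.
#' @return A `census_trajectory`: list with `counts` (integer array ward x
#'   day x type), `dates`, `wards`.
#' @export
derive_census <- function(stays, from = NULL, to = NULL) {
  stopifnot(nrow(stays) >= 0)
  if (is.null(from)) from <- min(stays$arrival_date)
  if (is.null(to)) {
    cand <- c(stays$arrival_date,
              stays$departure_date[!is.na(stays$departure_date)] - 1L)
    to <- max(cand)
  }
  from <- as.Date(from); to <- as.Date(to)
  if (to < from) stop("derive_census: empty date range")
  keep <- !same_day_spell(stays)
  s <- stays[keep, , drop = FALSE]
  dates <- seq(from, to, by = "day")
  wards <- sort(unique(stays$ward))
  types <- c("emergency", "elective")
  counts <- array(0L, dim = c(length(wards), length(dates), 2L),
                  dimnames = list(wards, NULL, types))
  if (nrow(s)) {
    a <- as.integer(s$arrival_date) - as.integer(from)          # day index
    d <- ifelse(is.na(s$departure_date),
                length(dates),
                as.integer(s$departure_date) - as.integer(from))
    lo <- pmax(a, 0L)
    hi <- pmin(d - 1L, length(dates) - 1L)
    len <- pmax(hi - lo + 1L, 0L)
    if (any(len > 0L)) {
      i <- rep.int(seq_along(len), len)
      day <- sequence(len) - 1L + lo[i]
      w <- match(s$ward, wards)[i]
      ty <- match(s$admission_type, types)[i]
      lin <- w + (day) * length(wards) +
        (ty - 1L) * length(wards) * length(dates)
      tab <- tabulate(lin, nbins = length(counts))
      counts <- counts + array(as.integer(tab), dim = dim(counts),
                               dimnames = dimnames(counts))
    }
  }
  structure(list(counts = counts, dates = dates, wards = wards),
            class = "census_trajectory")
}

#' Restrict a census trajectory to a date window
#' @param census A `census_trajectory`.
#' @param from,to Window bounds (`Date`), inclusive.
#' @return A `census_trajectory` over the window.
#' @export
window_census <- function(census, from = NULL, to = NULL) {
  if (is.null(from)) from <- census$dates[1L]
  if (is.null(to)) to <- census$dates[length(census$dates)]
  keep <- census$dates >= as.Date(from) & census$dates <= as.Date(to)
  if (!any(keep)) stop("window_census: empty window")
  structure(list(counts = census$counts[, keep, , drop = FALSE],
                 dates = census$dates[keep], wards = census$wards),
            class = "census_trajectory")
}

# Ward totals (types summed): matrix ward x day.
census_totals <- function(census) {
  counts <- census$counts
  m <- counts[, , 1L, drop = FALSE] + counts[, , 2L, drop = FALSE]
  matrix(m, nrow = dim(counts)[1L], ncol = dim(counts)[2L],
         dimnames = list(census$wards, NULL))
}

#' @export
print.census_trajectory <- function(x, ...) {
  cat(sprintf("midnight census: %d ward(s), %d day(s) (%s to %s)\n",
              length(x$wards), length(x$dates),
              format(x$dates[1L]), format(x$dates[length(x$dates)])))
  tot <- census_totals(x)
  cat("mean occupancy by ward:\n")
  print(round(rowMeans(tot), 2))
  invisible(x)
}

#' @export
as.data.frame.census_trajectory <- function(x, ...) {
  grid <- expand.grid(ward = x$wards, date = x$dates,
                      admission_type = c("emergency", "elective"),
                      stringsAsFactors = FALSE)
  grid$count <- as.integer(x$counts)
  grid
}

#' Write a census trajectory as long-format CSV
#' @param census A `census_trajectory`.
#' @param path Output path; columns ward, date, admission_type, count.
#' @return `path`, invisibly.
#' @export
write_census <- function(census, path) {
  utils::write.csv(as.data.frame(census), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
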