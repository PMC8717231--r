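# Internal helpers: classed error conditions and calendar arithmetic.

ex_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "exmort_error"), call = call))
}

ex_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "exmort_warning")))
}

is_leap_year <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

days_in_year <- function(year) {
  365L + as.integer(is_leap_year(year))
}

days_in_month <- function(year, month) {
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  d <- base[month]
  d[month == 2L & is_leap_year(year)] <- 29L
  d
}

#' First day (Monday) of an ISO-8601 week
#'
#' ISO week 1 of a year is the week containing January 4th; weeks start on
#' Monday. Vectorised over both arguments.
#'
#' @param iso_year ISO week-based year.
#' @param iso_week ISO week number (1--53).
#' @return `Date` vector of the Mondays starting each requested week.
#' @keywords internal
iso_week_start <- function(iso_year, iso_week) {
  jan4 <- as.Date(sprintf("%d-01-04", iso_year))
  # as.POSIXlt wday: 0 = Sunday; convert to ISO weekday 1 = Monday ... 7 = Sunday
  wday <- as.POSIXlt(jan4)$wday
  iso_wday <- ifelse(wday == 0, 7L, wday)
  jan4 - (iso_wday - 1L) + 7L * (iso_week - 1L)
}

# Guess the field separator of a delimited text file among comma/semicolon/tab.
detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- vapply(c(",", ";", "\t"), function(d) {
    length(gregexpr(d, header, fixed = TRUE)[[1L]][
      gregexpr(d, header, fixed = TRUE)[[1L]] > 0])
  }, integer(1))
  if (all(counts == 0)) return(",")
  c(",", ";", "\t")[which.max(counts)]
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) {
    ex_stop(sprintf("file not found: %s", path), "exmort_io_error")
  }
  utils::read.table(path, header = TRUE, sep = detect_delimiter(path),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
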