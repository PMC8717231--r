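# Reading, validating and writing mortality panels and covariate tables,
# and disaggregating weekly (STMF-style) death series to calendar months.

#' Construct and validate a monthly mortality panel
#'
#' A monthly panel holds one record per (unit, year, month) with the
#' all-cause death count for that calendar month and the annual population
#' exposure (person-years) of the unit-year. Monthly exposure is taken
#' downstream as one twelfth of the annual figure.
#'
#' @param data data.frame with columns `unit_id`, `year`, `month`,
#'   `deaths`, `exposure`.
#' @return The validated data.frame with class `monthly_panel`.
#' @export
monthly_panel <- function(data) {
  required <- c("unit_id", "year", "month", "deaths", "exposure")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    ex_stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
            "exmort_schema_error")
  }
  data <- as.data.frame(data)[required]
  data$unit_id <- as.character(data$unit_id)
  data$year <- as.integer(data$year)
  data$month <- as.integer(data$month)
  data$deaths <- as.numeric(data$deaths)
  data$exposure <- as.numeric(data$exposure)

  if (anyNA(data)) {
    ex_stop("panel contains missing values", "exmort_value_error")
  }
  if (any(data$month < 1L | data$month > 12L)) {
    ex_stop("month must be in 1..12", "exmort_value_error")
  }
  if (any(data$deaths < 0)) {
    ex_stop("deaths must be non-negative", "exmort_value_error")
  }
  if (any(data$exposure <= 0)) {
    ex_stop("exposure must be positive", "exmort_value_error")
  }
  key <- paste(data$unit_id, data$year, data$month, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- data[duplicated(key), , drop = FALSE][1L, ]
    ex_stop(sprintf("duplicate record for (%s, %d, %d)",
                    dup$unit_id, dup$year, dup$month),
            "exmort_integrity_error")
  }
  # exposure constant within a unit-year
  uy <- paste(data$unit_id, data$year, sep = "\r")
  n_expo <- tapply(data$exposure, uy, function(x) length(unique(x)))
  if (any(n_expo > 1L)) {
    ex_stop("exposure must be constant within a unit-year", "exmort_value_error")
  }
  data <- data[order(data$unit_id, data$year, data$month), , drop = FALSE]
  rownames(data) <- NULL
  class(data) <- c("monthly_panel", "data.frame")
  data
}

#' Read a monthly mortality panel from delimited text
#'
#' The delimiter is auto-detected among comma, semicolon and tab. Column
#' names can be remapped through `schema` when the file uses different
#' headers.
#'
#' @param path Path to a UTF-8 delimited text file.
#' @param schema Named character vector mapping panel fields to file column
#'   names, e.g. `c(deaths = "D", exposure = "pop")`. Fields not listed are
#'   assumed to carry their canonical names (`unit_id`, `year`, `month`,
#'   `deaths`, `exposure`).
#' @return A [monthly_panel].
#' @export
read_monthly_panel <- function(path, schema = NULL) {
  raw <- read_delim_auto(path)
  required <- c("unit_id", "year", "month", "deaths", "exposure")
  colmap <- stats::setNames(required, required)
  if (!is.null(schema)) colmap[names(schema)] <- schema
  missing_cols <- setdiff(colmap, names(raw))
  if (length(missing_cols) > 0) {
    ex_stop(sprintf("file %s lacks column(s): %s", path,
                    paste(missing_cols, collapse = ", ")),
            "exmort_schema_error")
  }
  out <- stats::setNames(raw[colmap], required)
  monthly_panel(out)
}

#' Write a monthly panel as CSV
#'
#' Emits the canonical long format (`unit_id, year, month, deaths,
#' exposure`) that [read_monthly_panel()] reads back unchanged.
#'
#' @param panel A [monthly_panel].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_monthly_panel <- function(panel, path) {
  stopifnot(inherits(panel, "monthly_panel"))
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct and validate a weekly death series
#'
#' Weekly all-cause death counts keyed by ISO-8601 week (the format of the
#' Short-Term Mortality Fluctuations series). Each ISO week covers exactly
#' seven calendar dates starting on a Monday.
#'
#' @param data data.frame with columns `unit_id`, `iso_year`, `iso_week`,
#'   `deaths`.
#' @return Validated data.frame with class `weekly_series`.
#' @export
weekly_series <- function(data) {
  required <- c("unit_id", "iso_year", "iso_week", "deaths")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    ex_stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
            "exmort_schema_error")
  }
  data <- as.data.frame(data)[required]
  data$unit_id <- as.character(data$unit_id)
  data$iso_year <- as.integer(data$iso_year)
  data$iso_week <- as.integer(data$iso_week)
  data$deaths <- as.numeric(data$deaths)
  if (anyNA(data)) ex_stop("weekly series contains missing values", "exmort_value_error")
  if (any(data$iso_week < 1L | data$iso_week > 53L)) {
    ex_stop("iso_week must be in 1..53", "exmort_value_error")
  }
  if (any(data$deaths < 0)) ex_stop("deaths must be non-negative", "exmort_value_error")
  key <- paste(data$unit_id, data$iso_year, data$iso_week, sep = "\r")
  if (anyDuplicated(key)) {
    ex_stop("duplicate (unit, iso_year, iso_week) rows", "exmort_integrity_error")
  }
  class(data) <- c("weekly_series", "data.frame")
  data
}

#' Read a weekly (STMF-style) death series from delimited text
#'
#' @param path Path to a delimited file with columns `unit_id`, `iso_year`,
#'   `iso_week`, `deaths`.
#' @return A [weekly_series].
#' @export
read_weekly_series <- function(path) {
  weekly_series(read_delim_auto(path))
}

#' Disaggregate weekly death counts to calendar months
#'
#' Each ISO week's deaths are spread uniformly over its seven days and
#' allocated to calendar months by day count: a week straddling a month
#' boundary contributes `deaths * days_in_month / 7` to each side. Monthly
#' counts are therefore fractional in general; totals over any fully
#' covered span are conserved exactly.
#'
#' @param series A [weekly_series] (or data.frame coercible to one).
#' @param target_years Integer vector of calendar years to return. Every
#'   day of every month of these years must be covered by an input week.
#' @return data.frame `unit_id, year, month, deaths` with one row per
#'   unit-month of `target_years`.
#' @export
weekly_to_monthly <- function(series, target_years) {
  if (!inherits(series, "weekly_series")) series <- weekly_series(series)
  target_years <- as.integer(target_years)

  out <- lapply(split(series, series$unit_id), function(su) {
    starts <- iso_week_start(su$iso_year, su$iso_week)
    # one row per (week, day): daily deaths = weekly deaths / 7
    dates <- rep(starts, each = 7L) + 0:6
    daily <- rep(su$deaths / 7, each = 7L)
    yr <- as.integer(format(dates, "%Y"))
    mo <- as.integer(format(dates, "%m"))
    keep <- yr %in% target_years
    yr <- yr[keep]; mo <- mo[keep]; daily <- daily[keep]; dates <- dates[keep]

    # coverage: every day of every target month must appear exactly once
    for (y in target_years) {
      for (m in 1:12) {
        n_cov <- sum(yr == y & mo == m)
        if (n_cov != days_in_month(y, m)) {
          ex_stop(sprintf("unit %s: month %d-%02d not fully covered by input weeks (%d of %d days)",
                          su$unit_id[1L], y, m, n_cov, days_in_month(y, m)),
                  "exmort_coverage_error")
        }
      }
    }
    agg <- stats::aggregate(daily, by = list(year = yr, month = mo), FUN = sum)
    data.frame(unit_id = su$unit_id[1L], year = agg$year, month = agg$month,
               deaths = agg$x, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$unit_id, out$year, out$month), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read per-unit reported epidemic burden covariates
#'
#' One row per unit with cumulative reported cases and deaths per 100,000.
#'
#' @param path Delimited file with columns `unit_id`, `cases_per_100k`,
#'   `deaths_per_100k`.
#' @return Validated data.frame keyed by `unit_id`.
#' @export
read_covariates <- function(path) {
  raw <- read_delim_auto(path)
  required <- c("unit_id", "cases_per_100k", "deaths_per_100k")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    ex_stop(sprintf("file %s lacks column(s): %s", path,
                    paste(missing_cols, collapse = ", ")),
            "exmort_schema_error")
  }
  out <- raw[required]
  out$unit_id <- as.character(out$unit_id)
  out$cases_per_100k <- as.numeric(out$cases_per_100k)
  out$deaths_per_100k <- as.numeric(out$deaths_per_100k)
  if (anyNA(out)) ex_stop("covariates contain missing values", "exmort_value_error")
  if (any(out$cases_per_100k < 0) || any(out$deaths_per_100k < 0)) {
    ex_stop("covariate rates must be non-negative", "exmort_value_error")
  }
  if (anyDuplicated(out$unit_id)) {
    ex_stop("duplicate unit_id rows in covariates", "exmort_integrity_error")
  }
  out
}

#' Join covariates against a set of analysis units
#'
#' Restricts the covariate table to the units present in `unit_ids`,
#' warning about units on either side that do not match.
#'
#' @param covariates Table from [read_covariates()].
#' @param unit_ids Character vector of unit identifiers to keep.
#' @return The covariate rows for the intersection, in `unit_ids` order.
#' @export
join_covariates <- function(covariates, unit_ids) {
  unmatched <- union(setdiff(unit_ids, covariates$unit_id),
                     setdiff(covariates$unit_id, unit_ids))
  if (length(unmatched) > 0) {
    ex_warn(sprintf("unmatched unit(s) dropped in covariate join: %s",
                    paste(sort(unmatched), collapse = ", ")),
            "exmort_join_warning")
  }
  keep <- intersect(unit_ids, covariates$unit_id)
  out <- covariates[match(keep, covariates$unit_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a spatial adjacency list
#'
#' @param path Delimited file with columns `unit_i`, `unit_j`, `weight`
#'   (one row per directed pair; the list must be symmetric).
#' @return data.frame with the three columns, weights numeric and positive.
#' @export
read_adjacency <- function(path) {
  raw <- read_delim_auto(path)
  required <- c("unit_i", "unit_j", "weight")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    ex_stop(sprintf("file %s lacks column(s): %s", path,
                    paste(missing_cols, collapse = ", ")),
            "exmort_schema_error")
  }
  out <- raw[required]
  out$unit_i <- as.character(out$unit_i)
  out$unit_j <- as.character(out$unit_j)
  out$weight <- as.numeric(out$weight)
  if (anyNA(out) || any(out$weight < 0)) {
    ex_stop("adjacency weights must be non-negative numbers", "exmort_value_error")
  }
  out
}
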