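# End-to-end orchestration: configuration, unit screening, the full
# read -> rates -> baselines -> excess -> association -> clustering chain,
# and tabular report outputs.

#' Drop units with incomplete panel coverage
#'
#' Units missing any (year, month) cell over the required years are
#' removed with a warning naming them; no imputation is attempted.
#'
#' @param panel A [monthly_panel].
#' @param years Years every retained unit must fully cover.
#' @return The panel restricted to complete units.
#' @export
drop_incomplete_units <- function(panel, years) {
  if (!inherits(panel, "monthly_panel")) panel <- monthly_panel(panel)
  need <- length(years) * 12L
  sub <- panel[panel$year %in% years, ]
  counts <- table(sub$unit_id)
  bad <- union(names(counts)[counts < need],
               setdiff(unique(panel$unit_id), names(counts)))
  if (length(bad) > 0) {
    ex_warn(sprintf("dropping unit(s) with incomplete coverage: %s",
                    paste(sort(bad), collapse = ", ")),
            "exmort_dropped_units_warning")
    panel <- panel[!panel$unit_id %in% bad, ]
    class(panel) <- c("monthly_panel", "data.frame")
  }
  panel
}

#' Assemble a pipeline configuration
#'
#' @param monthly_deaths Path to a monthly panel CSV (`unit_id, year,
#'   month, deaths, exposure`), or `NULL` when starting from weekly data.
#' @param weekly_deaths Path to an STMF-style weekly CSV (`unit_id,
#'   iso_year, iso_week, deaths`); requires `exposures`.
#' @param exposures Path to an annual exposure CSV (`unit_id, year,
#'   exposure`), used only with `weekly_deaths`.
#' @param covariates Optional path to a reported-burden CSV (`unit_id,
#'   cases_per_100k, deaths_per_100k`).
#' @param adjacency Optional path to an adjacency CSV (`unit_i, unit_j,
#'   weight`) enabling the cluster stage.
#' @param ref_years Reference years (default 2015--2019).
#' @param target_year Target year (default 2020).
#' @param methods Baselines to run, subset of `c("A", "B", "lee_carter")`.
#' @param periods Periods to report.
#' @param bootstrap Bootstrap replicates for confidence intervals (0 = none).
#' @param seed Integer seed for all stochastic stages.
#' @param out_dir Output directory for the report bundle.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(monthly_deaths = NULL, weekly_deaths = NULL,
                            exposures = NULL, covariates = NULL,
                            adjacency = NULL, ref_years = 2015:2019,
                            target_year = 2020,
                            methods = c("A", "B"),
                            periods = c("year", "Q2", "Q3", "Q4"),
                            bootstrap = 0, seed = 1, out_dir = ".") {
  if (is.null(monthly_deaths) && is.null(weekly_deaths)) {
    ex_stop("either monthly_deaths or weekly_deaths must be given",
            "exmort_config_error")
  }
  if (!is.null(weekly_deaths) && is.null(exposures)) {
    ex_stop("weekly_deaths requires an exposures table", "exmort_config_error")
  }
  if (max(ref_years) >= target_year) {
    ex_stop("reference years must precede the target year", "exmort_config_error")
  }
  structure(list(monthly_deaths = monthly_deaths,
                 weekly_deaths = weekly_deaths, exposures = exposures,
                 covariates = covariates, adjacency = adjacency,
                 ref_years = as.integer(ref_years),
                 target_year = as.integer(target_year),
                 methods = match.arg(methods, c("A", "B", "lee_carter"),
                                     several.ok = TRUE),
                 periods = periods, bootstrap = bootstrap,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @param ... Overrides applied on top of the file's values.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path, ...) {
  x <- yaml::read_yaml(path)
  dots <- list(...)
  x[names(dots)] <- dots
  # a two-element ref_years entry is read as an inclusive [first, last] range
  if (!is.null(x$ref_years) && length(x$ref_years) == 2L &&
      x$ref_years[2] - x$ref_years[1] > 1) {
    x$ref_years <- x$ref_years[1]:x$ref_years[2]
  }
  do.call(pipeline_config, x)
}

log_line <- function(lines, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message(msg)
  c(lines, msg)
}

#' Run the full excess-mortality pipeline
#'
#' Reads the inputs, converts weekly series to monthly counts when needed,
#' screens out incompletely covered units, computes month-length-adjusted
#' rates, fits the requested baselines, estimates annual and quarterly
#' excess with optional bootstrap intervals, ranks units, relates excess
#' to reported burden, and (given an adjacency list) runs the local
#' Moran's I cluster stage. All tables are written as CSV into
#' `config$out_dir` along with a `run_manifest.txt` log recording the
#' package version, seed and record counts. Outputs are identical across
#' reruns with the same configuration and seed.
#'
#' @param config A [pipeline_config].
#' @return Invisibly, a list with the in-memory results (`estimates`,
#'   `rankings`, `associations`, `local_moran`, `quarter_scatter`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  log <- log_line(log, "exmort %s | seed %d | ref %d-%d | target %d",
                  as.character(utils::packageVersion("exmort")), config$seed,
                  min(config$ref_years), max(config$ref_years),
                  config$target_year)

  panel <- if (!is.null(config$monthly_deaths)) {
    read_monthly_panel(config$monthly_deaths)
  } else {
    weekly <- read_weekly_series(config$weekly_deaths)
    monthly <- weekly_to_monthly(weekly, c(config$ref_years, config$target_year))
    expo <- read_delim_auto(config$exposures)
    if (!all(c("unit_id", "year", "exposure") %in% names(expo))) {
      ex_stop("exposures file needs columns unit_id, year, exposure",
              "exmort_schema_error")
    }
    merged <- merge(monthly, expo[c("unit_id", "year", "exposure")],
                    by = c("unit_id", "year"))
    monthly_panel(merged)
  }
  log <- log_line(log, "stage read: %d records, %d unit(s)",
                  nrow(panel), length(unique(panel$unit_id)))

  dropped <- character()
  withCallingHandlers(
    panel <- drop_incomplete_units(panel,
                                   c(config$ref_years, config$target_year)),
    exmort_dropped_units_warning = function(w) {
      dropped <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  if (length(dropped) > 0) log <- log_line(log, "stage screen: %s", dropped)

  estimates <- excess_table(panel, config$ref_years, config$target_year,
                            methods = config$methods, periods = config$periods,
                            B = config$bootstrap, seed = config$seed)
  utils::write.csv(estimates, file.path(config$out_dir, "excess_estimates.csv"),
                   row.names = FALSE, quote = FALSE)
  log <- log_line(log, "stage excess: %d estimate rows", nrow(estimates))

  rankings <- NULL
  if ("year" %in% config$periods) {
    rankings <- do.call(rbind, lapply(config$methods, function(m) {
      rank_units(estimates[estimates$period == "year" &
                             estimates$method == m, ])
    }))
    utils::write.csv(rankings, file.path(config$out_dir, "rankings.csv"),
                     row.names = FALSE, quote = FALSE)
    log <- log_line(log, "stage rank: %d rows", nrow(rankings))
  }

  assoc_method <- if ("B" %in% config$methods) "B" else config$methods[1L]
  associations <- NULL
  local_moran <- NULL
  if (!is.null(config$covariates)) {
    covs <- read_covariates(config$covariates)
    joined <- character()
    withCallingHandlers(
      covs <- join_covariates(covs, sort(unique(panel$unit_id))),
      exmort_join_warning = function(w) {
        joined <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      })
    if (length(joined) > 0) log <- log_line(log, "stage associate: %s", joined)
    exc <- estimates[estimates$method == assoc_method,
                     c("unit_id", "period", "excess_abs")]
    exc <- exc[exc$unit_id %in% covs$unit_id, ]
    assoc_cases <- quarterly_association_profile(
      exc, data.frame(unit_id = covs$unit_id, value = covs$cases_per_100k))
    assoc_deaths <- quarterly_association_profile(
      exc, data.frame(unit_id = covs$unit_id, value = covs$deaths_per_100k))
    associations <- rbind(cbind(covariate = "cases_per_100k", assoc_cases),
                          cbind(covariate = "deaths_per_100k", assoc_deaths))
    utils::write.csv(associations,
                     file.path(config$out_dir, "associations.csv"),
                     row.names = FALSE, quote = FALSE)
    log <- log_line(log, "stage associate: %d rows (method %s)",
                    nrow(associations), assoc_method)
  }

  if (!is.null(config$adjacency)) {
    adj <- read_adjacency(config$adjacency)
    exc_year <- estimates[estimates$period == "year" &
                            estimates$method == assoc_method, ]
    w <- spatial_weights(adj, units = exc_year$unit_id)
    local_moran <- local_morans_i(exc_year$excess_abs, w, seed = config$seed)
    utils::write.csv(local_moran, file.path(config$out_dir, "local_moran.csv"),
                     row.names = FALSE, quote = FALSE)
    log <- log_line(log, "stage cluster: global Moran's I = %.4f",
                    attr(local_moran, "global_i"))
  }

  quarter_scatter <- NULL
  if (all(c("Q2", "Q4") %in% config$periods)) {
    quarter_scatter <- make_quarter_scatter_table(
      estimates[estimates$method == assoc_method, ])
    utils::write.csv(quarter_scatter,
                     file.path(config$out_dir, "quarter_scatter.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  writeLines(log, file.path(config$out_dir, "run_manifest.txt"))
  invisible(list(estimates = estimates, rankings = rankings,
                 associations = associations, local_moran = local_moran,
                 quarter_scatter = quarter_scatter))
}

#' Second-quarter vs fourth-quarter excess per unit
#'
#' One row per unit with its Q2 (first-wave) and Q4 (second-wave) excess
#' death rates, the table behind the wave-timing scatter that separates
#' units hit in spring from units hit in autumn-winter. Units missing
#' either quarter are excluded with a warning.
#'
#' @param estimates `excess_estimate` rows for a single method containing
#'   Q2 and Q4 periods.
#' @return data.frame `unit_id, excess_Q2, excess_Q4`.
#' @export
make_quarter_scatter_table <- function(estimates) {
  if (length(unique(estimates$method)) > 1L) {
    ex_stop("estimates must come from a single method", "exmort_contract_error")
  }
  q2 <- estimates[estimates$period == "Q2", c("unit_id", "excess_abs")]
  q4 <- estimates[estimates$period == "Q4", c("unit_id", "excess_abs")]
  names(q2)[2L] <- "excess_Q2"
  names(q4)[2L] <- "excess_Q4"
  out <- merge(q2, q4, by = "unit_id")
  missing <- setdiff(union(q2$unit_id, q4$unit_id), out$unit_id)
  if (length(missing) > 0) {
    ex_warn(sprintf("unit(s) missing a quarter, excluded: %s",
                    paste(sort(missing), collapse = ", ")),
            "exmort_missing_quarter_warning")
  }
  out[order(out$unit_id), , drop = FALSE]
}
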