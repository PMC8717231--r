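# Month-length-adjusted crude death rates and the three baseline
# (expected-mortality) models: seasonal averages (A), seasonal averages with
# a linear secular trend (B), and a Lee-Carter factor model used as a
# sensitivity baseline.

#' Compute month-length-adjusted crude death rates
#'
#' Monthly death counts are first rescaled to the average month length so
#' that calendar-month duration does not distort monthly comparisons:
#' `D* = D * (days_in_year / 12) / days_in_month`, leap-aware. The
#' annualised crude death rate is then `CDR = D* / (P / 12) * 100000`, with
#' `P` the annual person-years exposure of the unit-year.
#'
#' @param panel A [monthly_panel].
#' @return data.frame of class `rate_series` with columns `unit_id`,
#'   `year`, `month`, `adjusted_deaths`, `cdr` (deaths per 100,000 per
#'   year) and `exposure` carried through for downstream resampling.
#' @export
compute_cdr <- function(panel) {
  if (!inherits(panel, "monthly_panel")) panel <- monthly_panel(panel)
  if (any(panel$exposure <= 0)) {
    ex_stop("exposure must be positive", "exmort_value_error")
  }
  adj <- panel$deaths * (days_in_year(panel$year) / 12) /
    days_in_month(panel$year, panel$month)
  cdr <- adj / (panel$exposure / 12) * 1e5
  out <- data.frame(unit_id = panel$unit_id, year = panel$year,
                    month = panel$month, adjusted_deaths = adj, cdr = cdr,
                    exposure = panel$exposure, stringsAsFactors = FALSE)
  class(out) <- c("rate_series", "data.frame")
  out
}

# Reshape one unit's rates into a complete years x 12 CDR matrix.
rate_matrix <- function(rates, unit, years) {
  sub <- rates[rates$unit_id == unit & rates$year %in% years, , drop = FALSE]
  Y <- matrix(NA_real_, nrow = length(years), ncol = 12,
              dimnames = list(as.character(years), as.character(1:12)))
  Y[cbind(match(sub$year, years), sub$month)] <- sub$cdr
  if (anyNA(Y)) {
    ex_stop(sprintf("unit %s: incomplete rate panel over years %d-%d",
                    unit, min(years), max(years)),
            "exmort_coverage_error")
  }
  Y
}

single_unit <- function(rates) {
  u <- unique(rates$unit_id)
  if (length(u) != 1L) {
    ex_stop("expected rates for exactly one unit; use fit_baselines() for panels",
            "exmort_contract_error")
  }
  u
}

new_baseline_model <- function(unit_id, method, alphas, beta, residuals,
                               ref_years, lc_params = NULL) {
  structure(list(unit_id = unit_id, method = method,
                 alphas = stats::setNames(alphas, month.abb),
                 beta = beta, residuals = residuals,
                 ref_years = ref_years, lc_params = lc_params),
            class = "baseline_model")
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("Baseline model (method %s) for unit %s\n", x$method, x$unit_id))
  cat(sprintf("  reference years: %d-%d\n", min(x$ref_years), max(x$ref_years)))
  at_end <- predict_expected(x, max(x$ref_years))
  cat(sprintf("  fitted monthly rates at %d (per 100,000/yr): %s ...\n",
              max(x$ref_years),
              paste(sprintf("%.1f", at_end[1:4]), collapse = ", ")))
  if (x$method == "B") cat(sprintf("  trend slope: %+.3f per year\n", x$beta))
  if (x$method == "lee_carter") {
    cat(sprintf("  k drift: %+.4f per year\n", x$lc_params$drift))
  }
  invisible(x)
}

# Closed-form OLS for the balanced month-dummy + common-year-slope design.
# With a complete years x 12 matrix the slope is
#   beta = sum_t (t - tbar) * rowsum_t / (12 * sum_t (t - tbar)^2)
# and alpha_m = colmean_m - beta * tbar; identical to lm(cdr ~ 0 + month + year).
fit_b_closed_form <- function(Y, years) {
  tc <- years - mean(years)
  beta <- sum(tc * rowSums(Y)) / (12 * sum(tc^2))
  alphas <- colMeans(Y) - beta * mean(years)
  list(alphas = alphas, beta = beta)
}

#' Fit the seasonal-average baseline (Method A)
#'
#' Expected mortality for each calendar month is the average of the
#' month-length-adjusted CDR in the same month over the reference years; a
#' monthly fixed-effects model with no trend term.
#'
#' @param rates A `rate_series` (one unit) from [compute_cdr()].
#' @param ref_years Integer vector of reference years (all 12 months of
#'   each must be present).
#' @return A `baseline_model` with `method = "A"`.
#' @export
fit_method_a <- function(rates, ref_years) {
  unit <- single_unit(rates)
  ref_years <- sort(as.integer(ref_years))
  Y <- rate_matrix(rates, unit, ref_years)
  alphas <- colMeans(Y)
  resid <- sweep(Y, 2, alphas)
  new_baseline_model(unit, "A", alphas, 0, resid, ref_years)
}

#' Fit the trend-adjusted seasonal baseline (Method B)
#'
#' Ordinary least squares on `CDR(t, m) = alpha_m + beta * t + eps`, i.e.
#' monthly fixed effects plus a common linear secular trend in the year.
#' With a complete balanced reference panel the fit has a closed form,
#' which is what this function computes; it is numerically identical to
#' `lm(cdr ~ 0 + factor(month) + year)`. Predictions are invariant to any
#' affine recoding of the year covariate.
#'
#' @inheritParams fit_method_a
#' @return A `baseline_model` with `method = "B"`; `alphas` are the month
#'   intercepts at year 0 and `beta` the slope per calendar year.
#' @export
fit_method_b <- function(rates, ref_years) {
  unit <- single_unit(rates)
  ref_years <- sort(as.integer(ref_years))
  if (length(ref_years) < 2L) {
    ex_stop("method B needs at least 2 reference years to identify a trend",
            "exmort_rank_error")
  }
  Y <- rate_matrix(rates, unit, ref_years)
  fit <- fit_b_closed_form(Y, ref_years)
  fitted <- outer(fit$beta * ref_years, rep(1, 12)) +
    matrix(fit$alphas, nrow(Y), 12, byrow = TRUE)
  new_baseline_model(unit, "B", fit$alphas, fit$beta, Y - fitted, ref_years)
}

#' Fit a Lee-Carter baseline on monthly rates
#'
#' Month-as-stratum adaptation of the Lee-Carter log-rate factor model:
#' `log CDR(t, m) = a_m + b_m * k_t + error`. `a_m` is the time-mean of the
#' log rates; `(b_m, k_t)` is the leading singular component of the
#' centred log-rate matrix under the identification constraints
#' `sum(b) = 1`, `sum(k) = 0`. The time index is carried to the target
#' year by a random walk with drift, `drift = (k_N - k_1) / (N - 1)`.
#'
#' @inheritParams fit_method_a
#' @return A `baseline_model` with `method = "lee_carter"` and an
#'   `lc_params` list holding `a`, `b`, `k`, `drift` and the fitted years.
#' @export
fit_lee_carter <- function(rates, ref_years) {
  unit <- single_unit(rates)
  ref_years <- sort(as.integer(ref_years))
  if (length(ref_years) < 3L) {
    ex_stop("Lee-Carter needs at least 3 reference years", "exmort_rank_error")
  }
  Y <- rate_matrix(rates, unit, ref_years)
  if (any(Y <= 0)) {
    ex_stop("Lee-Carter requires strictly positive reference CDRs (log scale)",
            "exmort_domain_error")
  }
  L <- log(Y)
  a <- colMeans(L)
  C <- sweep(L, 2, a)
  sv <- svd(C)
  b_raw <- sv$v[, 1L]
  k_raw <- sv$u[, 1L] * sv$d[1L]
  # identification: sum(b) = 1 (also fixes sign), sum(k) = 0
  s <- sum(b_raw)
  if (abs(s) < sqrt(.Machine$double.eps)) s <- 1  # degenerate flat component
  b <- b_raw / s
  k <- k_raw * s
  a <- a + mean(k) * b
  k <- k - mean(k)
  drift <- (k[length(k)] - k[1L]) / (length(k) - 1L)
  fitted <- exp(matrix(a, nrow(Y), 12, byrow = TRUE) + outer(k, b))
  lc <- list(a = stats::setNames(a, month.abb), b = stats::setNames(b, month.abb),
             k = stats::setNames(k, as.character(ref_years)), drift = drift,
             years = ref_years)
  new_baseline_model(unit, "lee_carter", fitted_lc_alphas(lc, ref_years), 0,
                     Y - fitted, ref_years, lc_params = lc)
}

# For the common surface, store the last-reference-year fitted rates as the
# model's nominal monthly effects; predictions always go through lc_params.
fitted_lc_alphas <- function(lc, ref_years) {
  exp(lc$a + lc$b * lc$k[length(lc$k)])
}

#' Predict expected monthly death rates for a target year
#'
#' Method A predicts its monthly averages regardless of year; Method B
#' extrapolates `alpha_m + beta * year`; the Lee-Carter baseline
#' extrapolates its time index by drift and returns
#' `exp(a_m + b_m * k_target)`.
#'
#' @param model A fitted `baseline_model`.
#' @param target_year Calendar year to predict (typically one past the
#'   reference range).
#' @return Named numeric vector of 12 expected CDRs (per 100,000/year).
#' @export
predict_expected <- function(model, target_year) {
  if (!inherits(model, "baseline_model")) {
    ex_stop("model must be a fitted baseline_model", "exmort_state_error")
  }
  target_year <- as.integer(target_year)
  switch(model$method,
    A = model$alphas,
    B = model$alphas + model$beta * target_year,
    lee_carter = {
      lc <- model$lc_params
      k_target <- lc$k[length(lc$k)] +
        lc$drift * (target_year - lc$years[length(lc$years)])
      stats::setNames(exp(lc$a + lc$b * k_target), month.abb)
    },
    ex_stop(sprintf("unknown method '%s'", model$method), "exmort_state_error")
  )
}

#' Fit one baseline method for every unit of a rate panel
#'
#' @param rates A `rate_series` possibly holding many units.
#' @param ref_years Reference years common to all units.
#' @param method `"A"`, `"B"` or `"lee_carter"`.
#' @return Named list of `baseline_model` objects, one per unit.
#' @export
fit_baselines <- function(rates, ref_years, method = c("A", "B", "lee_carter")) {
  method <- match.arg(method)
  fitter <- switch(method, A = fit_method_a, B = fit_method_b,
                   lee_carter = fit_lee_carter)
  units <- sort(unique(rates$unit_id))
  stats::setNames(
    lapply(units, function(u) fitter(rates[rates$unit_id == u, ], ref_years)),
    units)
}

#' Serialise a baseline model to JSON
#'
#' Writes the documented layout (`unit_id`, `method`, `alphas`, `beta`,
#' `ref_years`, optional `lc_params`) so fitted models can be stored and
#' re-used without refitting. Residuals are included so bootstrap
#' resampling can be resumed from a stored model.
#'
#' @param model A `baseline_model`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "baseline_model"))
  payload <- list(
    unit_id = model$unit_id, method = model$method,
    alphas = unname(model$alphas), beta = model$beta,
    ref_years = model$ref_years,
    residuals = unname(as.matrix(model$residuals)))
  if (!is.null(model$lc_params)) {
    payload$lc_params <- list(a = unname(model$lc_params$a),
                              b = unname(model$lc_params$b),
                              k = unname(model$lc_params$k),
                              drift = model$lc_params$drift,
                              years = model$lc_params$years)
  }
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Restore a baseline model from its JSON serialisation
#'
#' @param json JSON string or path to a JSON file from [model_to_json()].
#' @return A `baseline_model`.
#' @export
model_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- readLines(json)
  x <- jsonlite::fromJSON(paste(json, collapse = ""))
  resid <- x$residuals
  if (!is.matrix(resid)) {
    resid <- matrix(resid, nrow = length(x$ref_years), ncol = 12)
  }
  dimnames(resid) <- list(as.character(x$ref_years), as.character(1:12))
  lc <- NULL
  if (!is.null(x$lc_params)) {
    lc <- list(a = stats::setNames(x$lc_params$a, month.abb),
               b = stats::setNames(x$lc_params$b, month.abb),
               k = stats::setNames(x$lc_params$k, as.character(x$lc_params$years)),
               drift = x$lc_params$drift, years = as.integer(x$lc_params$years))
  }
  new_baseline_model(x$unit_id, x$method, x$alphas, x$beta, resid,
                     as.integer(x$ref_years), lc_params = lc)
}
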