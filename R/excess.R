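# Absolute and relative excess death rates for the target year, annual and
# quarterly, with residual-bootstrap confidence intervals and cross-unit
# rankings.

#' Months making up a reporting period
#'
#' The annual period covers January--December. The second quarter is
#' defined as the four months March--June (the first pandemic wave), the
#' third as July--September and the fourth as October--December.
#'
#' @param period One of `"year"`, `"Q2"`, `"Q3"`, `"Q4"` (or `"JanFeb"`,
#'   the pre-pandemic remainder used in aggregation identities).
#' @return Integer vector of calendar months.
#' @export
period_months <- function(period) {
  switch(period,
    year = 1:12,
    JanFeb = 1:2,
    Q2 = 3:6,
    Q3 = 7:9,
    Q4 = 10:12,
    ex_stop(sprintf("unknown period '%s'", period), "exmort_value_error"))
}

new_excess_estimate <- function(unit_id, period, method, observed, expected,
                                ci_low = NA_real_, ci_high = NA_real_) {
  out <- data.frame(unit_id = unit_id, period = period, method = method,
                    observed_rate = observed, expected_rate = expected,
                    excess_abs = observed - expected,
                    excess_rel = 100 * (observed - expected) / expected,
                    ci_low = ci_low, ci_high = ci_high,
                    stringsAsFactors = FALSE)
  class(out) <- c("excess_estimate", "data.frame")
  out
}

#' Excess death rate of one unit for one period
#'
#' Observed and expected rates are unweighted means of the annualised
#' monthly CDRs over the period's months (months are already normalised to
#' equal length by the month-length adjustment). Absolute excess is
#' observed minus expected, per 100,000 per year; relative excess is the
#' ratio of absolute excess to the expected rate, in percent.
#'
#' @param observed A `rate_series` covering the target year for one unit.
#' @param model A fitted `baseline_model` for the same unit.
#' @param period Period tag, see [period_months()].
#' @param target_year Target year; defaults to the single year present in
#'   `observed`.
#' @return One-row data.frame of class `excess_estimate`.
#' @export
compute_excess <- function(observed, model, period = "year",
                           target_year = NULL) {
  unit <- single_unit(observed)
  if (!inherits(model, "baseline_model")) {
    ex_stop("model must be a fitted baseline_model", "exmort_state_error")
  }
  if (unit != model$unit_id) {
    ex_stop(sprintf("rates are for unit %s but model for unit %s",
                    unit, model$unit_id), "exmort_contract_error")
  }
  if (is.null(target_year)) {
    ty <- unique(observed$year)
    if (length(ty) != 1L) {
      ex_stop("observed rates span several years; pass target_year",
              "exmort_contract_error")
    }
    target_year <- ty
  }
  months <- period_months(period)
  sub <- observed[observed$year == target_year & observed$month %in% months, ]
  if (nrow(sub) != length(months)) {
    ex_stop(sprintf("unit %s: period %s of %d not fully observed",
                    unit, period, target_year), "exmort_coverage_error")
  }
  observed_rate <- mean(sub$cdr)
  expected_rate <- mean(predict_expected(model, target_year)[months])
  new_excess_estimate(unit, period, model$method, observed_rate, expected_rate)
}

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Bootstrap confidence interval for an excess death rate
#'
#' Residual bootstrap of the baseline fit: reference-period residuals
#' `eps(t, m)` are resampled with replacement (pooled within the unit),
#' added back to the fitted reference surface, and the baseline refit on
#' each pseudo panel. The observed target-year monthly rates are
#' perturbed with independently resampled residuals on each replicate, so
#' the interval reflects both baseline-estimation and observed-period
#' sampling variability. Percentile 2.5/97.5 bounds are returned and are
#' deterministic given `seed`.
#'
#' @param panel A [monthly_panel] for one unit covering the reference
#'   years and the target year.
#' @param method `"A"`, `"B"` or `"lee_carter"`.
#' @param target_year Year whose excess is being estimated.
#' @param period Period tag, see [period_months()].
#' @param B Number of bootstrap replicates (at least 100).
#' @param seed Integer seed controlling all resampling.
#' @param ref_years Reference years; defaults to all panel years before
#'   `target_year`.
#' @return List with `ci_low`, `ci_high`, the point `excess_abs`, and the
#'   vector of replicate excesses (`replicates`).
#' @export
bootstrap_ci <- function(panel, method = c("A", "B", "lee_carter"),
                         target_year, period = "year", B = 1000, seed = 1,
                         ref_years = NULL) {
  method <- match.arg(method)
  if (B < 100) ex_stop("B must be at least 100", "exmort_value_error")
  if (!inherits(panel, "monthly_panel")) panel <- monthly_panel(panel)
  rates <- compute_cdr(panel)
  unit <- single_unit(rates)
  if (is.null(ref_years)) {
    ref_years <- sort(unique(rates$year[rates$year < target_year]))
  }
  model <- switch(method, A = fit_method_a(rates, ref_years),
                  B = fit_method_b(rates, ref_years),
                  lee_carter = fit_lee_carter(rates, ref_years))
  est <- compute_excess(rates[rates$year == target_year, ], model, period,
                        target_year)
  months <- period_months(period)
  eps <- as.vector(model$residuals)
  # degrees-of-freedom correction: raw residuals understate the error
  # variance by (n - p)/n, so rescale before resampling (p = free
  # parameters: 12 monthly effects, +1 slope for the trend model, and
  # 12 + 11 + (N - 1) for the constrained factor model)
  n_par <- switch(method, A = 12, B = 13,
                  lee_carter = 22 + length(ref_years))
  eps <- eps * sqrt(length(eps) / max(length(eps) - n_par, 1))

  if (all(abs(eps - mean(eps)) < .Machine$double.eps^0.5)) {
    ex_warn("zero-variance residuals: confidence interval collapses to the point estimate",
            "exmort_degenerate_ci_warning")
    return(list(ci_low = est$excess_abs, ci_high = est$excess_abs,
                excess_abs = est$excess_abs,
                replicates = rep(est$excess_abs, B)))
  }

  N <- length(ref_years)
  fitted <- rate_matrix(rates, unit, ref_years) - as.matrix(model$residuals)

  reps <- with_seed(seed, {
    # resampled residual matrices, one column per replicate (column-major:
    # entry (t, m) of replicate b sits at row (m-1)*N + t)
    S <- matrix(sample(eps, N * 12 * B, replace = TRUE), ncol = B)
    obs_noise <- colMeans(matrix(sample(eps, length(months) * B, replace = TRUE),
                                 nrow = length(months)))
    rows_M <- as.vector(outer(seq_len(N), months, function(t, m) (m - 1L) * N + t))
    mean_F_M <- mean(fitted[, months])

    expected_b <- switch(method,
      A = mean_F_M + colMeans(S[rows_M, , drop = FALSE]),
      B = {
        tc <- ref_years - mean(ref_years)
        wvec <- rep(tc, times = 12) / (12 * sum(tc^2))
        beta_b <- sum(wvec * as.vector(fitted)) + as.vector(crossprod(wvec, S))
        mean_F_M + colMeans(S[rows_M, , drop = FALSE]) +
          beta_b * (target_year - mean(ref_years))
      },
      lee_carter = {
        vapply(seq_len(B), function(b) {
          Ystar <- fitted + matrix(S[, b], nrow = N)
          if (any(Ystar <= 0)) Ystar[Ystar <= 0] <- min(fitted) * 1e-3
          lc_fit <- refit_lc_expected(Ystar, ref_years, target_year)
          mean(lc_fit[months])
        }, numeric(1))
      })
    (est$observed_rate + obs_noise) - expected_b
  })

  ci <- unname(stats::quantile(reps, c(0.025, 0.975)))
  list(ci_low = ci[1L], ci_high = ci[2L], excess_abs = est$excess_abs,
       replicates = reps)
}

# minimal Lee-Carter refit returning the 12 expected target-year CDRs
refit_lc_expected <- function(Y, years, target_year) {
  L <- log(Y)
  a <- colMeans(L)
  sv <- svd(sweep(L, 2, a))
  s <- sum(sv$v[, 1L])
  if (abs(s) < sqrt(.Machine$double.eps)) s <- 1
  b <- sv$v[, 1L] / s
  k <- sv$u[, 1L] * sv$d[1L] * s
  a <- a + mean(k) * b
  k <- k - mean(k)
  drift <- (k[length(k)] - k[1L]) / (length(k) - 1L)
  k_target <- k[length(k)] + drift * (target_year - years[length(years)])
  exp(a + b * k_target)
}

#' Excess estimates for every unit, method and period of a panel
#'
#' Convenience driver: computes rates, fits the requested baselines per
#' unit, and returns one `excess_estimate` row per unit x method x period,
#' with bootstrap confidence intervals when `B > 0`.
#'
#' @param panel A [monthly_panel] covering reference years and target year.
#' @param ref_years Reference years used for every unit.
#' @param target_year Year whose excess is estimated.
#' @param methods Subset of `c("A", "B", "lee_carter")`.
#' @param periods Subset of `c("year", "Q2", "Q3", "Q4")`.
#' @param B Bootstrap replicates per estimate; `0` skips intervals.
#' @param seed Integer seed for the bootstrap.
#' @return data.frame of class `excess_estimate`.
#' @export
excess_table <- function(panel, ref_years, target_year,
                         methods = c("A", "B"),
                         periods = c("year", "Q2", "Q3", "Q4"),
                         B = 0, seed = 1) {
  if (!inherits(panel, "monthly_panel")) panel <- monthly_panel(panel)
  rates <- compute_cdr(panel)
  units <- sort(unique(panel$unit_id))
  rows <- list()
  for (m in methods) {
    models <- fit_baselines(rates, ref_years, m)
    for (u in units) {
      obs <- rates[rates$unit_id == u & rates$year == target_year, ]
      for (p in periods) {
        est <- compute_excess(obs, models[[u]], p, target_year)
        if (B > 0) {
          # per-estimate seed derived deterministically from unit/method/period
          sub_seed <- (seed + 1000L * match(m, c("A", "B", "lee_carter")) +
                         100L * match(p, c("year", "Q2", "Q3", "Q4", "JanFeb")) +
                         match(u, units)) %% .Machine$integer.max
          ci <- bootstrap_ci(panel[panel$unit_id == u, ], m, target_year, p,
                             B = B, seed = sub_seed, ref_years = ref_years)
          est$ci_low <- ci$ci_low
          est$ci_high <- ci$ci_high
        }
        rows[[length(rows) + 1L]] <- est
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("excess_estimate", "data.frame")
  out
}

#' Rank units by excess death rate
#'
#' Orders a set of per-unit estimates for a common period and method in
#' descending order of absolute excess; ties broken lexicographically by
#' unit id.
#'
#' @param estimates `excess_estimate` rows, one per unit, sharing a single
#'   period and method.
#' @return The estimates with a `rank` column, sorted by rank.
#' @export
rank_units <- function(estimates) {
  if (length(unique(estimates$period)) != 1L ||
      length(unique(estimates$method)) != 1L) {
    ex_stop("rank_units needs estimates for a single period and method",
            "exmort_contract_error")
  }
  if (anyDuplicated(estimates$unit_id)) {
    ex_stop("rank_units needs one estimate per unit", "exmort_contract_error")
  }
  ord <- order(-estimates$excess_abs, estimates$unit_id)
  out <- estimates[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
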