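# Synthetic multi-unit mortality panels with known ground truth. The
# generator emulates the statistical structure of national-statistics
# inputs: month-specific seasonality, a linear secular trend in the crude
# death rate, Poisson count noise at realistic exposures, target-year
# epidemic waves with unit-specific timing, and reported case/death series
# with configurable under-ascertainment.

#' Define a synthetic mortality scenario
#'
#' All rate quantities are annualised crude death rates per 100,000. The
#' monthly expected CDR of unit u in year t, month m is
#' `base_level_u * seasonal_m + trend_u * (t - first ref year)` plus, in
#' the target year only, the unit's epidemic wave intensity for that
#' month. Expected death counts follow by converting the CDR back through
#' the month-length adjustment, and realised counts are Poisson (or exact
#' when `noise = "none"`).
#'
#' @param n_units Number of geographic units.
#' @param ref_years Reference (pre-pandemic) years, default 2015--2019.
#' @param target_year Pandemic year, default 2020.
#' @param base_level Per-unit annual CDR level (recycled if scalar).
#' @param seasonal_amplitudes 12 multiplicative month factors with mean 1.
#' @param trend_per_year Per-unit additive CDR change per calendar year.
#' @param waves Per-unit list of waves; each wave is a list with `start`,
#'   `peak`, `end` (months; `end` may exceed 12 for waves running into the
#'   next year) and `amplitude` (per 100,000/year at the peak). Intensity
#'   ramps linearly from 0 at `start` to `amplitude` at `peak` and back to
#'   0 at `end`.
#' @param exposure Per-unit annual person-years (recycled if scalar).
#' @param reporting List with `case_ascertainment` (per-unit fraction in
#'   (0, 1], or the string `"inverse_burden"` for ascertainment decaying
#'   with true burden), `death_reporting` (per-unit fraction),
#'   `covid_death_share` (true epidemic deaths as a share of true excess,
#'   default 0.7), `ifr` (infection fatality ratio linking epidemic deaths
#'   to infections, default 0.01), `inverse_power` and
#'   `max_ascertainment` for the inverse-burden mode.
#' @param noise `"poisson"` or `"none"`.
#' @param seed Integer seed; all randomness flows from it.
#' @param unit_ids Optional unit identifiers (default `"U01"`, ...).
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(n_units = 5,
                            ref_years = 2015:2019,
                            target_year = 2020,
                            base_level = 1200,
                            seasonal_amplitudes = default_seasonality(),
                            trend_per_year = 0,
                            waves = NULL,
                            exposure = 1e6,
                            reporting = list(),
                            noise = c("poisson", "none"),
                            seed = 20200101,
                            unit_ids = NULL) {
  noise <- match.arg(noise)
  n_units <- as.integer(n_units)
  if (n_units < 1L) ex_stop("n_units must be >= 1", "exmort_config_error")
  if (length(seasonal_amplitudes) != 12L) {
    ex_stop("seasonal_amplitudes must have 12 entries", "exmort_config_error")
  }
  if (abs(mean(seasonal_amplitudes) - 1) > 1e-8) {
    ex_stop("seasonal_amplitudes must average to 1", "exmort_config_error")
  }
  if (any(seasonal_amplitudes < 0)) {
    ex_stop("seasonal_amplitudes must be non-negative", "exmort_config_error")
  }
  if (max(ref_years) >= target_year) {
    ex_stop("reference years must precede the target year", "exmort_config_error")
  }
  if (is.null(unit_ids)) unit_ids <- sprintf("U%02d", seq_len(n_units))
  rep_defaults <- list(case_ascertainment = 1, death_reporting = 1,
                       covid_death_share = 0.7, ifr = 0.01,
                       inverse_power = 2, max_ascertainment = 0.9)
  rep_defaults[names(reporting)] <- reporting
  reporting <- rep_defaults
  if (is.numeric(reporting$case_ascertainment) &&
      (any(reporting$case_ascertainment <= 0) ||
       any(reporting$case_ascertainment > 1))) {
    ex_stop("case_ascertainment fractions must be in (0, 1]", "exmort_config_error")
  }
  if (any(reporting$death_reporting <= 0) || any(reporting$death_reporting > 1)) {
    ex_stop("death_reporting fractions must be in (0, 1]", "exmort_config_error")
  }
  if (is.null(waves)) waves <- rep(list(list()), n_units)
  if (length(waves) != n_units) {
    ex_stop("waves must have one entry (possibly empty) per unit", "exmort_config_error")
  }
  structure(list(
    n_units = n_units, unit_ids = unit_ids,
    ref_years = as.integer(sort(ref_years)), target_year = as.integer(target_year),
    base_level = rep_len(base_level, n_units),
    seasonal_amplitudes = seasonal_amplitudes,
    trend_per_year = rep_len(trend_per_year, n_units),
    waves = waves,
    exposure = rep_len(exposure, n_units),
    reporting = reporting, noise = noise, seed = as.integer(seed)),
    class = "scenario_config")
}

#' Default winter-peaked seasonality profile
#'
#' Cosine with a 20% January elevation over the annual mean; the 12
#' factors average to 1 exactly. The amplitude is deliberately strong so
#' that at regional exposures (around one million person-years) the
#' seasonal signal dominates Poisson noise and fitted monthly effects
#' track the truth sharply; it is not calibrated to any national series.
#'
#' @param amplitude Relative winter elevation (default 0.2).
#' @return Numeric vector of 12 month factors.
#' @export
default_seasonality <- function(amplitude = 0.2) {
  1 + amplitude * cos(2 * pi * (0:11) / 12)
}

# piecewise-linear wave intensity over months 1..12 (per 100,000/year)
wave_intensity <- function(waves, months = 1:12) {
  out <- numeric(length(months))
  for (w in waves) {
    if (length(w) == 0) next
    ramp_up <- if (w$peak > w$start) (months - w$start) / (w$peak - w$start) else
      as.numeric(months == w$peak)
    ramp_down <- if (w$end > w$peak) (w$end - months) / (w$end - w$peak) else
      as.numeric(months == w$peak)
    intensity <- w$amplitude * pmin(ramp_up, ramp_down)
    out <- out + pmax(intensity, 0)
  }
  out
}

#' Generate a synthetic monthly panel with its ground truth
#'
#' @param config A [scenario_config].
#' @return List with `panel` (a [monthly_panel] over reference + target
#'   years) and `truth` (class `synthetic_truth`): per-unit true monthly
#'   effects, trend, wave intensities, true annual/quarterly excess, and
#'   true epidemic infections and deaths per 100,000.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  years <- c(config$ref_years, config$target_year)
  t0 <- config$ref_years[1L]
  s <- config$seasonal_amplitudes

  grid <- expand.grid(month = 1:12, year = years,
                      unit = seq_len(config$n_units))
  u <- grid$unit
  wave_mat <- t(vapply(config$waves, wave_intensity, numeric(12)))
  cdr_expected <- config$base_level[u] * s[grid$month] +
    config$trend_per_year[u] * (grid$year - t0) +
    ifelse(grid$year == config$target_year, wave_mat[cbind(u, grid$month)], 0)
  if (any(cdr_expected < 0)) {
    ex_stop("negative expected death rate; weaken the trend or waves",
            "exmort_config_error")
  }
  # invert the month-length adjustment: expected raw deaths giving this CDR
  lambda <- cdr_expected / 1e5 * config$exposure[u] *
    days_in_month(grid$year, grid$month) / days_in_year(grid$year)
  deaths <- if (config$noise == "poisson") {
    with_seed(config$seed, stats::rpois(length(lambda), lambda))
  } else {
    lambda
  }
  panel <- monthly_panel(data.frame(
    unit_id = config$unit_ids[u], year = grid$year, month = grid$month,
    deaths = deaths, exposure = config$exposure[u],
    stringsAsFactors = FALSE))

  per_period <- function(p) {
    rowMeans(wave_mat[, period_months(p), drop = FALSE])
  }
  excess_year <- rowMeans(wave_mat)
  covid_deaths <- config$reporting$covid_death_share * excess_year
  truth <- structure(list(
    unit_ids = config$unit_ids,
    alphas = outer(config$base_level, s),
    trend = config$trend_per_year,
    wave_intensity = wave_mat,
    excess = data.frame(unit_id = config$unit_ids,
                        year = excess_year,
                        Q2 = per_period("Q2"), Q3 = per_period("Q3"),
                        Q4 = per_period("Q4"), stringsAsFactors = FALSE),
    covid_deaths_per_100k = covid_deaths,
    infections_per_100k = covid_deaths / config$reporting$ifr),
    class = "synthetic_truth")
  list(panel = panel, truth = truth)
}

#' Generate reported epidemic covariates from a scenario's ground truth
#'
#' Reported cases are true infections scaled by the per-unit case
#' ascertainment fraction; reported deaths are true epidemic deaths scaled
#' by the death-reporting fraction. With
#' `case_ascertainment = "inverse_burden"`, ascertainment decays as
#' `burden^(-inverse_power)` (rescaled so its maximum is
#' `max_ascertainment`), emulating units whose testing capacity is lowest
#' exactly where the epidemic hit hardest; this inverts the ecological
#' correlation between reported cases and true excess.
#'
#' @param config The [scenario_config] the truth came from.
#' @param truth The `synthetic_truth` from [generate_panel()].
#' @return data.frame `unit_id, cases_per_100k, deaths_per_100k`.
#' @export
generate_reported_covid <- function(config, truth) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(truth, "synthetic_truth"))
  if (!identical(config$unit_ids, truth$unit_ids)) {
    ex_stop("config and truth describe different unit sets", "exmort_contract_error")
  }
  asc <- config$reporting$case_ascertainment
  if (identical(asc, "inverse_burden")) {
    burden <- truth$excess$year
    if (any(burden <= 0)) {
      ex_stop("inverse-burden ascertainment needs positive true excess everywhere",
              "exmort_config_error")
    }
    raw <- burden^(-config$reporting$inverse_power)
    asc <- raw / max(raw) * config$reporting$max_ascertainment
  } else {
    asc <- rep_len(asc, config$n_units)
  }
  data.frame(unit_id = config$unit_ids,
             cases_per_100k = truth$infections_per_100k * asc,
             deaths_per_100k = truth$covid_deaths_per_100k *
               rep_len(config$reporting$death_reporting, config$n_units),
             stringsAsFactors = FALSE)
}

#' A multi-wave scenario shaped like the 2020 Russian epidemic
#'
#' Declining secular mortality trend; two "metropolitan" units hit by a
#' spring (Q2) wave; a broad autumn-winter (Q4) wave in every unit, with
#' the largest amplitudes in an "eastern" block of units; about half the
#' units also carry a moderate summer (Q3) wave. In aggregate the injected
#' excess is ordered Q4 > Q3 > Q2, and the negative trend makes the
#' trend-adjusted baseline exceed the simple seasonal average.
#'
#' @param n_units Number of regions (default 20; at least 4).
#' @param seed Seed used both to draw unit parameters and by the panel
#'   generator.
#' @param trend_per_year Common secular CDR trend (default -15 per year).
#' @param reporting Optional overrides of the reporting block.
#' @return A [scenario_config]. Units 1--2 are the metropolitan block;
#'   the last third of units forms the high-Q4 "eastern" block.
#' @export
scenario_russia_like <- function(n_units = 20, seed = 20200101,
                                 trend_per_year = -15, reporting = list()) {
  n_units <- as.integer(n_units)
  if (n_units < 4L) ex_stop("need at least 4 units", "exmort_config_error")
  params <- with_seed(seed, {
    list(base = stats::runif(n_units, 1050, 1400),
         q4_amp = stats::runif(n_units, 450, 700),
         q3_pick = sample(3:n_units, size = max(1L, (n_units - 2L) %/% 2L)),
         expo = round(stats::runif(n_units, 8e5, 3e6)))
  })
  eastern <- seq.int(max(3L, n_units - n_units %/% 3 + 1L), n_units)
  params$q4_amp[eastern] <- params$q4_amp[eastern] + 250
  params$expo[1:2] <- c(5e6, 4e6)  # metropolitan units

  waves <- lapply(seq_len(n_units), function(i) {
    w <- list(list(start = 9, peak = 11, end = 14,
                   amplitude = params$q4_amp[i]))
    if (i %in% params$q3_pick) {
      w <- c(w, list(list(start = 6, peak = 8, end = 10, amplitude = 280)))
    }
    if (i <= 2L) {
      w <- c(w, list(list(start = 3, peak = 5, end = 7, amplitude = 420)))
    }
    w
  })
  scenario_config(n_units = n_units, base_level = params$base,
                  trend_per_year = trend_per_year, waves = waves,
                  exposure = params$expo, reporting = reporting,
                  noise = "poisson", seed = seed,
                  unit_ids = sprintf("R%02d", seq_len(n_units)))
}

#' Read or write a scenario configuration as YAML
#'
#' @param config A [scenario_config].
#' @param path File path.
#' @return `scenario_to_yaml` returns `path` invisibly;
#'   `scenario_from_yaml` returns a [scenario_config].
#' @export
scenario_to_yaml <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname scenario_to_yaml
#' @export
scenario_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  scenario_config(n_units = x$n_units, ref_years = x$ref_years,
                  target_year = x$target_year, base_level = x$base_level,
                  seasonal_amplitudes = x$seasonal_amplitudes,
                  trend_per_year = x$trend_per_year, waves = x$waves,
                  exposure = x$exposure, reporting = x$reporting,
                  noise = x$noise, seed = x$seed, unit_ids = x$unit_ids)
}

#' Write a truth object's per-unit summary as CSV
#'
#' @param truth A `synthetic_truth`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  out <- truth$excess
  names(out) <- c("unit_id", "true_excess_year", "true_excess_Q2",
                  "true_excess_Q3", "true_excess_Q4")
  out$true_trend <- truth$trend
  out$true_covid_deaths_per_100k <- truth$covid_deaths_per_100k
  out$true_infections_per_100k <- truth$infections_per_100k
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
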