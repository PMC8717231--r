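test_that("crude death rates carry the month-length adjustment", {
  panel <- monthly_panel(data.frame(
    unit_id = "RU", year = c(2019, 2019, 2020),
    month = c(1, 4, 2), deaths = c(31, 0, 100),
    exposure = c(1.2e6, 1.2e6, 1.2e6)))
  rates <- compute_cdr(panel)

  # one death per day over a 31-day month scales to the average month length
  jan <- rates[rates$year == 2019 & rates$month == 1, ]
  expect_equal(jan$adjusted_deaths, 365 / 12)
  expect_equal(jan$cdr, (365 / 12) / (1.2e6 / 12) * 1e5)

  # zero deaths give a zero rate
  expect_equal(rates$cdr[rates$month == 4], 0)

  # leap-year February: 100 deaths in 29 days of a 366-day year
  feb <- rates[rates$year == 2020 & rates$month == 2, ]
  expect_equal(feb$adjusted_deaths, 100 * (366 / 12) / 29, tolerance = 1e-12)

  # adjusted deaths sum to annual deaths exactly on a uniform-daily-rate year
  daily <- 3
  uniform <- monthly_panel(data.frame(
    unit_id = "U", year = 2019, month = 1:12,
    deaths = daily * exmort:::days_in_month(2019, 1:12), exposure = 1e6))
  expect_equal(sum(compute_cdr(uniform)$adjusted_deaths), daily * 365)
})

test_that("method A averages months over reference years", {
  rates <- make_linear_rates(beta = 0)
  rates$cdr[rates$month == 1] <- c(90, 100, 110, 95, 105)
  model <- fit_method_a(rates, 2015:2019)
  expect_equal(unname(model$alphas[1]), 100)
  expect_equal(model$beta, 0)
  expect_equal(unname(model$residuals[1, 1]), 90 - 100)
  # per-month residual means vanish
  expect_equal(unname(colMeans(model$residuals)), rep(0, 12))

  # constant panel: every monthly effect equals the constant
  const <- make_linear_rates(alphas = rep(850, 12), beta = 0)
  expect_equal(unname(fit_method_a(const, 2015:2019)$alphas), rep(850, 12))

  # incomplete reference coverage is rejected
  expect_error(fit_method_a(rates[-1, ], 2015:2019),
               class = "exmort_coverage_error")
})

test_that("method B recovers exact linear structure and reduces to A", {
  alphas <- 1000 + 30 * cos(2 * pi * (0:11) / 12)
  rates <- make_linear_rates(alphas = alphas, beta = -12)
  model <- fit_method_b(rates, 2015:2019)
  expect_equal(model$beta, -12, tolerance = 1e-10)
  expect_equal(unname(model$alphas), alphas, tolerance = 1e-10)
  expect_equal(max(abs(model$residuals)), 0, tolerance = 1e-8)

  # prediction contract: alpha_m + beta * y*
  expect_equal(unname(predict_expected(model, 2020)),
               alphas - 12 * 2020, tolerance = 1e-10)

  # trendless data: slope ~ 0 and predictions equal method A's
  flat <- make_linear_rates(beta = 0)
  mb <- fit_method_b(flat, 2015:2019)
  ma <- fit_method_a(flat, 2015:2019)
  expect_equal(mb$beta, 0, tolerance = 1e-10)
  expect_equal(predict_expected(mb, 2020), predict_expected(ma, 2020),
               tolerance = 1e-9)

  expect_error(fit_method_b(make_linear_rates(years = 2019), 2019),
               class = "exmort_rank_error")
})

test_that("method B matches independent least-squares oracles", {
  # brute-force normal equations on the dummy-encoded design, plus lm()
  set.seed(101)
  for (rep in 1:25) {
    years <- 2015:(2016 + sample(1:3, 1))
    rates <- make_linear_rates(years = years,
                               alphas = runif(12, 800, 1200),
                               beta = runif(1, -20, 5))
    rates$cdr <- rates$cdr + rnorm(nrow(rates), 0, 2)
    model <- fit_method_b(rates, years)
    oracle <- oracle_month_year_ols(rates)
    # the uncentered normal equations are ill-conditioned (year ~ 2e3), so
    # the oracle itself only carries ~7 significant digits
    expect_equal(unname(model$alphas), oracle$alphas, tolerance = 1e-6)
    expect_equal(model$beta, oracle$beta, tolerance = 1e-6)
    lmfit <- lm(cdr ~ 0 + factor(month) + year, data = rates)
    expect_equal(model$beta, unname(coef(lmfit)["year"]), tolerance = 1e-6)
  }
})

test_that("method B predictions are invariant to affine year recoding", {
  rates <- make_linear_rates(beta = -12)
  set.seed(7)
  rates$cdr <- rates$cdr + rnorm(nrow(rates), 0, 3)
  model <- fit_method_b(rates, 2015:2019)
  shifted <- rates
  shifted$year <- shifted$year - 2017L
  model_s <- fit_method_b(shifted, (2015:2019) - 2017L)
  expect_equal(predict_expected(model, 2020),
               predict_expected(model_s, 2020 - 2017L), tolerance = 1e-9)
})

test_that("Lee-Carter handles rank-1, constant, and noisy panels", {
  years <- 2013:2019
  # common log-linear decline: log cdr = a_m + c*t
  a_m <- log(1000) + 0.05 * cos(2 * pi * (0:11) / 12)
  cc <- -0.02
  grid <- expand.grid(month = 1:12, year = years)
  rates <- data.frame(unit_id = "X", year = grid$year, month = grid$month,
                      cdr = exp(a_m[grid$month] + cc * grid$year))
  model <- fit_lee_carter(rates, years)
  expect_equal(unname(model$lc_params$b), rep(1 / 12, 12), tolerance = 1e-8)
  kk <- unname(model$lc_params$k)
  expect_equal(diff(kk), rep(diff(kk)[1], length(kk) - 1), tolerance = 1e-8)
  # forecast equals exact log-linear extrapolation
  expect_equal(unname(predict_expected(model, 2021)),
               exp(a_m + cc * 2021), tolerance = 1e-8)

  # constant panel: time index ~ 0, forecast equals the constant
  const <- make_linear_rates(alphas = rep(900, 12), beta = 0)
  mc <- fit_lee_carter(const, 2015:2019)
  expect_equal(unname(predict_expected(mc, 2020)), rep(900, 12),
               tolerance = 1e-8)

  # identification constraints hold on noisy data; components recovered
  set.seed(20200101)
  b_true <- abs(rnorm(12)); b_true <- b_true / sum(b_true)
  k_true <- seq(3, -3, length.out = length(years))
  lcdr <- outer(k_true, b_true) + rep(a_m, each = length(years)) +
    rnorm(12 * length(years), 0, 0.005)
  # as.vector(lcdr) runs year-fastest, so lay the frame out the same way
  noisy <- data.frame(unit_id = "X", year = rep(years, 12),
                      month = rep(1:12, each = length(years)),
                      cdr = exp(as.vector(lcdr)))
  mn <- fit_lee_carter(noisy, years)
  expect_equal(sum(mn$lc_params$b), 1, tolerance = 1e-10)
  expect_equal(sum(mn$lc_params$k), 0, tolerance = 1e-10)
  expect_gt(cor(mn$lc_params$b, b_true), 0.99)
  expect_gt(cor(mn$lc_params$k, k_true), 0.99)

  # zero rates are a domain error on the log scale
  zero <- const; zero$cdr[1] <- 0
  expect_error(fit_lee_carter(zero, 2015:2019), class = "exmort_domain_error")
})

test_that("predictions depend on target year only where they should", {
  rates <- make_linear_rates(beta = -1.5)
  ma <- fit_method_a(rates, 2015:2019)
  expect_identical(predict_expected(ma, 2020), predict_expected(ma, 2030))
  mb <- fit_method_b(rates, 2015:2019)
  expect_equal(predict_expected(mb, 2020) - predict_expected(mb, 2019),
               rep(-1.5, 12), ignore_attr = TRUE, tolerance = 1e-9)
  expect_error(predict_expected(list(), 2020), class = "exmort_state_error")
})

test_that("baseline models survive the JSON round trip", {
  # keep rates positive (log scale in the factor model): level ~1200 at 2017
  rates <- make_linear_rates(alphas = 1200 + 30 * cos(2 * pi * (0:11) / 12) +
                               8 * 2017, beta = -8)
  set.seed(3)
  rates$cdr <- rates$cdr + rnorm(nrow(rates), 0, 2)
  for (fitter in list(fit_method_a, fit_method_b, fit_lee_carter)) {
    model <- fitter(rates, 2015:2019)
    path <- withr::local_tempfile(fileext = ".json")
    model_to_json(model, path)
    restored <- model_from_json(path)
    expect_equal(restored$alphas, model$alphas)
    expect_equal(restored$beta, model$beta)
    expect_equal(as.matrix(restored$residuals), as.matrix(model$residuals),
                 ignore_attr = TRUE)
    expect_equal(predict_expected(restored, 2020),
                 predict_expected(model, 2020))
  }
})
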