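make_excess_fixture <- function(wave = c(start = 3, peak = 6, end = 12,
                                         amplitude = 600),
                                trend = -15, noise = "none", n_units = 1,
                                seed = 20200101) {
  waves <- rep(list(list(as.list(wave))), n_units)
  scenario_config(n_units = n_units, trend_per_year = trend, waves = waves,
                  noise = noise, seed = seed)
}

test_that("excess is observed minus expected, absolutely and relatively", {
  cfg <- make_excess_fixture(trend = 0, wave = c(start = 1, peak = 1,
                                                 end = 1, amplitude = 0))
  sim <- generate_panel(cfg)
  rates <- compute_cdr(sim$panel)
  model <- fit_method_a(rates[rates$year < 2020, ], 2015:2019)
  est <- compute_excess(rates[rates$year == 2020, ], model, "year")
  expect_equal(est$excess_abs, 0, tolerance = 1e-9)
  expect_equal(est$excess_rel, 0, tolerance = 1e-9)

  # the relative measure is the ratio of absolute excess to expected, in %
  est2 <- exmort:::new_excess_estimate("RU", "year", "B", 1441.2, 1200)
  expect_equal(est2$excess_rel, 20.1, tolerance = 1e-9)
  expect_equal(est2$excess_abs, 241.2, tolerance = 1e-9)
})

test_that("annual excess is the month-count-weighted mix of sub-period excesses", {
  cfg <- make_excess_fixture(noise = "poisson")
  sim <- generate_panel(cfg)
  rates <- compute_cdr(sim$panel)
  model <- fit_method_b(rates[rates$year < 2020, ], 2015:2019)
  obs <- rates[rates$year == 2020, ]
  e <- sapply(c("year", "JanFeb", "Q2", "Q3", "Q4"), function(p) {
    compute_excess(obs, model, p)$excess_abs
  })
  expect_equal(e[["year"]],
               (2 * e[["JanFeb"]] + 4 * e[["Q2"]] + 3 * e[["Q3"]] +
                  3 * e[["Q4"]]) / 12,
               tolerance = 1e-10)
})

test_that("relative excess is invariant to common rescaling of deaths and exposure", {
  cfg <- make_excess_fixture(noise = "poisson")
  sim <- generate_panel(cfg)
  scaled <- sim$panel
  scaled$deaths <- scaled$deaths * 3
  scaled$exposure <- scaled$exposure * 3
  scaled <- monthly_panel(scaled)
  rel_of <- function(p) {
    rates <- compute_cdr(p)
    model <- fit_method_b(rates[rates$year < 2020, ], 2015:2019)
    compute_excess(rates[rates$year == 2020, ], model, "year")$excess_rel
  }
  expect_equal(rel_of(scaled), rel_of(sim$panel), tolerance = 1e-10)
})

test_that("bootstrap intervals are deterministic, collapse without noise, and cover", {
  # noiseless: all residuals zero, CI width zero, with a warning
  cfg <- make_excess_fixture(noise = "none")
  sim <- generate_panel(cfg)
  expect_warning(
    ci0 <- bootstrap_ci(sim$panel, "B", 2020, "year", B = 200, seed = 5),
    class = "exmort_degenerate_ci_warning")
  expect_equal(ci0$ci_low, ci0$excess_abs)
  expect_equal(ci0$ci_high, ci0$excess_abs)

  cfg <- make_excess_fixture(noise = "poisson")
  sim <- generate_panel(cfg)
  ci1 <- bootstrap_ci(sim$panel, "B", 2020, "year", B = 300, seed = 11)
  ci2 <- bootstrap_ci(sim$panel, "B", 2020, "year", B = 300, seed = 11)
  expect_identical(ci1$replicates, ci2$replicates)
  expect_lt(ci1$ci_low, ci1$excess_abs)
  expect_gt(ci1$ci_high, ci1$excess_abs)
  expect_error(bootstrap_ci(sim$panel, "B", 2020, "year", B = 50, seed = 1),
               class = "exmort_value_error")
})

test_that("trend-adjusted estimates track truth while plain averages lag it", {
  # trend -15/year over 2015-2019 baseline: the simple seasonal average sits
  # 15 * (2020 - 2017) = 45 above the true 2020 baseline, so its excess is
  # biased low by ~45; the trend-adjusted method stays near the injected truth
  cfg <- make_excess_fixture(noise = "poisson", n_units = 3)
  sim <- generate_panel(cfg)
  truth <- sim$truth$excess$year[1]
  rates <- compute_cdr(sim$panel)
  for (u in cfg$unit_ids) {
    ru <- rates[rates$unit_id == u, ]
    mb <- fit_method_b(ru[ru$year < 2020, ], 2015:2019)
    ma <- fit_method_a(ru[ru$year < 2020, ], 2015:2019)
    eb <- compute_excess(ru[ru$year == 2020, ], mb, "year")
    ea <- compute_excess(ru[ru$year == 2020, ], ma, "year")
    boot <- bootstrap_ci(sim$panel[sim$panel$unit_id == u, ], "B", 2020,
                         "year", B = 300, seed = 77)
    se <- sd(boot$replicates)
    expect_lt(abs(eb$excess_abs - truth), 3 * se)
    expect_lt(ea$excess_abs, eb$excess_abs)  # declining trend understates
    expect_lt(abs((eb$excess_abs - ea$excess_abs) - 45), 3 * se)
  }
})

test_that("units rank by descending excess with lexicographic tie-breaks", {
  est <- exmort:::new_excess_estimate(c("RU", "BG", "NO"), "year", "B",
                                      c(1444, 1389, 1190), c(1200, 1200, 1200))
  ranked <- rank_units(est)
  expect_equal(ranked$unit_id, c("RU", "BG", "NO"))
  expect_equal(ranked$rank, 1:3)

  tied <- exmort:::new_excess_estimate(c("B", "A"), "year", "B",
                                       c(1300, 1300), c(1200, 1200))
  expect_equal(rank_units(tied)$unit_id, c("A", "B"))

  mixed <- est
  mixed$period <- c("year", "Q2", "year")
  expect_error(rank_units(mixed), class = "exmort_contract_error")
})

test_that("strong negative trends reorder units between methods A and B", {
  # two units with the same injected wave; the strongly declining unit is
  # pushed down the method-A ranking because its baseline is overstated
  waves <- list(list(list(start = 3, peak = 6, end = 12, amplitude = 500)),
                list(list(start = 3, peak = 6, end = 12, amplitude = 560)))
  cfg <- scenario_config(n_units = 2, base_level = c(1200, 1200),
                         trend_per_year = c(0, -40), waves = waves,
                         noise = "none")
  sim <- generate_panel(cfg)
  tab <- excess_table(sim$panel, 2015:2019, 2020, methods = c("A", "B"),
                      periods = "year")
  ra <- rank_units(tab[tab$method == "A", ])
  rb <- rank_units(tab[tab$method == "B", ])
  expect_equal(rb$unit_id[1], "U02")  # truth: U02 has the larger wave
  expect_equal(ra$unit_id[1], "U01")  # method A flips the order
})
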