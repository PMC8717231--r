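# Shared in-code fixtures: tiny panels, exact rate series, grid weights,
# and independent oracles used to cross-check the estimators.

# panel with exact additive structure cdr(t, m) = alpha_m + beta * t,
# returned as a rate_series-shaped data.frame for direct fitting
make_linear_rates <- function(unit = "X", years = 2015:2019,
                              alphas = 1000 + 30 * cos(2 * pi * (0:11) / 12),
                              beta = -12) {
  grid <- expand.grid(month = 1:12, year = years)
  data.frame(unit_id = unit, year = grid$year, month = grid$month,
             cdr = alphas[grid$month] + beta * grid$year,
             stringsAsFactors = FALSE)
}

# rook-adjacency spatial weights for an nr x nc grid
make_grid_weights <- function(nr, nc) {
  id <- function(r, c) sprintf("G%02d%02d", r, c)
  edges <- list()
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (c < nc) edges[[length(edges) + 1L]] <- c(id(r, c), id(r, c + 1))
      if (r < nr) edges[[length(edges) + 1L]] <- c(id(r, c), id(r + 1, c))
    }
  }
  e <- do.call(rbind, edges)
  spatial_weights(data.frame(unit_i = e[, 1], unit_j = e[, 2], weight = 1,
                             stringsAsFactors = FALSE))
}

# independent least-squares oracle: explicit dummy design, normal equations
oracle_month_year_ols <- function(rates) {
  X <- cbind(stats::model.matrix(~ 0 + factor(month, levels = 1:12),
                                 data = rates),
             year = rates$year)
  beta_hat <- solve(t(X) %*% X, t(X) %*% rates$cdr)
  list(alphas = unname(beta_hat[1:12]), beta = unname(beta_hat[13]))
}

# independent global Moran's I: brute-force double sum over all pairs,
# classic (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2 form
oracle_global_moran <- function(values, W_rs) {
  z <- values - mean(values)
  n <- length(z)
  S0 <- sum(W_rs)
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- acc + W_rs[i, j] * z[i] * z[j]
    }
  }
  (n / S0) * acc / sum(z^2)
}

# full-coverage weekly series for calendar year `year` (including the
# boundary ISO weeks of adjacent years), all deaths zero unless overridden
make_full_year_weekly <- function(year, unit = "W1") {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  labels <- unique(paste(format(dates, "%G"), format(dates, "%V")))
  parts <- do.call(rbind, strsplit(labels, " "))
  data.frame(unit_id = unit, iso_year = as.integer(parts[, 1]),
             iso_week = as.integer(parts[, 2]), deaths = 0,
             stringsAsFactors = FALSE)
}
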