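# Cross-unit association between excess mortality and reported epidemic
# burden (OLS + Pearson), and Anselin local Moran's I cluster detection
# with conditional-permutation pseudo p-values.

#' Correlate excess mortality with a reported-burden covariate
#'
#' Ordinary least squares of `y` (excess death rate) on `x` (e.g.
#' cumulative reported cases per 100,000) across units, together with the
#' Pearson product-moment correlation and its two-sided p-value from the
#' exact t-transform with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (pairs with missing values
#'   are dropped); at least 3 complete pairs, both with nonzero variance.
#' @return data.frame of class `association_result` with `slope`,
#'   `intercept`, `pearson_r`, `p_value`, `n`.
#' @export
correlate <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) ex_stop("need at least 3 paired units", "exmort_sample_size_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    ex_stop("zero variance in one of the variables", "exmort_degenerate_error")
  }
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y, method = "pearson")
  out <- data.frame(slope = unname(stats::coef(fit)[2L]),
                    intercept = unname(stats::coef(fit)[1L]),
                    pearson_r = unname(ct$estimate),
                    p_value = ct$p.value, n = n)
  class(out) <- c("association_result", "data.frame")
  out
}

#' Per-quarter association between excess and a covariate
#'
#' Applies [correlate()] separately for each period present in the excess
#' table. The covariate is either static per unit (recycled across
#' periods) or carries its own `period` column.
#'
#' @param excess data.frame with `unit_id`, `period`, `excess_abs`.
#' @param covariate data.frame with `unit_id`, `value` and optionally
#'   `period`.
#' @return `association_result` rows, one per period, with a `period`
#'   column.
#' @export
quarterly_association_profile <- function(excess, covariate) {
  periods <- unique(excess$period)
  rows <- lapply(periods, function(p) {
    e <- excess[excess$period == p, c("unit_id", "excess_abs")]
    cv <- if ("period" %in% names(covariate)) {
      covariate[covariate$period == p, c("unit_id", "value")]
    } else {
      covariate[, c("unit_id", "value")]
    }
    m <- merge(e, cv, by = "unit_id")
    cbind(period = p, correlate(m$value, m$excess_abs))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("association_result", "data.frame")
  out
}

#' Build a spatial weights object from an adjacency list
#'
#' @param adjacency data.frame with `unit_i`, `unit_j`, `weight`; must be
#'   symmetric (every pair listed in both directions with equal weight,
#'   or in one direction, in which case it is symmetrised).
#' @param units Optional character vector fixing unit order; defaults to
#'   the sorted units present in the adjacency list.
#' @return Object of class `spatial_weights`: list with `units` and the
#'   raw symmetric `W` matrix (zero diagonal, not yet row-standardised).
#' @export
spatial_weights <- function(adjacency, units = NULL) {
  if (is.null(units)) {
    units <- sort(unique(c(adjacency$unit_i, adjacency$unit_j)))
  }
  n <- length(units)
  W <- matrix(0, n, n, dimnames = list(units, units))
  i <- match(adjacency$unit_i, units)
  j <- match(adjacency$unit_j, units)
  if (anyNA(i) || anyNA(j)) {
    ex_stop("adjacency references units not in the unit list", "exmort_contract_error")
  }
  W[cbind(i, j)] <- adjacency$weight
  # symmetrise one-directional lists; reject contradictory weights
  asym <- W != t(W)
  if (any(asym & W > 0 & t(W) > 0)) {
    ex_stop("adjacency weights are asymmetric", "exmort_value_error")
  }
  W <- pmax(W, t(W))
  diag(W) <- 0
  structure(list(units = units, W = W), class = "spatial_weights")
}

row_standardise <- function(W) {
  rs <- rowSums(W)
  Wrs <- W
  has <- rs > 0
  Wrs[has, ] <- W[has, , drop = FALSE] / rs[has]
  list(W = Wrs, isolated = !has)
}

#' Global Moran's I
#'
#' Computed with the population (n-denominator) variance; under
#' row-standardised weights this equals the mean of the local statistics
#' over non-isolated units.
#'
#' @param values Numeric vector ordered as `weights$units`.
#' @param weights A [spatial_weights] object.
#' @return Scalar global Moran's I.
#' @export
global_morans_i <- function(values, weights) {
  rs <- row_standardise(weights$W)
  keep <- !rs$isolated
  z <- values - mean(values)
  m2 <- sum(z^2) / length(z)
  lag <- as.vector(rs$W %*% z)
  mean(z[keep] * lag[keep]) / m2
}

#' Anselin local Moran's I with conditional permutation inference
#'
#' For unit i, `I_i = (z_i / m2) * sum_j w_ij z_j` with `z` the
#' mean-centred values, `m2` their population variance (n-denominator) and
#' `w` row-standardised weights. Pseudo p-values come from conditional
#' permutation: the value at i is held fixed while its neighbours' values
#' are drawn without replacement from the remaining units; the two-sided
#' pseudo p is `(1 + #{|I_perm| >= |I_obs|}) / (1 + permutations)`.
#' Significant units are classed into cluster quadrants (HH, LL) and
#' spatial outliers (HL, LH) from the signs of `z_i` and its spatial lag.
#'
#' @param values Numeric vector ordered as `weights$units` (nonconstant,
#'   at least 4 units).
#' @param weights A [spatial_weights] object.
#' @param permutations Number of conditional permutations (default 999).
#' @param seed Integer seed making the pseudo p-values reproducible.
#' @param alpha Significance threshold for quadrant assignment.
#' @return data.frame of class `local_moran_result` with `unit_id`,
#'   `local_i`, `pseudo_p`, `quadrant` and an attribute `global_i`.
#'   Isolated units get `NA` statistics and quadrant `"none"`.
#' @export
local_morans_i <- function(values, weights, permutations = 999, seed = 1,
                           alpha = 0.05) {
  stopifnot(inherits(weights, "spatial_weights"))
  n <- length(weights$units)
  if (length(values) != n) {
    ex_stop("values must align with weights$units", "exmort_contract_error")
  }
  if (n < 4L) ex_stop("need at least 4 units", "exmort_sample_size_error")
  if (stats::sd(values) == 0) {
    ex_stop("constant values: local Moran's I undefined", "exmort_degenerate_error")
  }
  rs <- row_standardise(weights$W)
  if (any(rs$isolated)) {
    ex_warn(sprintf("isolated unit(s) without neighbours: %s",
                    paste(weights$units[rs$isolated], collapse = ", ")),
            "exmort_isolated_unit_warning")
  }
  z <- values - mean(values)
  m2 <- sum(z^2) / n
  lag <- as.vector(rs$W %*% z)
  local_i <- z * lag / m2
  local_i[rs$isolated] <- NA_real_

  pseudo_p <- rep(NA_real_, n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      if (rs$isolated[i]) next
      nb <- which(weights$W[i, ] > 0)
      w_nb <- rs$W[i, nb]
      zo <- z[-i]
      m <- length(zo)
      k <- length(nb)
      obs <- abs(local_i[i])
      hits <- 0L
      scale_i <- z[i] / m2
      for (p in seq_len(permutations)) {
        lag_p <- sum(w_nb * zo[sample.int(m, k)])
        if (abs(scale_i * lag_p) >= obs) hits <- hits + 1L
      }
      pseudo_p[i] <- (1 + hits) / (1 + permutations)
    }
  })

  quadrant <- rep("none", n)
  sig <- !is.na(pseudo_p) & pseudo_p < alpha
  quadrant[sig & z > 0 & lag > 0] <- "HH"
  quadrant[sig & z < 0 & lag < 0] <- "LL"
  quadrant[sig & z > 0 & lag < 0] <- "HL"
  quadrant[sig & z < 0 & lag > 0] <- "LH"

  out <- data.frame(unit_id = weights$units, local_i = local_i,
                    pseudo_p = pseudo_p, quadrant = quadrant,
                    stringsAsFactors = FALSE)
  attr(out, "global_i") <- mean(local_i[!rs$isolated])
  class(out) <- c("local_moran_result", "data.frame")
  out
}
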