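# Pearson and partial correlations with exact t-transform p-values, and
# Bayes factors BF01 for the null hypothesis of no (partial) correlation
# under the Zellner-Siow g-prior, evaluated by adaptive quadrature on a
# bounded transformed domain.

#' Pearson correlation with exact p-value
#'
#' @param x,y numeric vectors of equal length n >= 3 with nonzero variance.
#' @return One-row tibble: `r`, `n`, `statistic` (t), `p_value` (two-sided,
#'   from the exact t-transform with n - 2 degrees of freedom).
#' @export
pearson_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("Need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero variance in `x` or `y`.")
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  tibble(r = r, n = n, statistic = tstat,
         p_value = 2 * pt(-abs(tstat), df = n - 2))
}

# log of the Zellner-Siow integrand at mixing parameter g (negative
# exponential in the prior; the printed positive sign diverges)
zs_log_integrand <- function(g, r2, n, p) {
  ((n - p - 1) / 2) * log1p(g) - ((n - 1) / 2) * log1p((1 - r2) * g) -
    1.5 * log(g) - n / (2 * g)
}

# integral of exp(zs_log_integrand) over g in (0, Inf) via g = u / (1 - u),
# rescaled by the peak of the log-integrand for stability
zs_integral <- function(r2, n, p, rel_tol = 1e-10) {
  gg <- exp(seq(log(1e-3), log(1e6), length.out = 200))
  M <- max(zs_log_integrand(gg, r2, n, p))
  f <- function(u) {
    g <- u / (1 - u)
    exp(zs_log_integrand(g, r2, n, p) - M) / (1 - u)^2
  }
  q <- integrate(f, 0, 1, rel.tol = rel_tol, abs.tol = 0,
                 subdivisions = 500L, stop.on.error = FALSE)
  if (q$message != "OK")
    abort(sprintf("Quadrature failed: %s", q$message))
  list(log_value = M + log(q$value), abs_error = q$abs.error)
}

#' Bayes factor BF01 for a Pearson correlation
#'
#' Evidence in favour of the null hypothesis of zero correlation, under the
#' Zellner-Siow g-prior on the regression slope:
#' `BF10 = sqrt(n/2)/Gamma(1/2) * Int_0^Inf (1+g)^{(n-p-1)/2}
#' (1+(1-r^2)g)^{-(n-1)/2} g^{-3/2} exp(-n/(2g)) dg`, with `BF01 = 1/BF10`.
#' The improper integral is mapped to (0, 1) by `g = u/(1-u)` and evaluated
#' by adaptive quadrature at relative tolerance 1e-10.
#'
#' @param r Pearson coefficient, |r| < 1.
#' @param n sample size, n > p_covariates + 2.
#' @param p_covariates number of covariates in the alternative model
#'   (default 1: the slope).
#' @param rel_tol quadrature relative tolerance.
#' @return BF01 (scalar, > 0).
#' @export
bf01_correlation <- function(r, n, p_covariates = 1, rel_tol = 1e-10) {
  if (abs(r) >= 1) abort("`r` must satisfy |r| < 1.")
  if (n <= p_covariates + 2) abort("`n` must exceed p_covariates + 2.")
  zi <- zs_integral(r^2, n, p_covariates, rel_tol)
  log_bf10 <- 0.5 * log(n / 2) - lgamma(0.5) + zi$log_value
  exp(-log_bf10)
}

#' Partial correlation coefficient
#'
#' For a single control variable the recursion
#' `r_xy|z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))` is applied
#' to the three pairwise coefficients. With several control variables the
#' coefficient is computed by correlating the residuals of least-squares
#' projections of `x` and `y` onto `[1, z]` (equivalent to the recursion for
#' one covariate). The p-value uses the exact t-transform with
#' `n - 2 - k` degrees of freedom for `k` control variables.
#'
#' @param x,y numeric vectors.
#' @param z control variables: a vector, matrix or data frame.
#' @return One-row tibble: `r`, `n`, `k`, `statistic`, `p_value`.
#' @export
partial_correlation <- function(x, y, z) {
  z <- as.matrix(as.data.frame(z))
  ok <- stats::complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok, , drop = FALSE]
  n <- length(x); k <- ncol(z)
  if (n < k + 4) abort("Too few complete cases for partial correlation.")
  rx <- resid(lm(x ~ z))
  ry <- resid(lm(y ~ z))
  if (sd(rx) == 0 || sd(ry) == 0)
    abort("Degenerate residuals: a variable is collinear with the controls.")
  r <- cor(rx, ry)
  df <- n - 2 - k
  tstat <- r * sqrt(df / (1 - r^2))
  tibble(r = r, n = n, k = k, statistic = tstat,
         p_value = 2 * pt(-abs(tstat), df = df))
}

#' @rdname partial_correlation
#' @param r_xy,r_xz,r_yz pairwise Pearson coefficients (|r| < 1 for the
#'   control pairs).
#' @return `partial_cor_from_r()` returns the scalar coefficient.
#' @export
partial_cor_from_r <- function(r_xy, r_xz, r_yz) {
  if (abs(r_xz) >= 1 || abs(r_yz) >= 1)
    abort("Control correlations must satisfy |r| < 1.")
  (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
}

#' Bayes factor BF01 for nested regression models
#'
#' Ratio of the two Zellner-Siow marginal-likelihood integrals for nested
#' linear models with coefficients of determination `r2_reduced` (p
#' covariates) and `r2_full` (p' > p covariates), under the same mixing prior
#' on g; `BF01 = 1/BF10` favours the reduced (null) model. With `p' = p` and
#' equal fits the integrals coincide and BF01 = 1.
#'
#' @param r2_full,r2_reduced coefficients of determination, in [0, 1).
#' @param n sample size.
#' @param p,p_prime numbers of covariates in the reduced and full models.
#' @param rel_tol quadrature relative tolerance.
#' @return BF01 (scalar).
#' @export
bf01_partial <- function(r2_full, r2_reduced, n, p = 1, p_prime = 2,
                         rel_tol = 1e-10) {
  if (r2_full < 0 || r2_full >= 1 || r2_reduced < 0 || r2_reduced >= 1)
    abort("Coefficients of determination must lie in [0, 1).")
  num <- zs_integral(r2_full, n, p_prime, rel_tol)
  den <- zs_integral(r2_reduced, n, p, rel_tol)
  exp(den$log_value - num$log_value)
}

#' Bayes factor for one feature given control covariates
#'
#' Compares the regression of `y` on the controls alone against the
#' regression with `x` added, via [bf01_partial()].
#'
#' @inheritParams partial_correlation
#' @return BF01 (scalar).
#' @export
bf01_given_covariates <- function(x, y, z) {
  z <- as.matrix(as.data.frame(z))
  ok <- stats::complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok, , drop = FALSE]
  r2_reduced <- summary(lm(y ~ z))$r.squared
  r2_full <- summary(lm(y ~ x + z))$r.squared
  bf01_partial(r2_full, r2_reduced, n = length(y),
               p = ncol(z), p_prime = ncol(z) + 1)
}

#' Jeffreys evidence label for a Bayes factor
#'
#' Standard Jeffreys bands on BF01: 1-3 anecdotal, 3-10 moderate, 10-30
#' strong, 30-100 very strong, >100 decisive evidence for H0; reciprocal
#' bands below 1 label evidence for H1.
#'
#' @param bf01 Bayes factor(s) favouring the null, > 0.
#' @return Character vector of labels.
#' @export
jeffreys_label <- function(bf01) {
  if (any(bf01 <= 0)) abort("`bf01` must be positive.")
  band <- function(b) {
    if (b >= 1) {
      grade <- if (b > 100) "decisive" else if (b > 30) "very strong"
        else if (b > 10) "strong" else if (b > 3) "moderate" else "anecdotal"
      sprintf("%s evidence for H0", grade)
    } else {
      band_h1 <- 1 / b
      grade <- if (band_h1 > 100) "decisive" else if (band_h1 > 30) "very strong"
        else if (band_h1 > 10) "strong" else if (band_h1 > 3) "moderate" else "anecdotal"
      sprintf("%s evidence for H1", grade)
    }
  }
  vapply(bf01, band, character(1))
}

#' Empirical conditional probability between cohort features
#'
#' Probability that `event_col` exceeds its threshold among the patients
#' whose `condition_col` exceeds its threshold. Thresholds are percentiles of
#' the cohort distribution (70th by default) or fixed values.
#'
#' @param features cohort feature table (one row per patient).
#' @param condition_col,event_col column names.
#' @param condition_percentile,event_percentile percentiles in (0, 1) used
#'   when no fixed value is given.
#' @param condition_value,event_value optional fixed thresholds overriding
#'   the percentiles.
#' @return One-row tibble: `probability`, the thresholds, `n_condition`,
#'   `n_joint`; probability is `NA` (flagged) when no patient satisfies the
#'   condition.
#' @export
conditional_probability <- function(features, condition_col, event_col,
                                    condition_percentile = 0.7,
                                    event_percentile = 0.7,
                                    condition_value = NULL,
                                    event_value = NULL) {
  cv <- features[[condition_col]]
  ev <- features[[event_col]]
  if (is.null(cv) || is.null(ev)) abort("Column not found in `features`.")
  ct <- condition_value %||% quantile(cv, condition_percentile, na.rm = TRUE,
                                      names = FALSE)
  et <- event_value %||% quantile(ev, event_percentile, na.rm = TRUE,
                                  names = FALSE)
  cond <- !is.na(cv) & cv > ct
  joint <- cond & !is.na(ev) & ev > et
  n_c <- sum(cond); n_j <- sum(joint)
  tibble(
    probability = if (n_c > 0) n_j / n_c else NA_real_,
    condition_threshold = ct, event_threshold = et,
    n_condition = n_c, n_joint = n_j,
    flag = if (n_c > 0) NA_character_ else "empty_condition"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
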