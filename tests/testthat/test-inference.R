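# Correlations, Zellner-Siow Bayes factors, Jeffreys labels, conditional
# probabilities.

test_that("Pearson correlation handles exact linear relations and errors", {
  x <- 1:20
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  expect_error(pearson_cor(x, rep(1, 20)), "variance")
  expect_error(pearson_cor(1:2, 2:3), "3 complete")
})

test_that("the exact t-transform reproduces the printed p-values", {
  set.seed(81)
  d1 <- pair_with_r(-0.44, 27)
  expect_equal(round(pearson_cor(d1$x, d1$y)$p_value, 2), 0.02)
  d2 <- pair_with_r(-0.29, 50)
  expect_equal(round(pearson_cor(d2$x, d2$y)$p_value, 2), 0.04)
  # and matches R's reference implementation
  d <- pair_with_r(0.31, 40)
  expect_equal(pearson_cor(d$x, d$y)$p_value,
               cor.test(d$x, d$y)$p.value, tolerance = 1e-12)
})

test_that("p-values are invariant under affine transforms", {
  set.seed(83)
  d <- pair_with_r(0.4, 30)
  p0 <- pearson_cor(d$x, d$y)$p_value
  expect_equal(pearson_cor(5 - 2 * d$x, 0.1 * d$y + 7)$p_value, p0,
               tolerance = 1e-12)
})

test_that("BF01 is symmetric in the sign of r and decreasing in |r|", {
  expect_equal(bf01_correlation(0.3, 40), bf01_correlation(-0.3, 40),
               tolerance = 1e-14)
  for (n in c(20, 50)) {
    bfs <- vapply(seq(0, 0.9, by = 0.1), bf01_correlation, numeric(1), n = n)
    expect_true(all(diff(bfs) < 0))
  }
})

test_that("null support grows with sample size at r = 0", {
  bfs <- vapply(c(10, 20, 50, 100, 200), bf01_correlation, numeric(1), r = 0)
  expect_true(all(diff(bfs) > 0))
})

test_that("adaptive quadrature agrees with the Romberg oracle to 4 significant digits", {
  expect_equal(bf01_correlation(0, 50), romberg_bf01(0, 50), tolerance = 1e-4)
  expect_equal(bf01_correlation(-0.44, 27), romberg_bf01(-0.44, 27),
               tolerance = 1e-4)
})

test_that("the quadrature is stable under halving the tolerance", {
  for (r in c(0, 0.3, 0.7)) {
    a <- bf01_correlation(r, 35, rel_tol = 1e-8)
    b <- bf01_correlation(r, 35, rel_tol = 5e-9)
    expect_equal(a, b, tolerance = 1e-4)
  }
})

test_that("BF01 inputs are validated", {
  expect_error(bf01_correlation(1, 30), "\\|r\\|")
  expect_error(bf01_correlation(0.2, 3), "exceed")
})

test_that("partial correlation reduces to the textbook recursion", {
  expect_equal(partial_cor_from_r(0, 0, 0), 0)
  expect_equal(partial_cor_from_r(0.5, 0.5, 0.5), 1 / 3)
  set.seed(87)
  n <- 500
  z <- rnorm(n); x <- 0.8 * z + rnorm(n); y <- -0.5 * z + rnorm(n)
  direct <- partial_correlation(x, y, z)$r
  via_r <- partial_cor_from_r(cor(x, y), cor(x, z), cor(y, z))
  expect_equal(direct, via_r, tolerance = 1e-12)
})

test_that("controlling a shared driver removes a spurious correlation", {
  set.seed(89)
  n <- 1e4
  z <- rnorm(n)
  x <- z + 0.8 * rnorm(n)
  y <- z + 0.8 * rnorm(n)
  expect_gt(abs(cor(x, y)), 0.5)
  expect_lt(abs(partial_correlation(x, y, z)$r), 0.1)
})

test_that("nested-model Bayes factors behave at their boundaries", {
  expect_equal(bf01_partial(0.2, 0.2, n = 40, p = 2, p_prime = 2), 1,
               tolerance = 1e-10)
  # equal fits, one extra covariate: ratio checked against the Romberg oracle
  f <- function(u, R2, p) {
    g <- u / (1 - u)
    exp(((40 - p - 1) / 2) * log1p(g) - ((40 - 1) / 2) * log1p((1 - R2) * g) -
          1.5 * log(g) - 40 / (2 * g)) / (1 - u)^2
  }
  num <- pracma::romberg(function(u) f(u, 0.3, 3), 1e-12, 1 - 1e-9, tol = 1e-10)$value
  den <- pracma::romberg(function(u) f(u, 0.3, 2), 1e-12, 1 - 1e-9, tol = 1e-10)$value
  expect_equal(bf01_partial(0.3, 0.3, n = 40, p = 2, p_prime = 3),
               den / num, tolerance = 1e-4)
})

test_that("an uninformative added covariate is rejected in the median", {
  set.seed(91)
  bfs <- replicate(200, {
    n <- 50
    x <- rnorm(n); z <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    bf01_given_covariates(z, y, x)   # z has zero true effect given x
  })
  expect_gt(median(bfs), 1)
})

test_that("Jeffreys labels cover both directions of evidence", {
  expect_equal(jeffreys_label(6.6), "moderate evidence for H0")
  expect_equal(jeffreys_label(1.5), "anecdotal evidence for H0")
  expect_equal(jeffreys_label(475), "decisive evidence for H0")
  expect_equal(jeffreys_label(0.5), "anecdotal evidence for H1")
  expect_equal(jeffreys_label(c(15, 45, 1 / 200)),
               c("strong evidence for H0", "very strong evidence for H0",
                 "decisive evidence for H1"))
  expect_error(jeffreys_label(0), "positive")
})

test_that("conditional probabilities follow their definition", {
  feats <- tibble::tibble(a = c(rep(1, 5), rep(0, 5)),
                          b = c(1, 1, 1, 0, 0, 1, 1, 1, 1, 1))
  out <- conditional_probability(feats, "a", "b",
                                 condition_value = 0.5, event_value = 0.5)
  expect_equal(out$probability, 0.6)
  expect_equal(out$n_condition, 5)
  expect_equal(out$n_joint, 3)

  # event contains condition
  out2 <- conditional_probability(feats, "b", "b",
                                  condition_value = 0.5, event_value = 0.5)
  expect_equal(out2$probability, 1)

  none <- conditional_probability(feats, "a", "b",
                                  condition_value = 2, event_value = 0.5)
  expect_true(is.na(none$probability))
  expect_equal(none$flag, "empty_condition")
})

test_that("independent features give the marginal event rate", {
  set.seed(93)
  feats <- tibble::tibble(u = rnorm(1e4), v = rnorm(1e4))
  out <- conditional_probability(feats, "u", "v")
  expect_equal(out$probability, 0.30, tolerance = 0.05 / 0.30)
})
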