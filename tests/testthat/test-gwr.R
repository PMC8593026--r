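test_that("the bi-square kernel has its closed form and compact support", {
  expect_equal(bisquare_weight(0, 100), 1)
  expect_equal(bisquare_weight(100, 100), 0)
  expect_equal(bisquare_weight(150, 100), 0)
  expect_equal(bisquare_weight(50, 100), 0.5625)
  d <- seq(0, 120, by = 1)
  w <- bisquare_weight(d, 100)
  expect_true(all(diff(w) <= 1e-12))          # non-increasing
  expect_true(all(w >= 0 & w <= 1))
  expect_error(bisquare_weight(10, 0), "bandwidth")
  expect_error(bisquare_weight(-1, 10), "distance")
})

test_that("OLS reproduces exact fits and the pseudoinverse solution", {
  x <- seq(-3, 3, length.out = 20)
  g <- make_lattice_grid(4, 5, vars = list(x = x, y = 2 * x))
  fit <- fit_ols(g, "y", "x")
  expect_equal(unname(fit$coefficients[, "Estimate"]), c(0, 2))
  expect_equal(fit$r_squared, 1)

  set.seed(8)
  df <- data.frame(u = runif(20), v = runif(20),
                   x1 = rnorm(20), x2 = rnorm(20))
  df$y <- 1 + 0.5 * df$x1 - 2 * df$x2 + rnorm(20)
  fit2 <- fit_ols(df, "y", c("x1", "x2"))
  X <- cbind(1, df$x1, df$x2)
  expect_lt(max(abs(fit2$coefficients[, "Estimate"] -
                    ols_pinv_oracle(X, df$y))), 1e-10)
  expect_lte(fit2$adj_r_squared, fit2$r_squared)
  # t statistics are coefficient / standard error
  expect_equal(fit2$coefficients[, "t value"],
               fit2$coefficients[, "Estimate"] /
                 fit2$coefficients[, "Std. Error"])

  df$x3 <- df$x1 + df$x2   # exactly collinear
  expect_error(fit_ols(df, "y", c("x1", "x2", "x3")), "x3")
})

test_that("slope p-values are roughly uniform when y is independent of x", {
  set.seed(31)
  p <- replicate(200, {
    d <- data.frame(u = 1:15, v = 1:15, x = rnorm(15), y = rnorm(15))
    fit_ols(d, "y", "x")$coefficients["x", "Pr(>|t|)"]
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("every local GWR solve equals the explicit weighted normal equations",
{
  set.seed(12)
  g <- make_lattice_grid(8, 8, vars = list(x = rnorm(64)))
  g$cells$y <- 1 + 0.5 * g$cells$x + rnorm(64, sd = 0.3)
  k <- 20L
  gw <- gwr_fit(g, "y", "x", kernel_spec("bisquare", "adaptive", k))
  X <- cbind(1, g$cells$x)
  for (i in c(1, 13, 32, 64)) {
    d <- sqrt((g$cells$u - g$cells$u[i])^2 + (g$cells$v - g$cells$v[i])^2)
    b <- sort(d)[k]
    w <- bisquare_weight(d, b)
    idx <- w > 0
    ref <- wls_oracle(X[idx, ], g$cells$y[idx], w[idx])
    expect_lt(max(abs(gw$coefficients[i, ] - drop(ref))), 1e-10)
  }
  expect_true(all(is.finite(gw$std_residuals)))
  pct <- summarize_gwr(gw, "x")$pct_stdres_in_band
  expect_gte(pct, 0); expect_lte(pct, 100)
})

test_that("an all-ones kernel makes every local fit the global OLS fit", {
  set.seed(13)
  g <- make_lattice_grid(6, 6, vars = list(x = rnorm(36)))
  g$cells$y <- 2 - 3 * g$cells$x + rnorm(36)
  ols <- fit_ols(g, "y", "x")
  diam <- sqrt(2) * 6 * 500
  # fixed bandwidth so large that (1 - (d/b)^2)^2 is 1 to machine precision
  gw <- gwr_fit(g, "y", "x", kernel_spec("bisquare", "fixed", diam * 1e9))
  expect_lt(max(abs(sweep(gw$coefficients, 2,
                          ols$coefficients[, "Estimate"]))), 1e-8)
})

test_that("bandwidth selection: homogeneous data pick wide kernels, and golden
           section matches exhaustive search", {
  set.seed(14)
  g <- make_lattice_grid(7, 7, vars = list(x = rnorm(49)))
  g$cells$y <- 1 + 2 * g$cells$x + rnorm(49, sd = 0.5)   # no heterogeneity
  gold <- select_bandwidth(g, "y", "x", criterion = "aicc")
  grid_all <- select_bandwidth(g, "y", "x", criterion = "aicc",
                               search = "grid")
  expect_equal(gold$bandwidth, grid_all$bandwidth)
  expect_gte(gold$bandwidth, 49 * 0.6)   # near the top of the range
  # profile is reported and covers the evaluated points
  expect_true(all(c("bandwidth", "score") %in% names(gold$profile)))
  expect_equal(min(gold$profile$score), gold$score)
})

test_that("the AIC verdict applies the |delta| > 3 rule", {
  expect_equal(aic_verdict(134948.273, 130634.719), "GWR preferred")
  expect_equal(130634.719 - 134948.273, -4313.554)
  expect_equal(aic_verdict(100, 102), "indistinguishable")
  expect_equal(aic_verdict(100, 98), "indistinguishable")
  expect_equal(aic_verdict(98, 102), "OLS preferred")
  expect_equal(aic_verdict(100, 100), "indistinguishable")
})

test_that("summarize_gwr splits coefficient signs into complementary shares", {
  gw <- structure(list(
    coefficients = cbind(`(Intercept)` = rep(0, 4), x = c(-1, -1, 2, 4)),
    std_residuals = c(0.1, -0.2, 0.3, 2.4),
    y_var = "y", x_vars = "x"), class = "gwr_result")
  s <- summarize_gwr(gw, "x")
  expect_equal(s[c("min", "max", "mean")], list(min = -1, max = 4, mean = 1))
  expect_equal(s$pct_positive, 50)
  expect_equal(s$pct_negative, 50)
  expect_equal(s$pct_stdres_in_band, 100)
  expect_error(summarize_gwr(gw, "nope"), "unknown coefficient")
})

test_that("compare_models rejects mismatched fits and reports delta AIC", {
  set.seed(15)
  g <- make_lattice_grid(5, 5, vars = list(x = rnorm(25)))
  g$cells$y <- g$cells$x + rnorm(25)
  ols <- fit_ols(g, "y", "x")
  gw <- gwr_fit(g, "y", "x", kernel_spec("bisquare", "adaptive", 12))
  cmp <- compare_models(ols, gw)
  expect_equal(cmp$delta_aic, gw$aic - ols$aic)
  expect_true(cmp$verdict %in%
                c("GWR preferred", "OLS preferred", "indistinguishable"))
  ols2 <- fit_ols(g[["cells"]][1:20, ], "y", "x")
  expect_error(compare_models(ols2, gw), "same cells")
})
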