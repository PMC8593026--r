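test_that("the elementwise impact formulas do their arithmetic", {
  expect_equal(compute_npp_h(0, 500), 500)
  expect_equal(compute_npp_h(1, 500), 0)
  expect_equal(compute_npp_h(0.4, 500), 300)
  expect_error(compute_npp_h(1.2, 500), "beta")

  expect_equal(compute_npp_dir(0.1, 0.6, 500), -250)
  expect_equal(compute_npp_dir(0.3, 0.3, 500), 0)
  expect_equal(compute_npp_dir(0.6, 0.1, 500), 250)   # de-urbanization
  expect_error(compute_npp_dir(c(0.1, 0.2), 0.6, 500), "length")

  expect_equal(compute_npp_ind(350, 0.4, 500), 50)
  expect_equal(compute_npp_ind((1 - 0.4) * 500, 0.4, 500), 0)
})

test_that("npp_ind is invariant to shifting both terms by a constant", {
  set.seed(2)
  npp <- runif(50, 100, 800); b <- runif(50); fv <- runif(50, 300, 900)
  base <- compute_npp_ind(npp, b, fv)
  shift <- compute_npp_ind(npp + 123.4, b, fv + 123.4 / (1 - b))
  expect_equal(shift, base)
})

test_that("npp_dir is non-increasing in beta_t1 for nonnegative npp_fv", {
  b1 <- seq(0, 1, by = 0.05)
  d <- compute_npp_dir(rep(0.2, length(b1)), b1, rep(400, length(b1)))
  expect_true(all(diff(d) <= 0))
})

test_that("the low-beta-mean estimator averages pristine neighborhoods", {
  g <- make_lattice_grid(1, 5, vars = list(
    beta_t0 = c(0, 0.01, 0.5, 0.9, 0.02),
    npp_t0 = c(400, 500, 100, 50, 600)))
  fv <- estimate_npp_fv(g, beta_threshold = 0.05,
                        neighborhood_radius = Inf)
  expect_equal(fv, rep(500, 5))   # mean of 400, 500, 600

  # beta = 0 everywhere: plain mean of npp_t0
  g2 <- make_lattice_grid(2, 2, vars = list(beta_t0 = rep(0, 4),
                                            npp_t0 = c(1, 2, 3, 4)))
  expect_equal(estimate_npp_fv(g2, neighborhood_radius = Inf), rep(2.5, 4))

  # finite radius: only nearby pristine cells count, with global fallback
  g3 <- make_lattice_grid(1, 4, cell = 1000, vars = list(
    beta_t0 = c(0, 0.8, 0.8, 0),
    npp_t0 = c(100, 0, 0, 900)))
  fv3 <- estimate_npp_fv(g3, neighborhood_radius = 1500)
  expect_equal(fv3, c(100, 100, 900, 900))

  expect_error(estimate_npp_fv(
    make_lattice_grid(1, 3, vars = list(beta_t0 = rep(0.5, 3),
                                        npp_t0 = 1:3))),
    "beta_threshold")

  # supplied mode passes truth through untouched
  g4 <- make_lattice_grid(1, 3, vars = list(npp_fv = c(5, 6, 7)))
  expect_identical(estimate_npp_fv(g4, mode = "supplied"), c(5, 6, 7))
})

test_that("summarize_npp_ind counts and summarizes only positive cells", {
  s <- summarize_npp_ind(c(-5, 0, 2, 8))
  expect_equal(s, list(grid_count = 2L, min = 2, max = 8, mean = 5))
  s0 <- summarize_npp_ind(c(-1, 0, -3))
  expect_equal(s0$grid_count, 0L)
  expect_true(is.na(s0$mean))
})

test_that("decompose_impacts reports the t0 baseline residual diagnostic", {
  city <- quiet_city(16)
  g <- aggregate_to_fishnet(c(city$layers, city$truth), cell_size = 250)
  g$cells$npp_fv <- g$cells$npp_fv_true
  g <- decompose_impacts(g, npp_fv_mode = "supplied")
  # noise-free: t0 is exactly land-cover controlled
  expect_lt(max(abs(g$cells$resid_t0)), 1e-9)
  expect_equal(g$cells$npp_h,
               (1 - g$cells$beta_t1) * g$cells$npp_fv)
})
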