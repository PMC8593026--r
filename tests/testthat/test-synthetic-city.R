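test_that("generation is deterministic in the seed and beta stays in [0,1]", {
  a <- generate_city(city_config(grid_n = 16, seed = 1))
  b <- generate_city(city_config(grid_n = 16, seed = 1))
  d <- generate_city(city_config(grid_n = 16, seed = 2))
  expect_identical(a$layers, b$layers)
  expect_false(identical(a$layers$npp_t1$values, d$layers$npp_t1$values))
  for (nm in c("beta_t0", "beta_t1")) {
    v <- a$layers[[nm]]$values
    expect_true(all(v >= 0 & v <= 1))
  }
  # calling generate_city must not disturb the caller's RNG stream
  set.seed(99); x1 <- rnorm(1)
  set.seed(99); invisible(generate_city(city_config(grid_n = 8))); x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("degenerate configurations reduce to the pure land-cover model", {
  # no indirect effect, no noise: npp_t1 is exactly (1 - beta_t1) * npp_fv
  c0 <- generate_city(city_config(grid_n = 12, noise_sd_npp = 0,
                                  noise_sd_lst = 0, gamma_core = 0,
                                  gamma_far = 0))
  expect_equal(c0$layers$npp_t1$values,
               (1 - c0$layers$beta_t1$values) * c0$truth$npp_fv_true$values)
  expect_true(all(c0$truth$npp_ind_true$values == 0))

  # no expansion: direct impact identically zero
  c1 <- generate_city(city_config(grid_n = 12, beta_max_t0 = 0.5,
                                  beta_max_t1 = 0.5, noise_sd_npp = 0,
                                  noise_sd_lst = 0))
  expect_true(all(c1$truth$npp_dir_true$values == 0))
})

test_that("truth surfaces satisfy the decomposition identity when noise is off",
{
  city <- quiet_city()
  lhs <- city$layers$npp_t1$values - city$layers$npp_t0$values
  rhs <- city$truth$npp_dir_true$values + city$truth$npp_ind_true$values
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("raising the UHI amplitude warms the core but not the gamma truth", {
  base <- generate_city(city_config(grid_n = 20, seed = 4))
  hot <- generate_city(city_config(grid_n = 20, seed = 4,
                                   uhi_amplitude = 8))
  core <- base$layers$beta_t1$values > 0.5
  expect_gt(mean(hot$layers$lst_t1$values[core]),
            mean(base$layers$lst_t1$values[core]))
  expect_identical(hot$truth$gamma_true$values, base$truth$gamma_true$values)
})

test_that("invalid configurations name the offending field", {
  expect_error(city_config(grid_n = 4), "grid_n")
  expect_error(city_config(beta_max_t0 = 0.9, beta_max_t1 = 0.5),
               "beta_max_t0")
  expect_error(city_config(beta_max_t1 = 1.4), "beta_max_t1")
  expect_error(city_config(noise_sd_npp = -1), "noise_sd_npp")
  expect_error(city_config(gamma_scale = 0), "gamma_scale")
})

test_that("a written city round-trips through the manifest and raster reader",
{
  city <- generate_city(city_config(grid_n = 10, seed = 3))
  dir <- withr::local_tempdir()
  manifest <- write_city(city, dir)
  expect_length(manifest$layers, 6L)
  expect_length(manifest$truth_layers, 4L)
  back <- read_city(dir)
  expect_equal(back$layers$beta_t1$values, city$layers$beta_t1$values)
  expect_equal(back$truth$gamma_true$values, city$truth$gamma_true$values)
  expect_equal(back$config$seed, city$config$seed)
})
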