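test_that("lattice contiguity weights have the expected cardinalities", {
  g <- make_lattice_grid(3, 3)
  rook <- build_weights(g, "rook", "B")
  expect_equal(rook$cardinality[c(1, 3, 7, 9)], rep(2L, 4))   # corners
  expect_equal(rook$cardinality[5], 4L)                       # center
  queen <- build_weights(g, "queen", "B")
  expect_equal(queen$cardinality[5], 8L)
  expect_equal(queen$cardinality[1], 3L)
  # binary contiguity is symmetric
  Wb <- dense_w(queen)
  expect_identical(Wb, t(Wb))
  # row standardization sums each nonempty row to 1
  qw <- build_weights(g, "queen", "W")
  expect_equal(unname(rowSums(dense_w(qw))), rep(1, 9))
  # knn neighbors exclude self
  kw <- build_weights(g, "knn", "W", k = 3)
  expect_true(all(vapply(seq_len(9), function(i)
    !(i %in% kw$neighbours[[i]]), logical(1))))
})

test_that("the null expectation is -1/(n-1) and constant fields error", {
  g <- make_lattice_grid(1, 5, vars = list(x = c(1, 3, 2, 5, 4)))
  w <- build_weights(g, "rook", "W")
  m <- global_morans_i(g$cells$x, w)
  expect_equal(m$E_I, -0.25)
  expect_error(global_morans_i(rep(1, 5), w), "variance")
  expect_error(global_morans_i(1:4, w), "length")
})

test_that("global Moran's I agrees with an independent implementation (ape)", {
  skip_if_not_installed("ape")
  set.seed(42)
  g <- make_lattice_grid(6, 7, vars = list(x = rnorm(42)))
  # ape row-normalizes the weight matrix internally, so hand it the binary
  # contiguity matrix and compare against our row-standardized statistic
  wW <- build_weights(g, "queen", "W")
  wB <- build_weights(g, "queen", "B")
  ours <- global_morans_i(g$cells$x, wW)
  ref <- ape::Moran.I(g$cells$x, dense_w(wB), scaled = FALSE)
  expect_equal(ours$I, ref$observed, tolerance = 1e-12)
  expect_equal(ours$E_I, ref$expected, tolerance = 1e-12)
})

test_that("permutation inference is seed-reproducible with a valid pseudo-p", {
  set.seed(3)
  g <- make_lattice_grid(7, 7, vars = list(x = smooth_field(7, 7, seed = 3)))
  w <- build_weights(g)
  a <- moran_permutation_test(g$cells$x, w, n_perm = 199, seed = 11)
  b <- moran_permutation_test(g$cells$x, w, n_perm = 199, seed = 11)
  expect_identical(a$perm_I, b$perm_I)
  expect_identical(a$p_perm, b$p_perm)
  expect_gt(a$p_perm, 0)
  expect_lte(a$p_perm, 1)
  expect_equal(min(a$p_perm, 1 / 200), 1 / 200)  # floor = 1/(n_perm+1)
  # a smooth field is detected as positive autocorrelation
  expect_gt(a$I, 0)
  expect_lte(a$p_perm, 0.01)
})

test_that("a strongly clustered field hits the pseudo-p floor at 999 perms", {
  g <- make_lattice_grid(8, 8, vars = list(x = smooth_field(8, 8, passes = 6,
                                                            seed = 5)))
  w <- build_weights(g)
  m <- moran_permutation_test(g$cells$x, w, n_perm = 999, seed = 21)
  expect_equal(m$p_perm, 0.001)
})

test_that("local Moran matches its closed form at the checkerboard center", {
  v <- as.vector(t(outer(1:3, 1:3, function(r, c) (-1)^(r + c))))
  g <- make_lattice_grid(3, 3, vars = list(x = v))
  w <- build_weights(g, "rook", "W")
  li <- local_morans_i(g$cells$x, w, n_perm = 99, seed = 1)
  z <- v - mean(v)
  s2 <- mean(z^2)
  expect_equal(li$table$I_i[5], z[5] / s2 * mean(z[c(2, 4, 6, 8)]))
  expect_equal(li$table$I_i, local_moran_oracle(v, dense_w(w)))
})

test_that("LISA classes follow the quadrant rule with a strict NS boundary", {
  lisa <- structure(list(
    table = data.frame(
      I_i = c(1, 1, -1, -1, 0.5, NA),
      p_i = c(0.01, 0.01, 0.01, 0.01, 0.05, NA),   # 5th exactly at alpha
      z_i = c(2, -2, -2, 2, 1, 0),
      lag_i = c(1.5, -1.5, 1.5, -1.5, 1, 0)),
    alpha = 0.05, n_perm = 99, seed = 1),
    class = "lisa_result")
  cl <- lisa_classify(lisa)$table$class
  expect_equal(as.character(cl),
               c("HH", "LL", "LH", "HL", "NS", NA))
})

test_that("island cells are excluded from LISA statistics", {
  cells <- data.frame(row = c(1, 1, 1, 10), col = c(1, 2, 3, 10),
                      u = c(250, 750, 1250, 4750),
                      v = c(250, 250, 250, -4250),
                      x = c(1, 5, 2, 9))
  g <- fishnet_grid(cells, cell_size = 500)
  w <- build_weights(g, "queen", "W")
  expect_equal(w$islands, 4L)
  li <- lisa_classify(local_morans_i(g$cells$x, w, n_perm = 99, seed = 2))
  expect_true(is.na(li$table$I_i[4]))
  expect_true(is.na(li$table$class[4]))
  expect_false(anyNA(li$table$class[1:3]))
})

test_that("spatial lag respects the row-standardized weights", {
  g <- make_lattice_grid(1, 3, vars = list(x = c(2, 4, 6)))
  w <- build_weights(g, "rook", "W")
  expect_equal(spatial_lag(w, g$cells$x), c(4, 4, 4))
})
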