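# Independent brute-force oracles and small fixture builders.
# These deliberately re-derive every statistic from its defining double sum /
# normal equations, without touching the package's vectorized code paths.

# Full lattice fishnet grid with optional variable columns.
make_lattice_grid <- function(nr, nc, cell = 500, vars = list()) {
  cells <- expand.grid(col = seq_len(nc), row = seq_len(nr))
  cells <- cells[order(cells$row, cells$col), ]
  cells$u <- (cells$col - 0.5) * cell
  cells$v <- (nr - cells$row + 0.5) * cell
  cells$id <- seq_len(nrow(cells))
  for (nm in names(vars)) cells[[nm]] <- vars[[nm]]
  fishnet_grid(cells, cell_size = cell)
}

dense_w <- function(w) as.matrix(w$W)

# Global Moran's I by the defining double loop.
moran_oracle <- function(y, Wm) {
  n <- length(y)
  z <- y - mean(y)
  s2 <- sum(z^2) / n
  num <- 0; wsum <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + Wm[i, j] * z[i] * z[j]
    wsum <- wsum + Wm[i, j]
  }
  num / (s2 * wsum)
}

# Local Moran's I_i by the defining loop.
local_moran_oracle <- function(y, Wm) {
  n <- length(y)
  z <- y - mean(y)
  s2 <- sum(z^2) / n
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) acc <- acc + Wm[i, j] * z[j]
    out[i] <- z[i] / s2 * acc
  }
  out
}

# Weighted least squares by explicit normal equations with a dense diagonal
# weight matrix (the estimator's defining form).
wls_oracle <- function(X, y, w) {
  Wd <- diag(w)
  solve(t(X) %*% Wd %*% X) %*% (t(X) %*% Wd %*% y)
}

# OLS coefficients through the SVD pseudoinverse (no lm, no qr).
ols_pinv_oracle <- function(X, y) {
  s <- svd(X)
  s$v %*% diag(1 / s$d) %*% t(s$u) %*% y
}

# A smooth spatially autocorrelated field: white noise blurred by repeated
# rook-neighbor averaging.
smooth_field <- function(nr, nc, passes = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(nr * nc), nr, nc)
  for (p in seq_len(passes)) {
    up <- rbind(m[1, ], m[-nr, ]); dn <- rbind(m[-1, ], m[nr, ])
    lf <- cbind(m[, 1], m[, -nc]); rt <- cbind(m[, -1], m[, nc])
    m <- (m + up + dn + lf + rt) / 5
  }
  as.vector(t(m))   # row-major to match lattice cell order
}

# Small noise-free city used by several exactness tests.
quiet_city <- function(grid_n = 24, seed = 7, ...) {
  generate_city(city_config(grid_n = grid_n, cell_size = 250,
                            core_radius = grid_n * 250 / 4,
                            core_softness = grid_n * 250 / 12,
                            gamma_scale = grid_n * 250 / 4,
                            noise_sd_npp = 0, noise_sd_lst = 0,
                            seed = seed, ...))
}
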