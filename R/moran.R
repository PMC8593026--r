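#' Global Moran's I with analytic inference
#'
#' Computes `I = (n / W0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with
#' `z = Y - mean(Y)` (equivalently the familiar ratio with
#' `S^2 = mean(z^2)` in the denominator). Under the null of no spatial
#' association `E(I) = -1/(n-1)`; both the normality and the randomization
#' (Cliff-Ord) variances are reported, with two-sided normal p-values. For a
#' distribution-free p-value use [moran_permutation_test()].
#'
#' @param values Numeric per-cell field (no NAs; non-constant).
#' @param w A [build_weights()] structure matching `values`.
#' @return Object of class `moran_result` with fields `I`, `E_I`,
#'   `var_norm`, `var_rand`, `z_norm`, `z_rand`, `p_norm`, `p_rand`, `n`.
#' @export
global_morans_i <- function(values, w) {
  stopifnot(inherits(w, "spatial_weights"))
  y <- as.numeric(values)
  n <- w$n
  if (length(y) != n) stop("length(values) != number of cells", call. = FALSE)
  if (anyNA(y)) stop("values contain NA; drop masked cells first",
                     call. = FALSE)
  if (n < 3) stop("need n >= 3 cells", call. = FALSE)
  z <- y - mean(y)
  m2 <- sum(z^2)
  if (m2 == 0) stop("zero variance: values are constant", call. = FALSE)

  I <- (n / w$W0) * sum(z * as.numeric(w$W %*% z)) / m2
  E_I <- -1 / (n - 1)

  W0 <- w$W0; S1 <- w$S1; S2 <- w$S2
  var_norm <- (n^2 * S1 - n * S2 + 3 * W0^2) / (W0^2 * (n^2 - 1)) - E_I^2
  b2 <- n * sum(z^4) / m2^2                       # sample kurtosis
  var_rand <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * W0^2) -
                 b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * W0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * W0^2) - E_I^2

  z_norm <- (I - E_I) / sqrt(var_norm)
  z_rand <- (I - E_I) / sqrt(var_rand)
  structure(list(
    I = I, E_I = E_I, var_norm = var_norm, var_rand = var_rand,
    z_norm = z_norm, z_rand = z_rand,
    p_norm = 2 * stats::pnorm(-abs(z_norm)),
    p_rand = 2 * stats::pnorm(-abs(z_rand)),
    n = n, W0 = W0
  ), class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.4f  (E[I] = %.4f, n = %d)\n",
              x$I, x$E_I, x$n))
  cat(sprintf("  normality:     z = %8.3f, p = %.4g\n", x$z_norm, x$p_norm))
  cat(sprintf("  randomization: z = %8.3f, p = %.4g\n", x$z_rand, x$p_rand))
  if (!is.null(x$p_perm))
    cat(sprintf("  permutation:   p = %.4g (%d permutations)\n",
                x$p_perm, x$n_perm))
  invisible(x)
}

#' Permutation test for global Moran's I
#'
#' Randomly reassigns the observed values to cells `n_perm` times and
#' recomputes I each time. The two-sided pseudo p-value is
#' `(#\{|I_perm - E(I)| >= |I_obs - E(I)|\} + 1) / (n_perm + 1)`, so the
#' smallest attainable p is `1/(n_perm + 1)` (0.001 at 999 permutations).
#'
#' @param values Per-cell field.
#' @param w A [build_weights()] structure.
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Integer seed (required, for reproducibility).
#' @return A `moran_result` augmented with `p_perm`, `n_perm`, `seed`, and
#'   `perm_I` (the simulated null values).
#' @export
moran_permutation_test <- function(values, w, n_perm = 999, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (n_perm < 99) stop("`n_perm` must be >= 99", call. = FALSE)
  res <- global_morans_i(values, w)
  n <- w$n
  z <- as.numeric(values) - mean(as.numeric(values))
  m2 <- sum(z^2)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  # permute in blocks to bound memory at n x <=200 doubles
  perm_I <- numeric(n_perm)
  done <- 0L
  while (done < n_perm) {
    nb <- min(200L, n_perm - done)
    Zp <- vapply(seq_len(nb), function(j) z[sample.int(n)], numeric(n))
    perm_I[done + seq_len(nb)] <-
      (n / w$W0) * Matrix::colSums(Zp * (w$W %*% Zp)) / m2
    done <- done + nb
  }
  exceed <- sum(abs(perm_I - res$E_I) >= abs(res$I - res$E_I))
  res$p_perm <- (exceed + 1) / (n_perm + 1)
  res$n_perm <- n_perm
  res$seed <- as.integer(seed)
  res$perm_I <- perm_I
  res
}

#' Local Moran's I (LISA) with conditional permutation inference
#'
#' `I_i = (z_i / S^2) * sum_j w_ij z_j` with `S^2 = mean(z^2)`. The local
#' statistics satisfy `sum_i I_i = I * W0` relative to the global statistic.
#' Pseudo p-values come from conditional permutation: cell i's value is held
#' fixed while the remaining `n - 1` values are randomly assigned to its
#' neighbor positions; two-sided around the conditional null mean. Island
#' cells (no neighbors) get `NA` statistics and are excluded from
#' classification.
#'
#' @param values Per-cell field.
#' @param w A [build_weights()] structure.
#' @param n_perm Conditional permutations per cell (default 999).
#' @param seed Integer seed (required).
#' @param alpha Significance level stored for downstream classification.
#' @return Object of class `lisa_result`: data.frame `table` with `I_i`,
#'   `p_i`, `z_i` (mean deviate), `lag_i`, plus `alpha`, `n_perm`, `seed`.
#' @export
local_morans_i <- function(values, w, n_perm = 999, seed, alpha = 0.05) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(inherits(w, "spatial_weights"))
  y <- as.numeric(values)
  n <- w$n
  if (length(y) != n) stop("length(values) != number of cells", call. = FALSE)
  if (anyNA(y)) stop("values contain NA; drop masked cells first",
                     call. = FALSE)
  z <- y - mean(y)
  S2 <- mean(z^2)
  if (S2 == 0) stop("zero variance: values are constant", call. = FALSE)
  lag <- spatial_lag(w, y)            # NA at islands
  lag_z <- spatial_lag(w, z)
  I_i <- z / S2 * lag_z

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  p_i <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ki <- w$cardinality[i]
    if (ki == 0L) next
    zo <- z[-i]
    wi <- w$weights[[i]]
    perm <- numeric(n_perm)
    for (j in seq_len(n_perm))
      perm[j] <- sum(wi * zo[sample.int(n - 1L, ki)])
    stat <- z[i] / S2 * perm
    center <- mean(stat)
    exceed <- sum(abs(stat - center) >= abs(I_i[i] - center))
    p_i[i] <- (exceed + 1) / (n_perm + 1)
  }
  structure(list(
    table = data.frame(I_i = I_i, p_i = p_i, z_i = z, lag_i = lag_z),
    alpha = alpha, n_perm = n_perm, seed = as.integer(seed),
    S2 = S2
  ), class = "lisa_result")
}

#' @export
print.lisa_result <- function(x, ...) {
  cat(sprintf("<lisa_result> %d cells, %d permutations, alpha = %g\n",
              nrow(x$table), x$n_perm, x$alpha))
  if (!is.null(x$table$class)) print(table(x$table$class))
  invisible(x)
}

#' Classify LISA clusters
#'
#' Assigns each cell to `NS` (p_i >= alpha, strictly), else to the quadrant
#' of its mean deviate and spatial lag: `(+,+) = HH`, `(-,-) = LL`,
#' `(-,+) = LH`, `(+,-) = HL`. HH means a high value surrounded by high
#' values (a hot-spot cluster), LL a cold-spot, LH/HL spatial outliers.
#' Island cells (undefined I_i) are classified `NA`.
#'
#' @param lisa A [local_morans_i()] result.
#' @param alpha Significance level (default: the one stored in `lisa`).
#' @return The `lisa_result` with a `class` factor column added
#'   (levels NS, HH, LL, LH, HL).
#' @export
lisa_classify <- function(lisa, alpha = NULL) {
  stopifnot(inherits(lisa, "lisa_result"))
  if (is.null(alpha)) alpha <- lisa$alpha
  tb <- lisa$table
  cls <- rep(NA_character_, nrow(tb))
  ok <- !is.na(tb$p_i)
  cls[ok] <- "NS"
  sig <- ok & tb$p_i < alpha
  cls[sig & tb$z_i > 0 & tb$lag_i > 0] <- "HH"
  cls[sig & tb$z_i < 0 & tb$lag_i < 0] <- "LL"
  cls[sig & tb$z_i < 0 & tb$lag_i >= 0] <- "LH"
  cls[sig & tb$z_i > 0 & tb$lag_i <= 0] <- "HL"
  lisa$table$class <- factor(cls, levels = c("NS", "HH", "LL", "LH", "HL"))
  lisa$alpha <- alpha
  lisa
}
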