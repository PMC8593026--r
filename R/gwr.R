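#' Global OLS baseline
#'
#' Ordinary least squares of `y_var` on `x_vars` over all fishnet cells: the
#' "global" model against which the geographically weighted fit is compared.
#' The AIC reported uses the same Gaussian form as [gwr_fit()]
#' (`2n log(sigma_ML) + n log(2 pi) + n + enp`, with `enp = p + 1`
#' parameters), so OLS and GWR AICs are directly comparable.
#'
#' @param grid A [fishnet_grid()] or data.frame.
#' @param y_var Response column name.
#' @param x_vars Character vector of predictor column names.
#' @return Object of class `ols_result`: `coefficients` table (estimate,
#'   std. error, t value, Pr(>|t|)), `residuals`, `fitted`, `r_squared`,
#'   `adj_r_squared`, `aic`, `sigma2_ml`, `n`, and the underlying `lm` fit.
#' @export
fit_ols <- function(grid, y_var, x_vars) {
  df <- if (inherits(grid, "fishnet_grid")) grid$cells else grid
  miss <- setdiff(c(y_var, x_vars), names(df))
  if (length(miss))
    stop("unknown column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  y <- df[[y_var]]
  X <- cbind(`(Intercept)` = 1, as.matrix(df[, x_vars, drop = FALSE]))
  n <- length(y); p <- length(x_vars)
  if (n <= p + 1) stop("need n > p + 1 observations", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_col <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank-deficient; collinear column(s): ",
         paste(drop_col, collapse = ", "), call. = FALSE)
  }
  fml <- stats::reformulate(x_vars, response = y_var)
  fit <- stats::lm(fml, data = df)
  sm <- summary(fit)
  rss <- sum(stats::residuals(fit)^2)
  sigma2_ml <- rss / n
  enp <- p + 1
  aic <- n * log(sigma2_ml) + n * log(2 * pi) + n + enp
  structure(list(
    coefficients = as.data.frame(sm$coefficients),
    residuals = stats::residuals(fit),
    fitted = stats::fitted(fit),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    aic = aic, sigma2_ml = sigma2_ml, rss = rss,
    n = n, enp = enp, y_var = y_var, x_vars = x_vars, lm = fit
  ), class = "ols_result")
}

#' @export
print.ols_result <- function(x, ...) {
  cat(sprintf("OLS: %s ~ %s  (n = %d)\n", x$y_var,
              paste(x$x_vars, collapse = " + "), x$n))
  stats::printCoefmat(as.matrix(x$coefficients), digits = 4)
  cat(sprintf("Adjusted R-squared: %.4f   AIC: %.3f\n",
              x$adj_r_squared, x$aic))
  invisible(x)
}

#' Bi-square kernel weight
#'
#' `w(d) = (1 - (d/b)^2)^2` for `d < b`, else 0: continuous, non-increasing,
#' compactly supported — the standard distance-decay kernel for
#' geographically weighted regression.
#'
#' @param d Distance(s), meters (>= 0).
#' @param b Bandwidth, meters (> 0).
#' @return Weight(s) in `[0, 1]`.
#' @export
bisquare_weight <- function(d, b) {
  if (any(!is.finite(b)) || any(b <= 0))
    stop("bandwidth `b` must be > 0", call. = FALSE)
  if (any(d < 0)) stop("distances must be >= 0", call. = FALSE)
  w <- (1 - (d / b)^2)^2
  w[d >= b] <- 0
  w
}

#' Kernel specification for GWR
#'
#' @param kind Kernel family; only `"bisquare"` is provided.
#' @param bandwidth_mode `"adaptive"` (bandwidth = distance to the k-th
#'   nearest observation, k = `bandwidth`, the regression point itself
#'   included) or `"fixed"` (bandwidth = `bandwidth` meters everywhere).
#' @param bandwidth Neighbor count (adaptive) or distance in meters (fixed).
#' @return Object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = "bisquare",
                        bandwidth_mode = c("adaptive", "fixed"),
                        bandwidth) {
  kind <- match.arg(kind)
  bandwidth_mode <- match.arg(bandwidth_mode)
  if (missing(bandwidth) || !is.numeric(bandwidth) || length(bandwidth) != 1 ||
      !is.finite(bandwidth) || bandwidth <= 0)
    stop("`bandwidth` must be a single positive number", call. = FALSE)
  if (bandwidth_mode == "adaptive") bandwidth <- as.integer(round(bandwidth))
  structure(list(kind = kind, bandwidth_mode = bandwidth_mode,
                 bandwidth = bandwidth), class = "kernel_spec")
}

# Precompute the geometry shared by every candidate bandwidth: pairwise
# distances and, for adaptive kernels, per-point sorted distances.
.gwr_prep <- function(df, y_var, x_vars) {
  y <- df[[y_var]]
  X <- cbind(`(Intercept)` = 1, as.matrix(df[, x_vars, drop = FALSE]))
  n <- length(y)
  u <- df$u; v <- df$v
  if (anyDuplicated(cbind(u, v)))
    warning("coincident cell centers detected; local solves may be ",
            "rank-deficient", call. = FALSE)
  D <- sqrt(outer(u, u, "-")^2 + outer(v, v, "-")^2)
  Dsort <- apply(D, 2L, sort)       # column i = sorted distances from i
  list(y = y, X = X, n = n, p = ncol(X) - 1L, D = D, Dsort = Dsort,
       diameter = max(D))
}

# One GWR pass at a given kernel; returns per-location results.
.gwr_solve <- function(prep, kernel) {
  n <- prep$n; X <- prep$X; y <- prep$y
  p1 <- ncol(X)
  beta <- matrix(NA_real_, n, p1, dimnames = list(NULL, colnames(X)))
  se <- matrix(NA_real_, n, p1, dimnames = list(NULL, colnames(X)))
  hat <- rep(NA_real_, n)
  local_r2 <- rep(NA_real_, n)
  fails <- 0L
  for (i in seq_len(n)) {
    b_i <- if (kernel$bandwidth_mode == "adaptive") {
      prep$Dsort[min(kernel$bandwidth, n), i]
    } else kernel$bandwidth
    w <- bisquare_weight(prep$D[, i], b_i)
    idx <- which(w > 0)
    if (length(idx) < p1) { fails <- fails + 1L; next }
    Xi <- X[idx, , drop = FALSE]
    wi <- w[idx]
    Xw <- Xi * wi
    A <- crossprod(Xw, Xi)                       # X' W X
    ok <- TRUE
    Ainv <- tryCatch(solve(A), error = function(e) { ok <<- FALSE; NULL })
    if (!ok || any(!is.finite(Ainv))) { fails <- fails + 1L; next }
    Ci <- Ainv %*% t(Xw)                         # (X'WX)^-1 X'W
    bi <- drop(Ci %*% y[idx])
    beta[i, ] <- bi
    # hat value: s_ii = x_i' (X'WX)^-1 X'W e_i
    self <- match(i, idx)
    if (!is.na(self)) hat[i] <- drop(X[i, ] %*% Ci[, self])
    # variance factor (X'WX)^-1 X'W^2X (X'WX)^-1; scaled by sigma2 later
    M <- crossprod(Xw)                           # X' W^2 X
    se[i, ] <- sqrt(pmax(diag(Ainv %*% M %*% Ainv), 0))
    yl <- y[idx]
    fit_l <- drop(Xi %*% bi)
    tss_l <- sum(wi * (yl - sum(wi * yl) / sum(wi))^2)
    if (tss_l > 0) local_r2[i] <- 1 - sum(wi * (yl - fit_l)^2) / tss_l
  }
  if (fails > 0.10 * n)
    stop("local design rank-deficient at ", fails, " of ", n,
         " locations (> 10%)", call. = FALSE)
  if (fails > 0)
    warning(fails, " location(s) had rank-deficient local designs; ",
            "their coefficients are NA", call. = FALSE)
  list(beta = beta, se_factor = se, hat = hat, local_r2 = local_r2,
       fails = fails)
}

# Gaussian AIC on the effective-parameter scale shared by OLS and GWR.
.gaussian_aic <- function(rss, n, enp) {
  n * log(rss / n) + n * log(2 * pi) + n + enp
}
.gaussian_aicc <- function(rss, n, enp) {
  n * log(rss / n) + n * log(2 * pi) + n * (n + enp) / (n - 2 - enp)
}

#' Geographically weighted regression
#'
#' Fits, at every cell center, a locally weighted least-squares regression
#' `beta(u_i, v_i) = (X' W_i X)^{-1} X' W_i y` with diagonal bi-square
#' kernel weights on the Euclidean distances from cell i. With an adaptive
#' bandwidth, the kernel reach at cell i is the distance to its k-th nearest
#' observation (self included), so dense areas get tight kernels and sparse
#' areas wide ones. Reported diagnostics: per-cell coefficients and standard
#' errors, hat-matrix trace `tr(S)` (effective parameters), AIC / AICc on
#' the Gaussian scale, global and adjusted R-squared, per-cell local
#' R-squared, and internally studentized residuals
#' `e_i / (sigma_hat sqrt(1 - h_ii))`.
#'
#' @param grid A [fishnet_grid()] or data.frame with `u`, `v` columns.
#' @param y_var Response column name.
#' @param x_vars Predictor column name(s).
#' @param kernel A [kernel_spec()].
#' @return Object of class `gwr_result`.
#' @export
gwr_fit <- function(grid, y_var, x_vars, kernel) {
  df <- if (inherits(grid, "fishnet_grid")) grid$cells else grid
  stopifnot(inherits(kernel, "kernel_spec"))
  miss <- setdiff(c(y_var, x_vars, "u", "v"), names(df))
  if (length(miss))
    stop("unknown column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  prep <- .gwr_prep(df, y_var, x_vars)
  if (kernel$bandwidth_mode == "adaptive" &&
      kernel$bandwidth < prep$p + 2)
    stop("adaptive bandwidth must be >= number of predictors + 2 (",
         prep$p + 2, ")", call. = FALSE)
  sol <- .gwr_solve(prep, kernel)
  .gwr_result(prep, sol, kernel, y_var, x_vars, df)
}

.gwr_result <- function(prep, sol, kernel, y_var, x_vars, df) {
  n <- prep$n
  fitted <- rowSums(prep$X * sol$beta)
  resid <- prep$y - fitted
  ok <- !is.na(fitted)
  rss <- sum(resid[ok]^2)
  tr_s <- sum(sol$hat[ok])
  enp <- tr_s
  sigma2 <- rss / (sum(ok) - enp)
  se <- sol$se_factor * sqrt(sigma2)
  denom <- 1 - sol$hat
  denom[!is.na(denom) & denom <= 0] <- NA
  std_res <- resid / sqrt(sigma2 * denom)
  tss <- sum((prep$y[ok] - mean(prep$y[ok]))^2)
  r2 <- 1 - rss / tss
  adj_r2 <- 1 - (1 - r2) * (sum(ok) - 1) / (sum(ok) - enp)
  structure(list(
    coefficients = sol$beta, se = se, fitted = fitted, residuals = resid,
    std_residuals = std_res, hat = sol$hat, tr_s = tr_s, enp = enp,
    local_r2 = sol$local_r2,
    aic = .gaussian_aic(rss, sum(ok), enp),
    aicc = .gaussian_aicc(rss, sum(ok), enp),
    r_squared = r2, adj_r_squared = adj_r2,
    sigma2 = sigma2, rss = rss, n = n, n_fit = sum(ok),
    kernel = kernel, y_var = y_var, x_vars = x_vars,
    u = df$u, v = df$v, id = df$id
  ), class = "gwr_result")
}

#' @export
print.gwr_result <- function(x, ...) {
  cat(sprintf("GWR: %s ~ %s  (n = %d, %s bandwidth = %g, bi-square)\n",
              x$y_var, paste(x$x_vars, collapse = " + "), x$n,
              x$kernel$bandwidth_mode, x$kernel$bandwidth))
  cat("Local coefficient quartiles:\n")
  print(apply(x$coefficients, 2L, stats::quantile,
              probs = c(0, .25, .5, .75, 1), na.rm = TRUE), digits = 4)
  cat(sprintf("tr(S) = %.2f   AIC = %.3f   AICc = %.3f   adj R2 = %.4f\n",
              x$tr_s, x$aic, x$aicc, x$adj_r_squared))
  invisible(x)
}

#' Select the GWR bandwidth
#'
#' Minimizes the small-sample-corrected `aicc` (default), the plain
#' Gaussian `aic`, or the leave-one-out `cv` score over the bandwidth.
#' AICc is the default because the plain-AIC penalty (`+ tr(S)`) cannot
#' counter the vanishing residual variance of near-interpolating local
#' fits, so minimizing it drives the bandwidth to degenerate small values;
#' the corrected form is what mainstream GWR implementations minimize. Adaptive bandwidths are searched on the integer neighbor
#' counts in `[p + 2, n]` by golden section (with deterministic rounding and
#' a final exhaustive sweep of the closing bracket), or exhaustively with
#' `search = "grid"`. If the profile is not unimodal the minimum over all
#' evaluated points is returned with a warning.
#'
#' @param grid,y_var,x_vars As in [gwr_fit()].
#' @param kernel_kind Only `"bisquare"`.
#' @param criterion `"aic"`, `"aicc"` or `"cv"`.
#' @param search `"golden"` or `"grid"`.
#' @param bandwidth_mode Only `"adaptive"` selection is supported.
#' @return List with `bandwidth` (integer neighbor count), `criterion`,
#'   `score`, and `profile` (data.frame of evaluated bandwidths and scores).
#' @export
select_bandwidth <- function(grid, y_var, x_vars, kernel_kind = "bisquare",
                             criterion = c("aicc", "aic", "cv"),
                             search = c("golden", "grid"),
                             bandwidth_mode = "adaptive") {
  criterion <- match.arg(criterion)
  search <- match.arg(search)
  stopifnot(identical(bandwidth_mode, "adaptive"),
            identical(kernel_kind, "bisquare"))
  df <- if (inherits(grid, "fishnet_grid")) grid$cells else grid
  prep <- .gwr_prep(df, y_var, x_vars)
  n <- prep$n
  kmin <- prep$p + 2L
  kmax <- n
  cache <- new.env(parent = emptyenv())
  score_at <- function(k) {
    key <- as.character(k)
    if (!is.null(cache[[key]])) return(cache[[key]])
    kern <- kernel_spec("bisquare", "adaptive", k)
    # infeasible bandwidths (e.g. lattice distance ties leaving too few
    # nonzero weights) score Inf instead of aborting the search
    s <- if (criterion == "cv") .gwr_cv(prep, kern) else {
      tryCatch({
        sol <- suppressWarnings(.gwr_solve(prep, kern))
        fitted <- rowSums(prep$X * sol$beta)
        ok <- !is.na(fitted)
        rss <- sum((prep$y[ok] - fitted[ok])^2)
        enp <- sum(sol$hat[ok])
        if (criterion == "aic") .gaussian_aic(rss, sum(ok), enp)
        else .gaussian_aicc(rss, sum(ok), enp)
      }, error = function(e) Inf)
    }
    cache[[key]] <- s
    s
  }

  if (search == "grid" || kmax - kmin <= 12L) {
    for (k in kmin:kmax) score_at(k)
  } else {
    phi <- (sqrt(5) - 1) / 2
    lo <- kmin; hi <- kmax
    x1 <- as.integer(round(hi - phi * (hi - lo)))
    x2 <- as.integer(round(lo + phi * (hi - lo)))
    while (hi - lo > 4L) {
      if (x1 == x2) x2 <- x1 + 1L
      # strict <: an Inf-Inf tie (infeasible small k) must move `lo` upward
      if (score_at(x1) < score_at(x2)) hi <- x2 else lo <- x1
      x1 <- as.integer(round(hi - phi * (hi - lo)))
      x2 <- as.integer(round(lo + phi * (hi - lo)))
    }
    for (k in lo:hi) score_at(k)
  }
  ks <- sort(as.integer(ls(cache)))
  scores <- vapply(as.character(ks), function(k) cache[[k]], numeric(1))
  best <- ks[which.min(scores)]
  # flag non-unimodality over the evaluated profile
  fin <- is.finite(scores)
  ds <- diff(scores[fin])
  sgn <- sign(ds[ds != 0])
  if (isTRUE(any(diff(sgn) < 0)))  # a rise followed by a fall = second valley
    warning("criterion profile not unimodal over evaluated bandwidths; ",
            "returning the minimum over evaluated points", call. = FALSE)
  list(bandwidth = best, criterion = criterion,
       score = min(scores),
       profile = data.frame(bandwidth = ks, score = unname(scores)))
}

# Leave-one-out CV score: self-weight zeroed at each location.
.gwr_cv <- function(prep, kernel) {
  n <- prep$n; X <- prep$X; y <- prep$y
  p1 <- ncol(X)
  err2 <- 0
  for (i in seq_len(n)) {
    b_i <- if (kernel$bandwidth_mode == "adaptive")
      prep$Dsort[min(kernel$bandwidth, n), i] else kernel$bandwidth
    w <- bisquare_weight(prep$D[, i], b_i)
    w[i] <- 0
    idx <- which(w > 0)
    if (length(idx) < p1) return(Inf)
    Xi <- X[idx, , drop = FALSE]; wi <- w[idx]
    A <- crossprod(Xi * wi, Xi)
    bi <- tryCatch(solve(A, crossprod(Xi * wi, y[idx])),
                   error = function(e) NULL)
    if (is.null(bi)) return(Inf)
    err2 <- err2 + (y[i] - drop(X[i, ] %*% bi))^2
  }
  err2
}

#' Summarize a local coefficient surface
#'
#' Descriptive statistics of one local coefficient over valid locations —
#' the per-coefficient summary row of a GWR report — plus the share of
#' locations whose internally studentized residual lies inside (-2.5, 2.5)
#' (the conventional high-reliability band) and the shares of positive and
#' negative local coefficients (the positive/negative-correlation-area
#' statistic).
#'
#' @param result A [gwr_fit()] result.
#' @param coefficient_var Coefficient name (one of `colnames(result$coefficients)`).
#' @return List with `min`, `max`, `mean`, `std_err` (SD of the local
#'   estimates across locations), `pct_stdres_in_band`, `pct_positive`,
#'   `pct_negative`.
#' @export
summarize_gwr <- function(result, coefficient_var) {
  stopifnot(inherits(result, "gwr_result"))
  if (!coefficient_var %in% colnames(result$coefficients))
    stop("unknown coefficient: ", coefficient_var, "; available: ",
         paste(colnames(result$coefficients), collapse = ", "),
         call. = FALSE)
  b <- result$coefficients[, coefficient_var]
  b <- b[!is.na(b)]
  sr <- result$std_residuals
  sr <- sr[!is.na(sr)]
  list(
    min = min(b), max = max(b), mean = mean(b),
    std_err = stats::sd(b),
    pct_stdres_in_band = 100 * mean(abs(sr) < 2.5),
    pct_positive = 100 * mean(b > 0),
    pct_negative = 100 * mean(b < 0)
  )
}

#' AIC model-comparison verdict
#'
#' Two models are distinguishable when their AICs differ by more than 3;
#' the lower AIC wins.
#'
#' @param aic_ols,aic_gwr AIC values on a common likelihood scale.
#' @param threshold Difference below which models are indistinguishable.
#' @return `"GWR preferred"`, `"OLS preferred"`, or `"indistinguishable"`.
#' @export
aic_verdict <- function(aic_ols, aic_gwr, threshold = 3) {
  if (aic_gwr < aic_ols - threshold) "GWR preferred"
  else if (aic_ols < aic_gwr - threshold) "OLS preferred"
  else "indistinguishable"
}

#' Compare OLS and GWR fits
#'
#' @param ols A [fit_ols()] result.
#' @param gwr A [gwr_fit()] result on the same cells and variables.
#' @return List with a `table` (adjusted R-squared and AIC per model),
#'   `delta_aic` (`AIC_GWR - AIC_OLS`) and `verdict` per [aic_verdict()].
#' @export
compare_models <- function(ols, gwr) {
  stopifnot(inherits(ols, "ols_result"), inherits(gwr, "gwr_result"))
  if (ols$n != gwr$n || !identical(ols$x_vars, gwr$x_vars) ||
      !identical(ols$y_var, gwr$y_var))
    stop("models were not fitted on the same cells/variables", call. = FALSE)
  tab <- data.frame(
    model = c("OLS", "GWR"),
    adj_r_squared = c(ols$adj_r_squared, gwr$adj_r_squared),
    aic = c(ols$aic, gwr$aic)
  )
  list(table = tab, delta_aic = gwr$aic - ols$aic,
       verdict = aic_verdict(ols$aic, gwr$aic))
}
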