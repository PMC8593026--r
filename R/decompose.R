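#' Estimate the full-vegetation productivity baseline NPP_fv
#'
#' `NPP_fv` is the productivity a cell would have under ideal full vegetation
#' cover before urbanization; it is assumed constant over time. Two modes:
#' \describe{
#'   \item{`supplied`}{pass through an existing `npp_fv` column (e.g. a
#'     ground-truth surface or an external raster aggregated onto the grid).}
#'   \item{`low_beta_mean`}{for each cell, the mean of `npp_t0` over
#'     near-pristine cells (`beta_t0 <= beta_threshold`) within
#'     `neighborhood_radius` meters; cells with no such neighbor fall back to
#'     the global low-beta mean.}
#' }
#'
#' @param grid A [fishnet_grid()] with columns `beta_t0`, `npp_t0` (and
#'   `npp_fv` for `mode = "supplied"`).
#' @param mode `"low_beta_mean"` (default) or `"supplied"`.
#' @param beta_threshold Impervious fraction below which a cell counts as
#'   unurbanized (default 0.05).
#' @param neighborhood_radius Radius in meters (default 5000; `Inf` uses the
#'   global low-beta mean everywhere).
#' @return Numeric vector of per-cell `NPP_fv`, in the row order of
#'   `grid$cells`.
#' @export
estimate_npp_fv <- function(grid, mode = c("low_beta_mean", "supplied"),
                            beta_threshold = 0.05,
                            neighborhood_radius = 5000) {
  stopifnot(inherits(grid, "fishnet_grid"))
  mode <- match.arg(mode)
  cells <- grid$cells
  if (mode == "supplied") {
    if (!"npp_fv" %in% names(cells))
      stop("mode = 'supplied' requires an `npp_fv` column", call. = FALSE)
    return(cells$npp_fv)
  }
  for (need in c("beta_t0", "npp_t0"))
    if (!need %in% names(cells))
      stop("mode = 'low_beta_mean' requires a `", need, "` column",
           call. = FALSE)
  low <- which(cells$beta_t0 <= beta_threshold & !is.na(cells$npp_t0))
  if (!length(low))
    stop("no cell has beta_t0 <= ", beta_threshold,
         "; increase `beta_threshold`", call. = FALSE)
  global_mean <- mean(cells$npp_t0[low])
  if (!is.finite(neighborhood_radius))
    return(rep(global_mean, nrow(cells)))
  lu <- cells$u[low]; lv <- cells$v[low]; lnpp <- cells$npp_t0[low]
  r2 <- neighborhood_radius^2
  out <- vapply(seq_len(nrow(cells)), function(i) {
    d2 <- (lu - cells$u[i])^2 + (lv - cells$v[i])^2
    sel <- d2 <= r2
    if (any(sel)) mean(lnpp[sel]) else global_mean
  }, numeric(1))
  out
}

.check_beta <- function(beta, what = "beta") {
  bad <- !is.na(beta) & (beta < 0 | beta > 1)
  if (any(bad))
    stop("`", what, "` must lie in [0, 1]; offending value(s) e.g. ",
         format(beta[bad][1]), call. = FALSE)
  invisible(beta)
}

#' Hypothetical productivity under land-cover change only
#'
#' `NPP_h = (1 - beta) * NPP_fv`: the productivity a cell would show if
#' urbanization acted solely by replacing vegetated surface with impervious
#' surface, with no change in growth conditions.
#'
#' @param beta_t Impervious fraction in `[0, 1]` at time t.
#' @param npp_fv Full-vegetation baseline, gC m-2 yr-1.
#' @return `(1 - beta_t) * npp_fv`, elementwise.
#' @export
compute_npp_h <- function(beta_t, npp_fv) {
  .check_beta(beta_t, "beta_t")
  (1 - beta_t) * npp_fv
}

#' Direct urbanization impact on productivity
#'
#' `NPP_dir(t1) = (beta(t0) - beta(t1)) * NPP_fv`: the productivity change
#' attributable purely to the change in impervious cover between the baseline
#' year and t1. Negative where impervious surface expanded; zero where beta
#' is unchanged; positive under de-urbanization.
#'
#' @param beta_t0,beta_t1 Impervious fractions in `[0, 1]`.
#' @param npp_fv Full-vegetation baseline.
#' @return Per-cell direct impact, gC m-2 yr-1.
#' @export
compute_npp_dir <- function(beta_t0, beta_t1, npp_fv) {
  if (length(beta_t0) != length(beta_t1) ||
      length(beta_t1) != length(npp_fv))
    stop("beta_t0, beta_t1 and npp_fv must have equal length", call. = FALSE)
  .check_beta(beta_t0, "beta_t0"); .check_beta(beta_t1, "beta_t1")
  (beta_t0 - beta_t1) * npp_fv
}

#' Indirect urbanization impact on productivity
#'
#' `NPP_ind(t1) = NPP(t1) - (1 - beta(t1)) * NPP_fv`: the residual
#' productivity change after accounting for land-cover replacement,
#' attributed to altered growth conditions (urban warming, management, CO2,
#' nutrient deposition). Positive where observed productivity exceeds the
#' land-cover-only expectation.
#'
#' @param npp_t1 Observed productivity at t1, gC m-2 yr-1.
#' @param beta_t1 Impervious fraction at t1, in `[0, 1]`.
#' @param npp_fv Full-vegetation baseline.
#' @return Per-cell indirect impact, gC m-2 yr-1.
#' @export
compute_npp_ind <- function(npp_t1, beta_t1, npp_fv) {
  if (length(npp_t1) != length(beta_t1) ||
      length(beta_t1) != length(npp_fv))
    stop("npp_t1, beta_t1 and npp_fv must have equal length", call. = FALSE)
  .check_beta(beta_t1, "beta_t1")
  npp_t1 - (1 - beta_t1) * npp_fv
}

#' Add the impact decomposition to a fishnet grid
#'
#' Convenience wrapper: estimates (or passes through) `npp_fv`, then adds
#' `npp_h` (hypothetical productivity at t1), `npp_dir`, `npp_ind`, and the
#' baseline-consistency diagnostic `resid_t0 = npp_t0 - (1 - beta_t0) *
#' npp_fv`. Where `resid_t0 = 0` the decomposition satisfies
#' `npp_dir + npp_ind = npp_t1 - npp_t0` exactly.
#'
#' @param grid A [fishnet_grid()] with `beta_t0`, `beta_t1`, `npp_t0`,
#'   `npp_t1` columns.
#' @param npp_fv_mode,beta_threshold,neighborhood_radius Passed to
#'   [estimate_npp_fv()].
#' @return The grid with columns `npp_fv`, `npp_h`, `npp_dir`, `npp_ind`,
#'   `resid_t0` added.
#' @export
decompose_impacts <- function(grid, npp_fv_mode = "low_beta_mean",
                              beta_threshold = 0.05,
                              neighborhood_radius = 5000) {
  stopifnot(inherits(grid, "fishnet_grid"))
  need <- c("beta_t0", "beta_t1", "npp_t0", "npp_t1")
  miss <- setdiff(need, names(grid$cells))
  if (length(miss))
    stop("grid lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  fv <- estimate_npp_fv(grid, mode = npp_fv_mode,
                        beta_threshold = beta_threshold,
                        neighborhood_radius = neighborhood_radius)
  cells <- grid$cells
  cells$npp_fv <- fv
  cells$npp_h <- compute_npp_h(cells$beta_t1, fv)
  cells$npp_dir <- compute_npp_dir(cells$beta_t0, cells$beta_t1, fv)
  cells$npp_ind <- compute_npp_ind(cells$npp_t1, cells$beta_t1, fv)
  cells$resid_t0 <- cells$npp_t0 - compute_npp_h(cells$beta_t0, fv)
  grid$cells <- cells
  grid
}

#' Summarize the positive indirect impact
#'
#' Counts the cells where the indirect impact is strictly positive and
#' reports min / max / mean of `npp_ind` over exactly those cells (the
#' growth-enhancement summary).
#'
#' @param grid A [fishnet_grid()] with an `npp_ind` column, or a numeric
#'   vector of `npp_ind` values.
#' @return List with `grid_count`, `min`, `max`, `mean` (the stats are `NA`
#'   when no cell is positive).
#' @export
summarize_npp_ind <- function(grid) {
  x <- if (inherits(grid, "fishnet_grid")) {
    if (!"npp_ind" %in% names(grid$cells))
      stop("grid lacks an `npp_ind` column; run decompose_impacts() first",
           call. = FALSE)
    grid$cells$npp_ind
  } else as.numeric(grid)
  pos <- x[!is.na(x) & x > 0]
  if (!length(pos))
    return(list(grid_count = 0L, min = NA_real_, max = NA_real_,
                mean = NA_real_))
  list(grid_count = length(pos), min = min(pos), max = max(pos),
       mean = mean(pos))
}
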