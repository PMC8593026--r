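#' Configuration for the synthetic-city generator
#'
#' Defines a stylized monocentric city on a square raster: an impervious
#' surface fraction (beta) that decays logistically with distance from the
#' urban core, a land surface temperature (LST) field with an urban-heat-
#' island signal proportional to beta, a full-vegetation productivity
#' baseline `NPP_fv`, and an indirect productivity response whose local
#' coefficient on the LST anomaly varies smoothly in space (positive in the
#' core, negative at the periphery). Two time points are generated: `t0`, a
#' pre-warming baseline in which productivity is purely land-cover
#' controlled, and `t1`, after urban expansion, in which the indirect
#' (growth-enhancement) term is active.
#'
#' @param grid_n Pixels per side (>= 8).
#' @param cell_size Pixel edge, meters.
#' @param core_center Core position as `(row, col)` in pixel units; default
#'   the grid center.
#' @param core_radius Logistic midpoint of the beta profile, meters.
#' @param core_softness Logistic scale of the beta profile, meters.
#' @param beta_max_t0,beta_max_t1 Peak impervious fraction at each time point
#'   (`0 <= beta_max_t0 <= beta_max_t1 <= 1`).
#' @param npp_fv_mean,npp_fv_sd Mean and per-pixel SD of the full-vegetation
#'   productivity baseline, gC m-2 yr-1.
#' @param lst_base Rural LST, degrees C.
#' @param uhi_amplitude Urban-heat-island amplitude: LST rises by this many
#'   degrees C per unit beta.
#' @param gamma_core,gamma_far Local coefficient of the indirect NPP response
#'   to the LST anomaly at the core and at infinity, gC m-2 per degree C.
#' @param gamma_scale Gaussian length scale of the gamma surface, meters.
#' @param noise_sd_npp,noise_sd_lst Independent per-pixel Gaussian noise SDs
#'   for the NPP and LST fields.
#' @param seed Integer RNG seed; fixed seed gives byte-identical output.
#' @return An object of class `city_config`.
#' @export
city_config <- function(grid_n = 120L,
                        cell_size = 250,
                        core_center = NULL,
                        core_radius = 6000,
                        core_softness = 1500,
                        beta_max_t0 = 0.45,
                        beta_max_t1 = 0.85,
                        npp_fv_mean = 600,
                        npp_fv_sd = 40,
                        lst_base = 20,
                        uhi_amplitude = 5,
                        gamma_core = 15,
                        gamma_far = -10,
                        gamma_scale = 6000,
                        noise_sd_npp = 8,
                        noise_sd_lst = 0.4,
                        seed = 1L) {
  if (is.null(core_center)) core_center <- c(grid_n / 2, grid_n / 2)
  cfg <- structure(as.list(environment()), class = "city_config")
  .validate_city_config(cfg)
  cfg
}

.validate_city_config <- function(cfg) {
  fail <- function(field, why)
    stop("invalid city_config: `", field, "` ", why, call. = FALSE)
  num1 <- function(f) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      fail(f, "must be a single finite number")
    v
  }
  if (num1("grid_n") < 8) fail("grid_n", "must be >= 8")
  if (num1("cell_size") <= 0) fail("cell_size", "must be > 0")
  if (!is.numeric(cfg$core_center) || length(cfg$core_center) != 2)
    fail("core_center", "must be a (row, col) pair")
  if (num1("core_radius") <= 0) fail("core_radius", "must be > 0")
  if (num1("core_softness") <= 0) fail("core_softness", "must be > 0")
  b0 <- num1("beta_max_t0"); b1 <- num1("beta_max_t1")
  if (b0 < 0 || b0 > 1) fail("beta_max_t0", "must lie in [0, 1]")
  if (b1 < 0 || b1 > 1) fail("beta_max_t1", "must lie in [0, 1]")
  if (b0 > b1) fail("beta_max_t0", "must not exceed beta_max_t1")
  for (f in c("npp_fv_sd", "noise_sd_npp", "noise_sd_lst"))
    if (num1(f) < 0) fail(f, "must be >= 0")
  if (num1("npp_fv_mean") < 0) fail("npp_fv_mean", "must be >= 0")
  num1("lst_base"); num1("uhi_amplitude")
  num1("gamma_core"); num1("gamma_far")
  if (num1("gamma_scale") <= 0) fail("gamma_scale", "must be > 0")
  num1("seed")
  invisible(cfg)
}

#' Generate a synthetic city raster stack
#'
#' Construction, with `d(x)` the Euclidean distance (meters) of pixel center
#' `x` from the core center and `logistic(u) = 1/(1 + exp(-u))`:
#' \itemize{
#'   \item `beta_t(x) = beta_max_t * logistic((core_radius - d(x)) / core_softness)`
#'   \item `LST_t(x) = lst_base + uhi_amplitude * beta_t(x) + noise`
#'   \item `gamma(x) = (gamma_core - gamma_far) * exp(-d(x)^2 / (2 gamma_scale^2)) + gamma_far`
#'   \item `NPP_t0(x) = (1 - beta_t0(x)) * NPP_fv(x) + noise`
#'   \item `NPP_ind_true(x) = gamma(x) * (LST_t1(x) - mean(LST_t1))`
#'   \item `NPP_t1(x) = (1 - beta_t1(x)) * NPP_fv(x) + NPP_ind_true(x) + noise`
#'   \item `NPP_dir_true(x) = (beta_t0(x) - beta_t1(x)) * NPP_fv(x)`
#' }
#' The indirect term enters at `t1` only, so that with noise off the truth
#' surfaces satisfy `NPP_t1 - NPP_t0 = NPP_dir_true + NPP_ind_true` exactly
#' and the decomposition recovers `NPP_ind_true` when fed the true `NPP_fv`.
#'
#' @param config A [city_config()].
#' @return An object of class `synthetic_city`: named [raster_layer()]s
#'   `beta_t0, beta_t1, lst_t0, lst_t1, npp_t0, npp_t1` (observables) and
#'   `npp_fv_true, gamma_true, npp_ind_true, npp_dir_true` (ground truth),
#'   plus the config.
#' @export
generate_city <- function(config = city_config()) {
  stopifnot(inherits(config, "city_config"))
  .validate_city_config(config)
  n <- as.integer(config$grid_n)
  px <- config$cell_size

  # RNG in a private stream so callers' seeds are untouched
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(config$seed))

  rowc <- matrix(rep(seq_len(n), n), n, n)          # row index
  colc <- t(rowc)                                   # col index
  d <- px * sqrt((rowc - config$core_center[1])^2 +
                 (colc - config$core_center[2])^2)

  logistic <- function(u) 1 / (1 + exp(-u))
  prof <- logistic((config$core_radius - d) / config$core_softness)
  beta_t0 <- config$beta_max_t0 * prof
  beta_t1 <- config$beta_max_t1 * prof

  gamma <- (config$gamma_core - config$gamma_far) *
    exp(-d^2 / (2 * config$gamma_scale^2)) + config$gamma_far

  npp_fv <- config$npp_fv_mean +
    config$npp_fv_sd * matrix(stats::rnorm(n * n), n, n)
  npp_fv[npp_fv < 0] <- 0

  lst_t0 <- config$lst_base + config$uhi_amplitude * beta_t0 +
    config$noise_sd_lst * matrix(stats::rnorm(n * n), n, n)
  lst_t1 <- config$lst_base + config$uhi_amplitude * beta_t1 +
    config$noise_sd_lst * matrix(stats::rnorm(n * n), n, n)

  npp_t0 <- (1 - beta_t0) * npp_fv +
    config$noise_sd_npp * matrix(stats::rnorm(n * n), n, n)
  npp_ind_true <- gamma * (lst_t1 - mean(lst_t1))
  npp_t1 <- (1 - beta_t1) * npp_fv + npp_ind_true +
    config$noise_sd_npp * matrix(stats::rnorm(n * n), n, n)
  npp_dir_true <- (beta_t0 - beta_t1) * npp_fv

  mk <- function(m) raster_layer(m, xll = 0, yll = 0, cellsize = px,
                                 crs = "LOCAL:meters")
  structure(list(
    layers = list(
      beta_t0 = mk(beta_t0), beta_t1 = mk(beta_t1),
      lst_t0 = mk(lst_t0), lst_t1 = mk(lst_t1),
      npp_t0 = mk(npp_t0), npp_t1 = mk(npp_t1)
    ),
    truth = list(
      npp_fv_true = mk(npp_fv), gamma_true = mk(gamma),
      npp_ind_true = mk(npp_ind_true), npp_dir_true = mk(npp_dir_true)
    ),
    config = config
  ), class = "synthetic_city")
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat(sprintf("<synthetic_city> %d x %d pixels @ %g m, seed = %d\n",
              x$config$grid_n, x$config$grid_n, x$config$cell_size,
              as.integer(x$config$seed)))
  cat("  observable layers:", paste(names(x$layers), collapse = ", "), "\n")
  cat("  truth layers:     ", paste(names(x$truth), collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic city to disk
#'
#' One ASCII-grid raster per layer (observables and truth surfaces) plus a
#' `manifest.json` listing filenames, CRS, pixel size and the generating
#' configuration. The layers round-trip bit-exactly through [read_raster()].
#'
#' @param city A [generate_city()] result.
#' @param directory Output directory (created if needed).
#' @return The manifest as a list, invisibly; written to
#'   `directory/manifest.json`.
#' @export
write_city <- function(city, directory) {
  stopifnot(inherits(city, "synthetic_city"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory))
    stop("cannot create directory: ", directory, call. = FALSE)
  all_layers <- c(city$layers, city$truth)
  files <- character(0)
  for (nm in names(all_layers)) {
    f <- file.path(directory, paste0(nm, ".asc"))
    write_raster(all_layers[[nm]], f)
    files[nm] <- basename(f)
  }
  manifest <- list(
    layers = as.list(files[names(city$layers)]),
    truth_layers = as.list(files[names(city$truth)]),
    crs = city$layers[[1]]$crs,
    cell_size = city$config$cell_size,
    config = unclass(city$config)
  )
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a synthetic city written by [write_city()]
#'
#' @param directory Directory containing `manifest.json`.
#' @return A `synthetic_city` object (config restored from the manifest).
#' @export
read_city <- function(directory) {
  mf <- file.path(directory, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", directory, call. = FALSE)
  manifest <- jsonlite::read_json(mf)
  rd <- function(x) read_raster(file.path(directory, x), crs = manifest$crs)
  cfg_in <- lapply(manifest$config, function(x) if (is.list(x)) unlist(x) else x)
  cfg <- do.call(city_config, cfg_in[names(formals(city_config))])
  structure(list(
    layers = lapply(manifest$layers, rd),
    truth = lapply(manifest$truth_layers, rd),
    config = cfg
  ), class = "synthetic_city")
}
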