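#' Construct a fishnet grid from a cell table
#'
#' A fishnet grid is a regular square tessellation over the study area; all
#' statistics in this package (Moran's I, LISA, OLS, GWR) operate on its cell
#' table. `cells` must contain columns `u` and `v` (projected cell-center
#' coordinates, meters) plus any number of variable columns; `id`, `row`,
#' `col` are derived when absent (`row` counted from the north).
#'
#' @param cells data.frame of cell centers and variables.
#' @param cell_size Cell edge length in meters.
#' @param crs Projected CRS identifier.
#' @return An object of class `fishnet_grid`.
#' @export
fishnet_grid <- function(cells, cell_size, crs = "LOCAL:meters") {
  stopifnot(is.data.frame(cells), all(c("u", "v") %in% names(cells)))
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("`cell_size` must be positive", call. = FALSE)
  .check_projected_crs(crs)
  if (!"col" %in% names(cells))
    cells$col <- as.integer(round((cells$u - min(cells$u)) / cell_size)) + 1L
  if (!"row" %in% names(cells))
    cells$row <- as.integer(round((max(cells$v) - cells$v) / cell_size)) + 1L
  if (!"id" %in% names(cells)) cells$id <- seq_len(nrow(cells))
  front <- c("id", "row", "col", "u", "v")
  cells <- cells[, c(front, setdiff(names(cells), front)), drop = FALSE]
  structure(list(cells = cells, cell_size = cell_size, crs = crs),
            class = "fishnet_grid")
}

#' @export
print.fishnet_grid <- function(x, ...) {
  vars <- setdiff(names(x$cells), c("id", "row", "col", "u", "v"))
  cat(sprintf("<fishnet_grid> %d cells @ %g m, crs = %s\n",
              nrow(x$cells), x$cell_size, x$crs))
  cat("  variables:", if (length(vars)) paste(vars, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Number of cells in a fishnet grid
#' @param grid A [fishnet_grid()].
#' @export
n_cells <- function(grid) nrow(grid$cells)

#' Aggregate raster layers onto a fishnet grid
#'
#' Each fishnet cell receives the mean of the valid source pixels whose
#' centers fall inside it. The grid origin is snapped to the upper-left corner
#' of the raster extent. A cell is masked for a variable when its valid-pixel
#' fraction (valid pixels over the `(cell_size / pixel)^2` a fully covered
#' cell would hold) falls below `min_valid_fraction`; a cell masked in any
#' variable is dropped from the joint table, so every downstream statistic
#' sees one common support.
#'
#' All layers must share an identical pixel grid (dimensions, origin, pixel
#' size, CRS), i.e. be co-registered. `cell_size` need not be an integer
#' multiple of the pixel size: assignment is by pixel center either way, and
#' reduces to exact block means when it is a multiple.
#'
#' @param layers Named list of [raster_layer()] objects.
#' @param cell_size Fishnet cell edge in meters (>= pixel size).
#' @param min_valid_fraction Minimum fraction of valid source pixels per cell
#'   (default 0.5).
#' @return A [fishnet_grid()] whose variables are `names(layers)`.
#' @export
aggregate_to_fishnet <- function(layers, cell_size, min_valid_fraction = 0.5) {
  if (!length(layers) || is.null(names(layers)) || any(names(layers) == ""))
    stop("`layers` must be a non-empty named list of raster_layer objects",
         call. = FALSE)
  ref <- layers[[1]]
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (!inherits(l, "raster_layer"))
      stop("layer '", nm, "' is not a raster_layer", call. = FALSE)
    if (!identical(l$crs, ref$crs))
      stop("CRS mismatch: layer '", nm, "' has '", l$crs,
           "', expected '", ref$crs, "'", call. = FALSE)
    if (!identical(dim(l$values), dim(ref$values)) ||
        l$cellsize != ref$cellsize || l$xll != ref$xll || l$yll != ref$yll)
      stop("layer '", nm, "' is not co-registered with '", names(layers)[1],
           "'", call. = FALSE)
  }
  px <- ref$cellsize
  if (cell_size < px)
    stop("`cell_size` (", cell_size, ") must be >= the pixel size (", px, ")",
         call. = FALSE)
  nr <- nrow(ref$values); nc <- ncol(ref$values)
  ytop <- ref$yll + nr * px
  cc <- raster_coords(ref)
  # fishnet index of each pixel, by pixel center, row-major from the NW corner
  gcol <- pmin(as.integer(floor((cc$x - ref$xll) / cell_size)) + 1L,
               ngc <- as.integer(ceiling(nc * px / cell_size)))
  grow <- pmin(as.integer(floor((ytop - cc$y) / cell_size)) + 1L,
               ngr <- as.integer(ceiling(nr * px / cell_size)))
  idx <- matrix(0L, nr, nc)
  for (j in seq_len(nc)) idx[, j] <- (grow - 1L) * ngc + gcol[j]
  idxv <- as.vector(idx)
  full <- (cell_size / px)^2
  ncell <- ngr * ngc

  means <- list(); valid <- matrix(TRUE, ncell, length(layers))
  for (k in seq_along(layers)) {
    v <- as.vector(layers[[k]]$values)
    ok <- !is.na(v)
    s <- rowsum(ifelse(ok, v, 0), idxv, reorder = TRUE)
    nvalid <- rowsum(as.numeric(ok), idxv, reorder = TRUE)
    m <- rep(NA_real_, ncell); nv <- rep(0, ncell)
    at <- as.integer(rownames(s))
    nv[at] <- nvalid
    m[at] <- ifelse(nvalid > 0, s / pmax(nvalid, 1), NA_real_)
    keep <- nv / full >= min_valid_fraction & nv > 0
    m[!keep] <- NA_real_
    means[[names(layers)[k]]] <- m
    valid[, k] <- keep
  }
  joint <- rowSums(valid) == length(layers)
  if (!any(joint))
    stop("no fishnet cell is valid in every layer; lower ",
         "`min_valid_fraction` or check nodata masks", call. = FALSE)
  cells <- data.frame(
    id = which(joint),
    row = (which(joint) - 1L) %/% ngc + 1L,
    col = (which(joint) - 1L) %% ngc + 1L
  )
  cells$u <- ref$xll + (cells$col - 0.5) * cell_size
  cells$v <- ytop - (cells$row - 0.5) * cell_size
  for (nm in names(means)) cells[[nm]] <- means[[nm]][joint]
  fishnet_grid(cells, cell_size = cell_size, crs = ref$crs)
}

#' Write / read a fishnet cell table as CSV
#'
#' The CSV holds one row per (unmasked) cell with `id,row,col,u,v` and all
#' variable columns; grid metadata (cell size, CRS) travels in a
#' `<path>.aux.json` sidecar so the table round-trips losslessly.
#'
#' @param grid A [fishnet_grid()].
#' @param path Output CSV path.
#' @return `path` invisibly (`write`), or a [fishnet_grid()] (`read`).
#' @export
write_fishnet_csv <- function(grid, path) {
  stopifnot(inherits(grid, "fishnet_grid"))
  if (!nrow(grid$cells)) stop("fishnet grid is empty", call. = FALSE)
  utils::write.csv(grid$cells, path, row.names = FALSE)
  jsonlite::write_json(list(cell_size = grid$cell_size, crs = grid$crs),
                       paste0(path, ".aux.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fishnet_csv
#' @param cell_size,crs Metadata fallbacks when no sidecar is present.
#' @export
read_fishnet_csv <- function(path, cell_size = NULL, crs = "LOCAL:meters") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cells <- utils::read.csv(path)
  side <- paste0(path, ".aux.json")
  if (file.exists(side)) {
    aux <- jsonlite::read_json(side)
    if (!is.null(aux$cell_size)) cell_size <- aux$cell_size
    if (!is.null(aux$crs)) crs <- aux$crs
  }
  if (is.null(cell_size))
    stop("cell_size unknown: no sidecar next to ", path,
         " and none supplied", call. = FALSE)
  fishnet_grid(cells, cell_size = cell_size, crs = crs)
}

#' Export fishnet cells as GeoJSON square polygons
#'
#' Writes a FeatureCollection of cell squares (coordinates in the projected
#' CRS of the grid) carrying the requested variables as properties — the
#' format used for cluster and coefficient maps.
#'
#' @param grid A [fishnet_grid()].
#' @param path Output `.geojson` path.
#' @param vars Variable columns to attach (default: all).
#' @return `path`, invisibly.
#' @export
write_fishnet_geojson <- function(grid, path, vars = NULL) {
  stopifnot(inherits(grid, "fishnet_grid"))
  cells <- grid$cells
  meta <- c("id", "row", "col", "u", "v")
  if (is.null(vars)) vars <- setdiff(names(cells), meta)
  if (!all(vars %in% names(cells)))
    stop("unknown variable(s): ",
         paste(setdiff(vars, names(cells)), collapse = ", "), call. = FALSE)
  h <- grid$cell_size / 2
  feats <- lapply(seq_len(nrow(cells)), function(i) {
    u <- cells$u[i]; v <- cells$v[i]
    ring <- list(c(u - h, v - h), c(u + h, v - h), c(u + h, v + h),
                 c(u - h, v + h), c(u - h, v - h))
    props <- c(list(id = cells$id[i]),
               as.list(cells[i, vars, drop = FALSE]))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = props)
  })
  jsonlite::write_json(
    list(type = "FeatureCollection",
         crs = list(type = "name",
                    properties = list(name = grid$crs)),
         features = feats),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
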