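#' Construct a raster layer
#'
#' A minimal in-memory single-band raster: a numeric matrix on a north-up
#' square-pixel grid in a projected (metric) coordinate reference system.
#' Row 1 of `values` is the northernmost row. Missing cells are `NA`.
#'
#' @param values Numeric matrix of cell values (`NA` = nodata).
#' @param xll,yll Coordinates (meters) of the lower-left corner of the extent.
#' @param cellsize Pixel edge length in meters (> 0).
#' @param crs Character identifier of the projected CRS. Anything that looks
#'   geographic (lon/lat degrees) is rejected, since all distances in this
#'   package are Euclidean meters.
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(values, xll = 0, yll = 0, cellsize = 1,
                         crs = "LOCAL:meters") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.finite(cellsize) || cellsize <= 0)
    stop("`cellsize` must be a finite positive number", call. = FALSE)
  .check_projected_crs(crs)
  structure(
    list(values = values, xll = xll, yll = yll,
         cellsize = cellsize, crs = crs),
    class = "raster_layer"
  )
}

.check_projected_crs <- function(crs) {
  if (grepl("longlat|latlon|4326|4269|degree|WGS ?84(?!.*UTM)", crs,
            ignore.case = TRUE, perl = TRUE))
    stop("geographic (degree) CRS '", crs,
         "' is not supported; supply rasters on a projected metric CRS",
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_layer> %d x %d pixels @ %g m, crs = %s\n",
              nrow(v), ncol(v), x$cellsize, x$crs))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$xll, x$xll + ncol(v) * x$cellsize,
              x$yll, x$yll + nrow(v) * x$cellsize))
  cat(sprintf("  values: [%g, %g], %d nodata cells\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)),
              sum(is.na(v))))
  invisible(x)
}

#' Coordinates of pixel centers
#'
#' @param layer A `raster_layer`.
#' @return List with numeric vectors `x` (by column) and `y` (by row, row 1 =
#'   north) of pixel-center coordinates in meters.
#' @export
raster_coords <- function(layer) {
  nr <- nrow(layer$values); nc <- ncol(layer$values)
  ytop <- layer$yll + nr * layer$cellsize
  list(
    x = layer$xll + (seq_len(nc) - 0.5) * layer$cellsize,
    y = ytop - (seq_len(nr) - 0.5) * layer$cellsize
  )
}

#' Read a raster from an ESRI ASCII grid file
#'
#' Reads the plain-text `.asc` interchange format (header of
#' `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` followed by
#' row-major values, northernmost row first). The format carries no CRS; if a
#' `<path>.aux.json` sidecar written by [write_raster()] is present its CRS is
#' used, otherwise `crs` applies. Rotated or rectangular-pixel georeferencing
#' is not representable in this format and therefore cannot occur.
#'
#' @param path Path to an `.asc` file.
#' @param crs Fallback CRS identifier when no sidecar is found.
#' @return A [raster_layer()]. An all-nodata file yields a layer whose valid
#'   mask is empty, with a warning.
#' @export
read_raster <- function(path, crs = "LOCAL:meters") {
  if (!file.exists(path))
    stop("raster file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  nhdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      nhdr <- nhdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  vals <- scan(path, what = double(), skip = nhdr, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("expected ", nr * nc, " values in ", path, ", got ", length(vals),
         call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  side <- paste0(path, ".aux.json")
  if (file.exists(side)) {
    aux <- jsonlite::read_json(side)
    if (!is.null(aux$crs)) crs <- aux$crs
  }
  if (all(is.na(m)))
    warning("raster ", path, " contains no valid cells", call. = FALSE)
  raster_layer(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
               cellsize = hdr$cellsize, crs = crs)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' Values are written with 17 significant digits so that a read/write cycle
#' reproduces the doubles bit-exactly. A `<path>.aux.json` sidecar records the
#' CRS.
#'
#' @param layer A [raster_layer()].
#' @param path Output path (conventionally `.asc`).
#' @param nodata Sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_raster <- function(layer, path, nodata = -9999) {
  stopifnot(inherits(layer, "raster_layer"))
  v <- layer$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", layer$xll),
    sprintf("yllcorner %.10g", layer$yll),
    sprintf("cellsize %.10g", layer$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  writeLines(apply(v, 1L, function(r) paste(sprintf("%.17g", r),
                                            collapse = " ")), con)
  jsonlite::write_json(list(crs = layer$crs, cellsize = layer$cellsize),
                       paste0(path, ".aux.json"), auto_unbox = TRUE)
  invisible(path)
}
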