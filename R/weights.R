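#' Build a spatial weights structure over fishnet cells
#'
#' Neighbor schemes on the cell lattice: `queen` (8-neighborhood, default —
#' the usual choice for fishnet grids), `rook` (4-neighborhood), or `knn`
#' (k nearest cell centers by Euclidean distance; note knn weights are not
#' symmetric in general). Weights are row-standardized (`style = "W"`, each
#' nonempty row sums to 1) or left binary (`style = "B"`). Cells with no
#' neighbor (islands) are retained but flagged; an all-island structure is an
#' error.
#'
#' @param grid A [fishnet_grid()], or a data.frame with `row`,`col`,`u`,`v`.
#' @param scheme `"queen"`, `"rook"` or `"knn"`.
#' @param style `"W"` (row-standardized) or `"B"` (binary).
#' @param k Neighbor count for `scheme = "knn"`.
#' @return An object of class `spatial_weights`: neighbor index lists,
#'   weight lists, and the Cliff-Ord sums `W0` (total weight), `S1`, `S2`
#'   used by the Moran variance formulas.
#' @export
build_weights <- function(grid, scheme = c("queen", "rook", "knn"),
                          style = c("W", "B"), k = 8L) {
  scheme <- match.arg(scheme)
  style <- match.arg(style)
  cells <- if (inherits(grid, "fishnet_grid")) grid$cells else grid
  n <- nrow(cells)
  if (n < 2) stop("need at least 2 cells to build weights", call. = FALSE)

  if (scheme %in% c("queen", "rook")) {
    stopifnot(all(c("row", "col") %in% names(cells)))
    # hash occupied lattice positions for O(1) neighbor lookup
    ncol_max <- max(cells$col) + 1L
    key <- cells$row * ncol_max + cells$col
    pos <- new.env(hash = TRUE, size = n)
    for (i in seq_len(n)) assign(as.character(key[i]), i, envir = pos)
    offs <- if (scheme == "rook") {
      cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
    } else {
      cbind(rep(c(-1L, 0L, 1L), each = 3L), rep(c(-1L, 0L, 1L), 3L))
    }
    offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), , drop = FALSE]
    nb <- vector("list", n)
    for (i in seq_len(n)) {
      kk <- (cells$row[i] + offs[, 1]) * ncol_max + (cells$col[i] + offs[, 2])
      hits <- integer(0)
      for (kv in kk) {
        j <- pos[[as.character(kv)]]
        if (!is.null(j)) hits <- c(hits, j)
      }
      nb[[i]] <- sort(hits)
    }
  } else {
    stopifnot(all(c("u", "v") %in% names(cells)))
    if (k < 1 || k >= n) stop("knn `k` must be in [1, n-1]", call. = FALSE)
    nb <- vector("list", n)
    for (i in seq_len(n)) {
      d2 <- (cells$u - cells$u[i])^2 + (cells$v - cells$v[i])^2
      d2[i] <- Inf
      nb[[i]] <- sort(order(d2)[seq_len(k)])
    }
  }

  card <- lengths(nb)
  islands <- which(card == 0L)
  if (length(islands) == n)
    stop("all cells are isolated; no weights can be built", call. = FALSE)
  wts <- lapply(seq_len(n), function(i) {
    if (card[i] == 0L) numeric(0)
    else if (style == "W") rep(1 / card[i], card[i])
    else rep(1, card[i])
  })

  W <- .weights_sparse_from_lists(n, nb, wts)
  W0 <- sum(W)
  S1 <- sum((W + Matrix::t(W))^2) / 2
  rs <- Matrix::rowSums(W); cs <- Matrix::colSums(W)
  S2 <- sum((rs + cs)^2)

  structure(list(
    n = n, neighbours = nb, weights = wts, scheme = scheme, style = style,
    cardinality = card, islands = islands,
    W0 = W0, S1 = S1, S2 = S2, W = W
  ), class = "spatial_weights")
}

.weights_sparse_from_lists <- function(n, nb, wts) {
  ii <- rep.int(seq_len(n), lengths(nb))
  Matrix::sparseMatrix(i = ii, j = unlist(nb), x = unlist(wts),
                       dims = c(n, n))
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("<spatial_weights> n = %d, scheme = %s, style = %s\n",
              x$n, x$scheme, x$style))
  cat(sprintf("  links: %d (mean %.2f per cell), islands: %d\n",
              sum(x$cardinality), mean(x$cardinality), length(x$islands)))
  cat(sprintf("  W0 = %.4f, S1 = %.4f, S2 = %.4f\n", x$W0, x$S1, x$S2))
  invisible(x)
}

#' Spatial lag of a variable
#'
#' `lag_i = sum_j w_ij x_j`; `NA` for island cells.
#'
#' @param w A [build_weights()] structure.
#' @param x Numeric vector of length `w$n`.
#' @return Numeric vector of spatial lags.
#' @export
spatial_lag <- function(w, x) {
  stopifnot(inherits(w, "spatial_weights"), length(x) == w$n)
  out <- as.numeric(w$W %*% x)
  out[w$cardinality == 0L] <- NA_real_
  out
}
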