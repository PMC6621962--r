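#' Landscape raster stack
#'
#' A lightweight container for a set of co-registered single-band rasters on
#' a shared planar grid (coordinates in meters). Layers are stored as
#' matrices indexed `[row, col]` with row 1 at the *bottom* (southern) edge,
#' so that `x` increases with column and `y` increases with row. Each layer
#' is either `"categorical"` (cells in {0,1}) or `"continuous"`.
#'
#' @param layers named list of numeric matrices, all the same dimension.
#' @param resolution cell size in meters (default 30, the grain of the
#'   land-cover products the analysis assumes).
#' @param origin numeric length-2, x/y of the lower-left corner of the grid.
#' @param kind named character vector (`"categorical"` or `"continuous"`),
#'   one entry per layer. Defaults to `"continuous"` for every layer.
#' @return an object of class `landscape`.
#' @export
landscape_stack <- function(layers, resolution = 30, origin = c(0, 0),
                            kind = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1, !is.null(names(layers)))
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all layers must share the same dimensions")
  if (is.null(kind)) kind <- setNames(rep("continuous", length(layers)),
                                      names(layers))
  kind <- kind[names(layers)]
  for (nm in names(layers)) {
    v <- layers[[nm]]
    if (!all(is.finite(v))) stop("layer '", nm, "' contains non-finite values")
    if (identical(unname(kind[nm]), "categorical") && !all(v %in% c(0, 1)))
      stop("categorical layer '", nm, "' must contain only 0/1")
  }
  structure(list(layers = layers, resolution = resolution,
                 origin = as.numeric(origin), kind = kind),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  d <- dim(x$layers[[1]])
  cat("landscape stack:", length(x$layers), "layers,",
      d[1], "x", d[2], "cells at", x$resolution, "m\n")
  cat("  extent: x", x$origin[1], "-", x$origin[1] + d[2] * x$resolution,
      " y", x$origin[2], "-", x$origin[2] + d[1] * x$resolution, "m\n")
  for (nm in names(x$layers))
    cat(sprintf("  %-22s %s\n", nm, x$kind[nm]))
  invisible(x)
}

ls_dim <- function(ls) dim(ls$layers[[1]])

#' Landscape extent
#' @param ls a `landscape`.
#' @return named vector xmin/xmax/ymin/ymax in meters.
#' @export
ls_extent <- function(ls) {
  d <- ls_dim(ls)
  c(xmin = ls$origin[1], xmax = ls$origin[1] + d[2] * ls$resolution,
    ymin = ls$origin[2], ymax = ls$origin[2] + d[1] * ls$resolution)
}

## row/col of the cells containing points; NA outside the grid
cell_rowcol <- function(ls, x, y) {
  d <- ls_dim(ls)
  col <- floor((x - ls$origin[1]) / ls$resolution) + 1L
  row <- floor((y - ls$origin[2]) / ls$resolution) + 1L
  bad <- col < 1L | col > d[2] | row < 1L | row > d[1]
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = row, col = col)
}

## x/y of cell centers for given rows/cols
cell_xy <- function(ls, row, col) {
  cbind(x = ls$origin[1] + (col - 0.5) * ls$resolution,
        y = ls$origin[2] + (row - 0.5) * ls$resolution)
}

#' Sample layer values at point locations
#'
#' Looks up the cell containing each point; points outside the grid get NA.
#'
#' @param ls a `landscape`.
#' @param x,y point coordinates in meters.
#' @param layers layer names (default: all).
#' @return matrix with one column per layer.
#' @export
extract_at_points <- function(ls, x, y, layers = names(ls$layers)) {
  rc <- cell_rowcol(ls, x, y)
  idx <- (rc[, "col"] - 1L) * ls_dim(ls)[1] + rc[, "row"]
  out <- vapply(layers, function(nm) ls$layers[[nm]][idx], numeric(length(x)))
  if (length(x) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, layers))
  out
}

## Banded Gaussian weight matrix for separable smoothing, truncated at
## `truncate` * sigma (in cells). Rows are smoothing targets, columns sources.
gaussian_band <- function(n, sigma_cells, truncate = 3) {
  if (sigma_cells <= 0) return(diag(n))
  r <- ceiling(truncate * sigma_cells)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  k <- exp(-d^2 / (2 * sigma_cells^2))
  k[d > r] <- 0
  k
}

#' Gaussian-smooth a raster layer
#'
#' Separable Gaussian filter with standard deviation `sigma` (meters),
#' truncated at `truncate` standard deviations and renormalized over
#' in-raster cells, so edge cells are weighted means of the cells actually
#' present (no zero-padding bias). Truncation is per axis, i.e. the support
#' is the square `|dx|, |dy| <= truncate * sigma`.
#'
#' @param m numeric matrix (a layer).
#' @param sigma standard deviation in meters.
#' @param resolution cell size in meters.
#' @param truncate support half-width in standard deviations (default 3).
#' @return smoothed matrix, same dimension.
#' @export
gaussian_smooth <- function(m, sigma, resolution = 30, truncate = 3) {
  sc <- sigma / resolution
  if (sc <= 1e-9) return(m)
  Kr <- gaussian_band(nrow(m), sc, truncate)
  Kc <- gaussian_band(ncol(m), sc, truncate)
  num <- Kr %*% m %*% Kc             # Kc symmetric
  den <- rowSums(Kr) %o% colSums(Kc)
  num / den
}

#' Write / read a layer as an ESRI ASCII grid
#'
#' Plain-text single-band raster interchange. Rows in the file run north to
#' south, so the matrix is flipped on the way in and out.
#'
#' @param ls a `landscape`.
#' @param layer layer name.
#' @param path file path.
#' @export
write_ascii_grid <- function(ls, layer, path) {
  m <- ls$layers[[layer]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", ls$origin[1]), paste("yllcorner", ls$origin[2]),
    paste("cellsize", ls$resolution), "NODATA_value -9999"), con)
  write.table(m[rev(seq_len(nrow(m))), , drop = FALSE], con,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param path file path.
#' @return for `read_ascii_grid`, a list with `matrix`, `resolution`, `origin`.
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  m <- as.matrix(read.table(path, skip = 6L))
  dimnames(m) <- NULL
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  list(matrix = m, resolution = unname(h["cellsize"]),
       origin = unname(c(h["xllcorner"], h["yllcorner"])))
}
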