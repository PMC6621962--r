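## Predictive movement surfaces: per-bear exponential SSF projection,
## inverse-distance-from-centroid weighting with per-pixel normalization,
## Boyce-index validation and surface comparison.

movement_surface <- function(values, ls, provenance = "combined",
                             season = "all", diel = "all") {
  stopifnot(all(is.finite(values)), all(values >= 0))
  structure(list(values = values, resolution = ls$resolution,
                 origin = ls$origin, provenance = provenance,
                 season = season, diel = diel),
            class = "movement_surface")
}

#' @export
print.movement_surface <- function(x, ...) {
  cat("relative movement-probability surface (", x$provenance, ",",
      x$season, "/", x$diel, ")\n")
  cat("  ", nrow(x$values), "x", ncol(x$values), "cells; value range",
      format(range(x$values), digits = 4), "\n")
  invisible(x)
}

#' Project a fitted SSF across the landscape
#'
#' Each retained covariate raster is Gaussian-smoothed at the variable's
#' characteristic scale (mirroring how availability entered the model),
#' standardized with the stored fit-time constants, combined linearly with
#' the fitted coefficients and exponentiated:
#' `w(x) = exp(b1 x1 + ... + bp xp)`. A null model gives a constant
#' surface of 1.
#'
#' @param model a `bear_ssf`.
#' @param ls a `landscape` containing every model variable.
#' @return a `movement_surface`.
#' @export
predict_bear_surface <- function(model, ls) {
  d <- ls_dim(ls)
  lp <- matrix(0, d[1], d[2])
  if (length(model$variables)) {
    if (!all(model$variables %in% names(ls$layers)))
      stop("landscape lacks model variables: ",
           paste(setdiff(model$variables, names(ls$layers)), collapse = ", "))
    if (any(!is.finite(model$z$sd)) || any(model$z$sd == 0))
      stop("missing standardization constants")
    for (i in seq_along(model$variables)) {
      v <- model$variables[i]
      sm <- gaussian_smooth(ls$layers[[v]], model$scales[[v]], ls$resolution)
      lp <- lp + model$beta[[v]] * (sm - model$z$mean[i]) / model$z$sd[i]
    }
  }
  movement_surface(exp(lp), ls, provenance = as.character(model$bear_id),
                   season = model$season, diel = model$diel)
}

#' @export
predict.bear_ssf <- function(object, ls, ...) predict_bear_surface(object, ls)

#' Combine per-bear surfaces by inverse centroid distance
#'
#' Each bear's weight at a pixel is the inverse of the distance to its
#' home-range centroid, floored at half a pixel width; weights are
#' normalized per pixel to sum to one, and the combined surface is the
#' weighted sum of the per-bear surfaces (a per-pixel convex combination).
#'
#' @param surfaces list of `movement_surface`s on a shared grid.
#' @param centroids matrix/data.frame of centroid `x, y` (one row per
#'   surface), e.g. from [estimate_kde_home_range()].
#' @return a combined `movement_surface`; per-bear weight rasters are kept
#'   in attribute `"weights"`.
#' @export
weight_and_combine <- function(surfaces, centroids) {
  stopifnot(length(surfaces) >= 1)
  centroids <- as.matrix(centroids)
  v1 <- surfaces[[1]]
  d <- dim(v1$values); res <- v1$resolution
  xmax <- v1$origin[1] + d[2] * res; ymax <- v1$origin[2] + d[1] * res
  if (any(centroids[, 1] < v1$origin[1] | centroids[, 1] > xmax |
          centroids[, 2] < v1$origin[2] | centroids[, 2] > ymax))
    stop("centroid outside the surface grid")
  cx <- v1$origin[1] + (col(v1$values) - 0.5) * res
  cy <- v1$origin[2] + (row(v1$values) - 0.5) * res
  eps <- res / 2
  w <- lapply(seq_along(surfaces), function(b)
    1 / pmax(sqrt((cx - centroids[b, 1])^2 + (cy - centroids[b, 2])^2), eps))
  tot <- Reduce(`+`, w)
  w <- lapply(w, function(wi) wi / tot)
  comb <- Reduce(`+`, Map(function(wi, s) wi * s$values, w, surfaces))
  out <- movement_surface(comb, list(resolution = res, origin = v1$origin),
                          provenance = "combined",
                          season = v1$season, diel = v1$diel)
  attr(out, "weights") <- w
  out
}

#' Boyce index of a predictive surface
#'
#' Partitions the surface's value range into `n_bins` equal-width classes
#' and compares, per class, the proportion of hold-out points falling in it
#' with the proportion of study-area pixels in it
#' (`F_i = observed / expected`). The index is the Spearman rank
#' correlation between `F_i` and class rank; classes with no pixels are
#' omitted. Values near 1 indicate that hold-out use increases
#' monotonically with predicted preference.
#'
#' @param surface a `movement_surface`.
#' @param points data.frame of hold-out locations `x, y` (>= 50 inside the
#'   surface).
#' @param n_bins number of habitat classes (default 10).
#' @return list of class `boyce_result`: `correlation`, `table` (per-class
#'   F_i), `n_points`.
#' @export
boyce_index <- function(surface, points, n_bins = 10) {
  v <- surface$values
  res <- surface$resolution
  col <- floor((points$x - surface$origin[1]) / res) + 1L
  row <- floor((points$y - surface$origin[2]) / res) + 1L
  ok <- col >= 1 & col <= ncol(v) & row >= 1 & row <= nrow(v)
  if (sum(ok) < 50) stop("need at least 50 hold-out points inside the surface")
  pv <- v[cbind(row[ok], col[ok])]
  br <- seq(min(v), max(v), length.out = n_bins + 1)
  br[1] <- br[1] - 1e-9; br[n_bins + 1] <- br[n_bins + 1] + 1e-9
  obs <- tabulate(findInterval(pv, br, rightmost.closed = TRUE), n_bins)
  exp_ <- tabulate(findInterval(as.numeric(v), br, rightmost.closed = TRUE),
                   n_bins)
  keep <- exp_ > 0
  F_i <- (obs[keep] / sum(obs)) / (exp_[keep] / sum(exp_))
  rk <- seq_len(n_bins)[keep]
  if (length(unique(F_i)) < 2 || sum(obs > 0) <= 1) {
    warning("hold-out points concentrated in one class; index undefined")
    corr <- NA_real_
  } else corr <- suppressWarnings(cor(F_i, rk, method = "spearman"))
  structure(list(correlation = corr,
                 table = data.frame(class = rk, F = F_i,
                                    n_points = obs[keep], n_pixels = exp_[keep]),
                 n_points = sum(ok), n_bins = n_bins),
            class = "boyce_result")
}

#' @export
print.boyce_result <- function(x, ...) {
  cat("Boyce index (Spearman):", round(x$correlation, 3), "over",
      nrow(x$table), "classes,", x$n_points, "hold-out points\n")
  invisible(x)
}

#' Sample hold-out locations from a surface
#'
#' Draws cells with probability proportional to surface value (or
#' uniformly), jittered uniformly within the cell. Used to emulate hold-out
#' bears whose use follows (or ignores) a predictive surface.
#'
#' @param surface a `movement_surface`.
#' @param n number of points.
#' @param uniform if TRUE, ignore the surface values.
#' @return data.frame `x, y`.
#' @export
sample_points_from_surface <- function(surface, n, uniform = FALSE) {
  v <- surface$values
  p <- if (uniform) rep(1, length(v)) else as.numeric(v)
  cells <- sample.int(length(v), n, replace = TRUE, prob = p)
  res <- surface$resolution
  rr <- (cells - 1) %% nrow(v) + 1
  cc <- (cells - 1) %/% nrow(v) + 1
  data.frame(x = surface$origin[1] + (cc - 1 + runif(n)) * res,
             y = surface$origin[2] + (rr - 1 + runif(n)) * res)
}

#' Compare two surfaces
#'
#' Pixelwise Pearson correlation, the difference raster `A - B`, and masks
#' of the strongest differences: the top `quantile` of positive differences
#' and the top `quantile` of negative differences, each computed over its
#' own sign class.
#'
#' @param a,b `movement_surface`s on a shared grid.
#' @param quantile tail fraction for the difference masks (default 0.2).
#' @return list: `pearson`, `diff` (matrix), `pos_mask`, `neg_mask`,
#'   `max_pos_diff`, `max_neg_diff`.
#' @export
compare_surfaces <- function(a, b, quantile = 0.2) {
  stopifnot(all(dim(a$values) == dim(b$values)))
  r <- if (stats::sd(a$values) == 0 || stats::sd(b$values) == 0) {
    warning("constant surface; correlation undefined")
    NA_real_
  } else cor(as.numeric(a$values), as.numeric(b$values))
  D <- a$values - b$values
  pos <- D > 0; neg <- D < 0
  pos_mask <- matrix(FALSE, nrow(D), ncol(D))
  neg_mask <- matrix(FALSE, nrow(D), ncol(D))
  if (any(pos))
    pos_mask[pos] <- D[pos] >= stats::quantile(D[pos], 1 - quantile)
  if (any(neg))
    neg_mask[neg] <- D[neg] <= stats::quantile(D[neg], quantile)
  list(pearson = r, diff = D, pos_mask = pos_mask, neg_mask = neg_mask,
       max_pos_diff = if (any(pos)) max(D) else 0,
       max_neg_diff = if (any(neg)) min(D) else 0)
}
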