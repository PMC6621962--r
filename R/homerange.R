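#' Kernel density home range with 95% isopleth
#'
#' Bivariate Gaussian kernel density of a bear's fixes on the landscape
#' grid (normal-reference bandwidth per axis), the smallest-area level set
#' holding at least `isopleth` of the density mass, the mass-weighted
#' centroid of that set, and per-layer availability proportions inside it.
#'
#' @param fixes data.frame with `x`, `y` (>= 30 rows).
#' @param ls a `landscape` (defines the evaluation grid).
#' @param isopleth probability mass of the home-range level set (default
#'   0.95).
#' @param bandwidth optional `c(hx, hy)` passed to [MASS::kde2d()];
#'   default is the normal-reference rule per axis.
#' @param bear_id,season labels carried on the result.
#' @return object of class `home_range`: `density` and `mask` matrices on
#'   the landscape grid, `centroid`, `mass_inside`, `area_km2`,
#'   `availability` (named per-layer means within the isopleth).
#' @export
estimate_kde_home_range <- function(fixes, ls, isopleth = 0.95,
                                    bandwidth = NULL, bear_id = NA,
                                    season = NA) {
  if (nrow(fixes) < 30) stop("need at least 30 fixes")
  if (diff(range(fixes$x)) == 0 && diff(range(fixes$y)) == 0)
    stop("all fixes identical: kernel bandwidth degenerate")
  if (is.null(bandwidth)) {
    bandwidth <- c(MASS::bandwidth.nrd(fixes$x), MASS::bandwidth.nrd(fixes$y))
    if (any(bandwidth <= 0)) stop("degenerate bandwidth")
  }
  d <- ls_dim(ls); res <- ls$resolution
  lims <- c(ls$origin[1] + res / 2, ls$origin[1] + (d[2] - 0.5) * res,
            ls$origin[2] + res / 2, ls$origin[2] + (d[1] - 0.5) * res)
  kd <- MASS::kde2d(fixes$x, fixes$y, h = bandwidth, n = c(d[2], d[1]),
                    lims = lims)
  dens <- t(kd$z)                      # [row = y, col = x]
  w <- dens / sum(dens)
  o <- order(w, decreasing = TRUE)
  cum <- cumsum(w[o])
  n_in <- which(cum >= isopleth)[1]
  mask <- matrix(FALSE, d[1], d[2])
  mask[o[seq_len(n_in)]] <- TRUE
  cells <- which(mask)
  xy <- cell_xy(ls, (cells - 1) %% d[1] + 1, (cells - 1) %/% d[1] + 1)
  wt <- w[cells] / sum(w[cells])
  avail <- vapply(names(ls$layers),
                  function(nm) mean(ls$layers[[nm]][cells]), 0)
  structure(list(bear_id = bear_id, season = season, density = dens,
                 mask = mask, centroid = c(x = sum(wt * xy[, 1]),
                                           y = sum(wt * xy[, 2])),
                 mass_inside = cum[n_in],
                 area_km2 = n_in * (res / 1000)^2,
                 availability = avail),
            class = "home_range")
}

#' @export
print.home_range <- function(x, ...) {
  cat("95% kernel density home range", if (!is.na(x$bear_id))
    paste0("(bear ", x$bear_id, if (!is.na(x$season)) paste0(", ", x$season),
           ")"), "\n")
  cat("  area:", round(x$area_km2, 2), "km^2  mass inside:",
      round(x$mass_inside, 4), "\n")
  cat("  centroid:", round(x$centroid[1]), ",", round(x$centroid[2]), "m\n")
  invisible(x)
}

#' Housing density within a home range
#'
#' Houses per km^2 inside the 95% isopleth: each cell contributes its
#' density times the cell area, and the total is divided by the isopleth
#' area (equivalently, the mean cell density).
#'
#' @param hr a [estimate_kde_home_range()] result.
#' @param housing houses/km^2 matrix on the same grid.
#' @export
housing_density_in_home_range <- function(hr, housing) {
  if (sum(hr$mask) == 0) stop("isopleth has zero area")
  mean(housing[hr$mask])
}
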