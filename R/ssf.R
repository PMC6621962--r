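## Multi-scale step selection functions. 'Used' habitat is summarized in a
## 30 m uniform buffer around each observed step; 'available' habitat is a
## Gaussian-kernel weighted summary around the step at a set of candidate
## scales (kernel SDs). Each used step is paired with its available summary
## and the contrast fitted by a 1:1 matched conditional logistic
## likelihood. Characteristic scales, correlation pruning and stepwise AICc
## selection follow.

#' Candidate scale set
#'
#' Gaussian-kernel standard deviations (m) used to represent availability.
#' Either supplied directly or computed as mean distances moved over a set
#' of time horizons ([compute_scales()]).
#'
#' @param sigmas positive, strictly increasing values in meters.
#' @export
scale_set <- function(sigmas) {
  stopifnot(all(sigmas > 0), !is.unsorted(sigmas, strictly = TRUE))
  structure(as.numeric(sigmas), class = "scale_set")
}

#' Mean distance moved over time horizons
#'
#' For each horizon, the mean net displacement between positions separated
#' by that much time (within `tolerance`), pooled across bears. The result
#' is the empirical scale ladder used as Gaussian-kernel SDs.
#'
#' @param steps movement steps (`bear_id, t_start, x1, y1, x2, y2, t_end`).
#' @param horizons_min time horizons in minutes (default 45 min to 6 h).
#' @param fix_interval_min the nominal fix interval; horizons below it are
#'   refused.
#' @param tolerance time-matching tolerance, minutes.
#' @return a [scale_set()]; the per-horizon means are in attribute
#'   `"horizon_means"`.
#' @export
compute_scales <- function(steps, horizons_min = c(45, 90, 135, 180, 270, 360),
                           fix_interval_min = 45, tolerance = 2) {
  if (any(horizons_min < fix_interval_min))
    stop("horizon shorter than the fix interval")
  means <- setNames(numeric(length(horizons_min)), horizons_min)
  sums <- counts <- setNames(numeric(length(horizons_min)), horizons_min)
  for (id in unique(steps$bear_id)) {
    st <- steps[steps$bear_id == id, ]
    st <- st[order(st$t_start), ]
    tt <- as.numeric(st$t_start)
    for (k in seq_along(horizons_min)) {
      h <- horizons_min[k] * 60
      j <- findInterval(tt + h - tolerance * 60, tt) + 1L
      ok <- j <= nrow(st) & abs(tt[pmin(j, nrow(st))] - (tt + h)) <= tolerance * 60
      j <- j[ok]
      i <- which(ok)
      if (!length(i)) next
      dsp <- sqrt((st$x1[j] - st$x1[i])^2 + (st$y1[j] - st$y1[i])^2)
      sums[k] <- sums[k] + sum(dsp)
      counts[k] <- counts[k] + length(dsp)
    }
  }
  means <- sums / counts
  out <- scale_set(sort(means))
  attr(out, "horizon_means") <- means
  out
}

#' Used-habitat extraction in a uniform buffer around each step
#'
#' Cells whose centers lie within `buffer` m of the step segment are
#' collected; each layer's value is averaged over them (for a 0/1 layer the
#' proportion of the buffer in that class). Steps whose buffer contains no
#' raster cell are returned as NA rows and counted in attribute
#' `"n_dropped"`.
#'
#' @param steps step data.frame.
#' @param ls a `landscape`.
#' @param layers layer names (default all).
#' @param buffer buffer radius, m (default 30).
#' @return n_steps x n_layers matrix.
#' @export
extract_used <- function(steps, ls, layers = names(ls$layers), buffer = 30) {
  d <- ls_dim(ls); res <- ls$resolution
  out <- matrix(NA_real_, nrow(steps), length(layers),
                dimnames = list(NULL, layers))
  n_dropped <- 0L
  for (i in seq_len(nrow(steps))) {
    cells <- segment_buffer_cells(ls, steps$x1[i], steps$y1[i],
                                  steps$x2[i], steps$y2[i], buffer)
    if (!length(cells)) { n_dropped <- n_dropped + 1L; next }
    out[i, ] <- vapply(layers, function(nm) mean(ls$layers[[nm]][cells]), 0)
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

## linear indices of cells whose centers are within `buffer` of the segment
segment_buffer_cells <- function(ls, x1, y1, x2, y2, buffer) {
  d <- ls_dim(ls); res <- ls$resolution
  cmin <- max(1L, floor((min(x1, x2) - buffer - ls$origin[1]) / res) + 1L)
  cmax <- min(d[2], floor((max(x1, x2) + buffer - ls$origin[1]) / res) + 1L)
  rmin <- max(1L, floor((min(y1, y2) - buffer - ls$origin[2]) / res) + 1L)
  rmax <- min(d[1], floor((max(y1, y2) + buffer - ls$origin[2]) / res) + 1L)
  if (cmin > cmax || rmin > rmax) return(integer())
  rows <- rmin:rmax; cols <- cmin:cmax
  cx <- ls$origin[1] + (rep(cols, each = length(rows)) - 0.5) * res
  cy <- ls$origin[2] + (rep(rows, times = length(cols)) - 0.5) * res
  dd <- point_segment_distance(cx, cy, x1, y1, x2, y2)
  idx <- (rep(cols, each = length(rows)) - 1L) * d[1] +
    rep(rows, times = length(cols))
  idx[dd <= buffer]
}

## Euclidean distance from points to a segment
point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  L2 <- vx^2 + vy^2
  t <- if (L2 == 0) rep(0, length(px)) else
    pmin(1, pmax(0, ((px - x1) * vx + (py - y1) * vy) / L2))
  sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
}

#' Available-habitat extraction under a Gaussian kernel
#'
#' A Gaussian kernel of standard deviation `sigma` (m) is placed over each
#' step — centered on the cell containing the step midpoint (or start
#' point) so that the extraction is identical to sampling the
#' Gaussian-smoothed raster at the step. The kernel is truncated at
#' `truncate` SDs per axis and renormalized over in-raster cells; each
#' layer's value is its weighted mean. Steps whose kernel support misses
#' the raster entirely get NA rows.
#'
#' @param steps step data.frame.
#' @param ls a `landscape`.
#' @param sigma kernel SD in meters.
#' @param layers layer names.
#' @param truncate support half-width in SDs (default 3).
#' @param center `"midpoint"` (default) or `"start"`.
#' @return n_steps x n_layers matrix.
#' @export
extract_available <- function(steps, ls, sigma, layers = names(ls$layers),
                              truncate = 3, center = "midpoint") {
  d <- ls_dim(ls); res <- ls$resolution
  cx <- if (center == "start") steps$x1 else (steps$x1 + steps$x2) / 2
  cy <- if (center == "start") steps$y1 else (steps$y1 + steps$y2) / 2
  rc <- cell_rowcol(ls, cx, cy)
  r <- ceiling(truncate * sigma / res)
  out <- matrix(NA_real_, nrow(steps), length(layers),
                dimnames = list(NULL, layers))
  for (i in seq_len(nrow(steps))) {
    if (is.na(rc[i, 1])) next
    rows <- max(1L, rc[i, 1] - r):min(d[1], rc[i, 1] + r)
    cols <- max(1L, rc[i, 2] - r):min(d[2], rc[i, 2] + r)
    wr <- exp(-((rows - rc[i, 1]) * res)^2 / (2 * sigma^2))
    wc <- exp(-((cols - rc[i, 2]) * res)^2 / (2 * sigma^2))
    w <- wr %o% wc
    idx <- (rep(cols, each = length(rows)) - 1L) * d[1] +
      rep(rows, times = length(cols))
    sw <- sum(w)
    out[i, ] <- vapply(layers, function(nm)
      sum(w * ls$layers[[nm]][idx]) / sw, 0)
  }
  out
}

## fast equivalent of extract_available for many steps: smooth each layer
## once, then sample the kernel-center cells
extract_available_smoothed <- function(steps, ls, sigma,
                                       layers = names(ls$layers),
                                       truncate = 3, center = "midpoint") {
  cx <- if (center == "start") steps$x1 else (steps$x1 + steps$x2) / 2
  cy <- if (center == "start") steps$y1 else (steps$y1 + steps$y2) / 2
  rc <- cell_rowcol(ls, cx, cy)
  idx <- (rc[, "col"] - 1L) * ls_dim(ls)[1] + rc[, "row"]
  out <- vapply(layers, function(nm)
    gaussian_smooth(ls$layers[[nm]], sigma, ls$resolution, truncate)[idx],
    numeric(nrow(steps)))
  dimnames(out) <- list(NULL, layers)
  out
}

#' Build a paired used/available SSF design
#'
#' One stratum per step: the used summary (30 m buffer) and the available
#' summary at every candidate scale. Strata with any missing value are
#' dropped listwise.
#'
#' @param steps step data.frame.
#' @param ls a `landscape`.
#' @param scales a [scale_set()].
#' @param layers covariate layers.
#' @param buffer used-side buffer radius, m.
#' @param center kernel placement, `"midpoint"` or `"start"`.
#' @return list of class `ssf_design`: `used` (n x p), `avail` (list by
#'   scale of n x p), `scales`, `layers`, `steps` (rows kept).
#' @export
build_ssf_design <- function(steps, ls, scales, layers = names(ls$layers),
                             buffer = 30, center = "midpoint") {
  used <- extract_used(steps, ls, layers, buffer)
  avail <- lapply(scales, function(s)
    extract_available_smoothed(steps, ls, s, layers, center = center))
  names(avail) <- as.character(scales)
  ok <- stats::complete.cases(used) &
    Reduce(`&`, lapply(avail, stats::complete.cases))
  structure(list(used = used[ok, , drop = FALSE],
                 avail = lapply(avail, function(a) a[ok, , drop = FALSE]),
                 scales = as.numeric(scales), layers = layers,
                 steps = steps[ok, , drop = FALSE]),
            class = "ssf_design")
}

#' Fit a 1:1 matched conditional logistic regression
#'
#' Maximizes the paired conditional likelihood
#' `sum log[exp(b'x_used) / (exp(b'x_used) + exp(b'x_avail))]` — logistic
#' regression without intercept on within-stratum differences — by Newton's
#' method. Complete separation is detected (diverging coefficients or a
#' non-vanishing gradient) and flagged with non-finite coefficients.
#'
#' @param used,avail n x p matrices of paired covariates (standardized).
#' @param min_strata minimum strata (default 20).
#' @return list: `beta`, `se`, `loglik`, `converged`, `separated`, `n`.
#' @export
fit_conditional_logit <- function(used, avail, min_strata = 20) {
  used <- as.matrix(used); avail <- as.matrix(avail)
  n <- nrow(used)
  if (n < min_strata) stop("need at least ", min_strata, " strata")
  d <- used - avail
  p <- ncol(d)
  beta <- rep(0, p)
  converged <- FALSE
  for (it in 1:100) {
    eta <- drop(d %*% beta)
    pr <- plogis(eta)                  # P(used | pair)
    g <- drop(crossprod(d, 1 - pr))
    W <- pr * (1 - pr)
    H <- crossprod(d * sqrt(W))
    if (sqrt(sum(g^2)) < 1e-6) { converged <- TRUE; break }
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    ## dampen huge jumps (separation paths)
    if (sqrt(sum(step^2)) > 10) step <- step * 10 / sqrt(sum(step^2))
    beta <- beta + step
    if (max(abs(beta)) > 40) break
  }
  eta <- drop(d %*% beta)
  ll <- sum(log(plogis(eta)))
  ## separation: diverging estimate, or a perfect fit (every stratum
  ## predicted with near-certainty, likelihood at its supremum of 0)
  separated <- !converged || max(abs(beta)) > 30 ||
    (all(eta > 0) && ll > -1e-3)
  se <- rep(NA_real_, p)
  if (!separated) {
    W <- plogis(eta) * (1 - plogis(eta))
    H <- crossprod(d * sqrt(W))
    se <- sqrt(diag(tryCatch(solve(H), error = function(e)
      matrix(NA, p, p))))
  }
  if (separated) beta <- rep(NaN, p)
  list(beta = setNames(beta, colnames(d)), se = setNames(se, colnames(d)),
       loglik = ll, converged = converged, separated = separated, n = n)
}

#' Small-sample corrected AIC
#' @param loglik model log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of strata.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) stop("AICc undefined: n - k - 1 <= 0")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

## z-score a used/available pair over the pooled rows; returns the pair
## plus the constants, or NULL when the covariate is constant
standardize_pair <- function(u, a) {
  mu <- mean(c(u, a)); sd_ <- stats::sd(c(u, a))
  if (!is.finite(sd_) || sd_ == 0) return(NULL)
  list(u = (u - mu) / sd_, a = (a - mu) / sd_, mean = mu, sd = sd_)
}

#' Characteristic scale per variable
#'
#' Univariate conditional-logit fits for every (variable, scale); the scale
#' with the lowest AICc is the variable's characteristic scale (ties go to
#' the smaller scale). Variables that are constant or separate at every
#' scale are excluded.
#'
#' @param design an `ssf_design`.
#' @return list: `table` (variable x scale AICc matrix), `chosen`
#'   (data.frame `variable, scale, aicc`), `excluded`.
#' @export
select_characteristic_scales <- function(design) {
  vars <- design$layers
  n <- nrow(design$used)
  tab <- matrix(NA_real_, length(vars), length(design$scales),
                dimnames = list(vars, names(design$avail)))
  for (v in vars) for (s in names(design$avail)) {
    z <- standardize_pair(design$used[, v], design$avail[[s]][, v])
    if (is.null(z)) next
    f <- fit_conditional_logit(cbind(x = z$u), cbind(x = z$a))
    if (!f$separated) tab[v, s] <- aicc(f$loglik, 1, n)
  }
  keep <- rowSums(is.finite(tab)) > 0
  chosen <- do.call(rbind, lapply(vars[keep], function(v) {
    i <- which(tab[v, ] == min(tab[v, ], na.rm = TRUE))[1]  # tie -> smaller
    data.frame(variable = v, scale = design$scales[i], aicc = tab[v, i],
               stringsAsFactors = FALSE)
  }))
  list(table = tab, chosen = chosen, excluded = vars[!keep])
}

## standardized design at the characteristic scales: matrices u, a and the
## z constants per variable
design_at_scales <- function(design, chosen) {
  u <- a <- matrix(NA_real_, nrow(design$used), nrow(chosen),
                   dimnames = list(NULL, chosen$variable))
  zc <- data.frame(variable = chosen$variable, scale = chosen$scale,
                   mean = NA_real_, sd = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(chosen))) {
    v <- chosen$variable[i]; s <- as.character(chosen$scale[i])
    z <- standardize_pair(design$used[, v], design$avail[[s]][, v])
    u[, i] <- z$u; a[, i] <- z$a
    zc$mean[i] <- z$mean; zc$sd[i] <- z$sd
  }
  list(u = u, a = a, z = zc)
}

#' Prune correlated variables
#'
#' While any pair of variables (at their characteristic scales, pooled
#' used+available values) has |Pearson r| strictly above `r_max`, the
#' member with the higher univariate AICc is dropped.
#'
#' @param das output of the internal standardized design (matrices `u`,`a`).
#' @param chosen data.frame from [select_characteristic_scales()].
#' @param r_max correlation threshold (default 0.7, strict).
#' @return character vector of retained variable names.
#' @export
prune_correlated <- function(das, chosen, r_max = 0.7) {
  keep <- chosen$variable
  if (length(keep) < 2) return(keep)
  pooled <- rbind(das$u, das$a)
  repeat {
    C <- abs(stats::cor(pooled[, keep, drop = FALSE]))
    diag(C) <- 0
    if (max(C) <= r_max) break
    ij <- which(C == max(C), arr.ind = TRUE)[1, ]
    pair <- keep[ij]
    worse <- pair[which.max(chosen$aicc[match(pair, chosen$variable)])]
    keep <- setdiff(keep, worse)
    if (length(keep) < 2) break
  }
  keep
}

#' Bidirectional stepwise AICc selection
#'
#' Greedy single-move search from the null model: at each iteration the one
#' addition or removal that most reduces AICc is taken; the search stops
#' when no move reduces AICc.
#'
#' @param das standardized design (matrices `u`, `a`).
#' @param candidates candidate variable names.
#' @param n number of strata.
#' @return list: `variables`, `fit` (final [fit_conditional_logit()]),
#'   `aicc`, `null_aicc`, `improved`.
#' @export
stepwise_select <- function(das, candidates, n = nrow(das$u)) {
  null_aicc <- aicc(n * log(0.5), 0, n)
  eval_set <- function(set) {
    if (!length(set)) return(list(aicc = null_aicc, fit = NULL))
    f <- fit_conditional_logit(das$u[, set, drop = FALSE],
                               das$a[, set, drop = FALSE])
    if (f$separated) return(list(aicc = Inf, fit = f))
    list(aicc = aicc(f$loglik, length(set), n), fit = f)
  }
  current <- character()
  cur <- eval_set(current)
  repeat {
    moves <- c(lapply(setdiff(candidates, current),
                      function(v) union(current, v)),
               lapply(current, function(v) setdiff(current, v)))
    if (!length(moves)) break
    scores <- vapply(moves, function(m) eval_set(m)$aicc, 0)
    if (min(scores) >= cur$aicc - 1e-12) break
    current <- moves[[which.min(scores)]]
    cur <- eval_set(current)
  }
  list(variables = current, fit = cur$fit, aicc = cur$aicc,
       null_aicc = null_aicc, improved = length(current) > 0)
}

#' Fit a multi-scale step selection function for one bear
#'
#' The full per-bear (or per bear-season-diel) procedure: build the paired
#' design, choose each variable's characteristic scale by univariate AICc,
#' prune pairs with |r| > 0.7, run bidirectional stepwise AICc selection,
#' and refit the final model.
#'
#' @param steps movement steps for one bear (optionally one season/diel
#'   subset).
#' @param ls a `landscape`.
#' @param scales a [scale_set()].
#' @param layers candidate covariate layers.
#' @param buffer used-side buffer radius, m.
#' @param bear_id,season,diel labels carried on the model.
#' @return object of class `bear_ssf`: `variables`, `scales` (named, per
#'   variable), `beta`, `se`, `z` (standardization constants), `loglik`,
#'   `aicc`, `n`, plus the scale-selection table.
#' @export
fit_ssf <- function(steps, ls, scales, layers = names(ls$layers),
                    buffer = 30, bear_id = NA, season = "all", diel = "all") {
  design <- build_ssf_design(steps, ls, scales, layers, buffer)
  cs <- select_characteristic_scales(design)
  if (is.null(cs$chosen) || !nrow(cs$chosen))
    stop("no usable covariates for bear ", bear_id)
  das <- design_at_scales(design, cs$chosen)
  kept <- prune_correlated(das, cs$chosen)
  sw <- stepwise_select(das, kept)
  vars <- sw$variables
  z <- das$z[match(vars, das$z$variable), , drop = FALSE]
  structure(list(bear_id = bear_id, season = season, diel = diel,
                 variables = vars,
                 scales = setNames(z$scale, vars),
                 beta = if (length(vars)) sw$fit$beta else numeric(),
                 se = if (length(vars)) sw$fit$se else numeric(),
                 z = z,
                 loglik = if (length(vars)) sw$fit$loglik else
                   nrow(das$u) * log(0.5),
                 aicc = sw$aicc, null_aicc = sw$null_aicc,
                 n = nrow(das$u), scale_table = cs$table,
                 chosen_scales = cs$chosen, pruned_to = kept),
            class = "bear_ssf")
}

#' @export
print.bear_ssf <- function(x, ...) {
  cat("step selection function — bear", x$bear_id,
      paste0("(", x$season, "/", x$diel, ")"), "\n")
  cat("  strata:", x$n, " AICc:", format(x$aicc, digits = 7),
      "(null", format(x$null_aicc, digits = 7), ")\n")
  if (!length(x$variables)) { cat("  null model (no variable retained)\n")
  } else {
    tab <- data.frame(scale_m = unname(x$scales), beta = unname(x$beta),
                      se = unname(x$se), row.names = x$variables)
    print(round(tab, 4))
  }
  invisible(x)
}

#' @export
summary.bear_ssf <- function(object, ...) {
  print(object)
  cat("characteristic-scale AICc table:\n")
  print(round(object$scale_table, 2))
  invisible(object)
}

#' @export
coef.bear_ssf <- function(object, ...) object$beta
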