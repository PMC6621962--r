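## Diel activity and third-order selection: bootstrapped mean step lengths
## per 45-minute bin, and used:available selection ratios against the 95%
## kernel density home range. The bootstrap unit is the bear (ratios and
## means are computed across bears), matching an individual-level design.

#' Fraction of a step path lying in a (possibly combined) category
#'
#' Samples points every `spacing` m along the step segment (endpoints
#' included) and averages the category layer value — for a 0/1 layer this
#' is the fraction of the path in the category. Combined categories are the
#' cellwise union of member layers.
#'
#' @param ls a `landscape`.
#' @param steps step data.frame (`x1, y1, x2, y2, length`).
#' @param layers character vector of layer names forming the category.
#' @param spacing sample spacing along the segment, m (default 10).
#' @return numeric vector, one fraction per step.
#' @export
step_path_fraction <- function(ls, steps, layers, spacing = 10) {
  lay <- combine_layers(ls, layers)
  n <- nrow(steps)
  npts <- pmax(2L, ceiling(steps$length / spacing) + 1L)
  idx <- rep(seq_len(n), npts)
  f <- unlist(lapply(seq_len(n), function(i) seq(0, 1, length.out = npts[i])))
  px <- steps$x1[idx] + f * (steps$x2[idx] - steps$x1[idx])
  py <- steps$y1[idx] + f * (steps$y2[idx] - steps$y1[idx])
  rc <- cell_rowcol(ls, px, py)
  v <- lay[(rc[, "col"] - 1L) * ls_dim(ls)[1] + rc[, "row"]]
  as.numeric(tapply(v, idx, mean, na.rm = TRUE))
}

## union (for 0/1 layers) or sum of member layers
combine_layers <- function(ls, layers) {
  stopifnot(all(layers %in% names(ls$layers)))
  m <- Reduce(`+`, ls$layers[layers])
  if (all(vapply(layers, function(l) ls$kind[[l]] == "categorical", TRUE)))
    m <- pmin(m, 1)
  m
}

## 45-minute diel bin (0..31) of POSIXct times, in local clock time
diel_bin <- function(times, tz_offset_hours = -5) {
  loc <- times + tz_offset_hours * 3600
  mins <- as.numeric(format(loc, "%H")) * 60 + as.numeric(format(loc, "%M"))
  as.integer(mins %/% 45)
}

#' Bootstrapped mean step length per 45-minute diel bin
#'
#' Bins steps by local start time into 32 bins of 45 minutes, computes the
#' per-bear mean length in each (season, bin), and bootstraps the across-
#' bear mean: bears are resampled with replacement `n_boot` times and the
#' percentile 95% interval reported. Bins represented by fewer than two
#' bears are flagged and get no interval.
#'
#' @param steps step data.frame with `season` labels (45-minute schedule).
#' @param n_boot bootstrap draws (default 1000).
#' @param seed integer seed.
#' @param tz_offset_hours local-time offset from UTC used for binning.
#' @return data.frame `season, bin, bin_start_hhmm, mean_length, ci_low,
#'   ci_high, n_bears, ci_flagged`.
#' @export
bootstrap_step_lengths <- function(steps, n_boot = 1000, seed = 1,
                                   tz_offset_hours = -5) {
  set.seed(seed)
  steps$bin <- diel_bin(steps$t_start, tz_offset_hours)
  out <- list()
  for (sea in levels(droplevels(factor(steps$season)))) {
    ss <- steps[steps$season == sea, ]
    for (b in sort(unique(ss$bin))) {
      sb <- ss[ss$bin == b, ]
      bm <- tapply(sb$length, sb$bear_id, mean)
      bm <- bm[!is.na(bm)]
      est <- mean(bm)
      if (length(bm) >= 2) {
        boot <- replicate(n_boot,
                          mean(bm[sample.int(length(bm), replace = TRUE)]))
        ci <- quantile(boot, c(0.025, 0.975), names = FALSE)
        flag <- FALSE
      } else { ci <- c(NA_real_, NA_real_); flag <- TRUE }
      out[[length(out) + 1]] <- data.frame(
        season = sea, bin = b,
        bin_start_hhmm = sprintf("%02d:%02d", (b * 45) %/% 60, (b * 45) %% 60),
        mean_length = est, ci_low = ci[1], ci_high = ci[2],
        n_bears = length(bm), ci_flagged = flag)
    }
  }
  do.call(rbind, out)
}

#' Third-order selection ratios per 45-minute diel bin
#'
#' For each bear, season, bin and category: the mean fraction of the bear's
#' step paths in the category, divided by the category's availability
#' inside the bear's seasonal 95% kernel density home range. Ratios are
#' then bootstrapped across bears (mean and percentile 95% CI per bin).
#' Bears whose home range holds none of a category have an undefined ratio
#' and are excluded with a warning.
#'
#' @param steps step data.frame with `season` labels.
#' @param home_ranges nested list `home_ranges[[bear_id]][[season]]` of
#'   [estimate_kde_home_range()] results.
#' @param ls a `landscape`.
#' @param categories named list; each element a character vector of layers
#'   forming one (possibly combined) category, e.g.
#'   `list(forest = c("deciduous","coniferous","mixed"))`.
#' @param n_boot bootstrap draws.
#' @param seed integer seed.
#' @param tz_offset_hours local-time offset used for binning.
#' @param spacing path sampling spacing, m.
#' @return data.frame `season, bin, bin_start_hhmm, category, mean_ratio,
#'   ci_low, ci_high, n_bears`.
#' @export
selection_ratio_by_bin <- function(steps, home_ranges, ls, categories,
                                   n_boot = 1000, seed = 1,
                                   tz_offset_hours = -5, spacing = 10) {
  set.seed(seed)
  steps$bin <- diel_bin(steps$t_start, tz_offset_hours)
  ## availability per bear-season-category
  avail <- function(id, sea, cat) {
    hr <- home_ranges[[id]][[sea]]
    if (is.null(hr)) return(NA_real_)
    mean(combine_layers(ls, categories[[cat]])[hr$mask])
  }
  out <- list()
  for (cat in names(categories)) {
    frac <- step_path_fraction(ls, steps, categories[[cat]], spacing)
    for (sea in levels(droplevels(factor(steps$season)))) {
      i_sea <- which(steps$season == sea)
      for (b in sort(unique(steps$bin[i_sea]))) {
        i <- i_sea[steps$bin[i_sea] == b]
        ratios <- c()
        for (id in unique(steps$bear_id[i])) {
          a <- avail(id, sea, cat)
          if (is.na(a)) next
          if (a == 0) {
            warning("category ", cat, " unavailable to bear ", id,
                    " in ", sea, "; bear excluded")
            next
          }
          ratios <- c(ratios, mean(frac[i][steps$bear_id[i] == id]) / a)
        }
        if (!length(ratios)) next
        est <- mean(ratios)
        ci <- if (length(ratios) >= 2)
          quantile(replicate(n_boot,
                             mean(ratios[sample.int(length(ratios),
                                                    replace = TRUE)])),
                   c(0.025, 0.975), names = FALSE)
        else c(NA_real_, NA_real_)
        out[[length(out) + 1]] <- data.frame(
          season = sea, bin = b,
          bin_start_hhmm = sprintf("%02d:%02d", (b * 45) %/% 60, (b * 45) %% 60),
          category = cat, mean_ratio = est, ci_low = ci[1], ci_high = ci[2],
          n_bears = length(ratios))
      }
    }
  }
  do.call(rbind, out)
}
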