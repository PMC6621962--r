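## Ecologically based seasons: smooth daily movement + habitat series per
## bear-year, range-standardize, k-means cluster with the gap statistic,
## and pool cluster labels across bear-years into one date calendar.

#' Centered moving average
#' @param x numeric series.
#' @param window odd window length (values at the edges use the available
#'   part of the window).
#' @export
moving_average <- function(x, window = 5) {
  n <- length(x)
  if (n < window) stop("series shorter than the smoothing window")
  h <- window %/% 2
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - h):min(n, i + h)]), 0)
}

#' Range standardization to [0, 1]
#'
#' Zero-range series cannot be standardized; they are set to 0 and flagged
#' via the `"degenerate"` attribute.
#' @param x numeric series.
#' @export
range_standardize <- function(x) {
  r <- range(x)
  if (diff(r) == 0)
    return(structure(rep(0, length(x)), degenerate = TRUE))
  (x - r[1]) / diff(r)
}

#' Build daily season features for clustering
#'
#' For each bear-year: daily means of movement speed, absolute turning
#' angle, and the point-sampled habitat layers; each series smoothed with a
#' centered `window_days` moving window and range standardized to [0, 1]
#' within the bear-year.
#'
#' @param steps step data.frame (one year per bear id; `length`,
#'   `duration_min`, `turning_angle`, `t_start`, end coordinates `x2, y2`).
#' @param landscape a `landscape`.
#' @param layers habitat layers sampled at step endpoints.
#' @param window_days smoothing window (default 5).
#' @return data.frame `bear_year, date` + one standardized column per
#'   feature; degenerate (zero-range) features are listed in the
#'   `"degenerate_features"` attribute.
#' @export
build_season_features <- function(steps, landscape,
                                  layers = c("coniferous", "deciduous",
                                             "forested_wetland", "agriculture",
                                             "impervious"),
                                  window_days = 5) {
  layers <- intersect(layers, names(landscape$layers))
  pv <- extract_at_points(landscape, steps$x2, steps$y2, layers)
  df <- data.frame(bear_year = steps$bear_id,
                   date = as.Date(steps$t_start),
                   speed = steps$length / steps$duration_min,
                   abs_turn = abs(steps$turning_angle))
  df <- cbind(df, as.data.frame(pv))
  feat_cols <- c("speed", "abs_turn", layers)
  degenerate <- character()
  out <- do.call(rbind, lapply(split(df, df$bear_year), function(d) {
    daily <- aggregate(d[feat_cols], list(date = d$date), mean, na.rm = TRUE)
    daily <- daily[order(daily$date), ]
    for (f in feat_cols) {
      v <- moving_average(daily[[f]], window_days)
      v <- range_standardize(v)
      if (isTRUE(attr(v, "degenerate")))
        degenerate <<- union(degenerate, f)
      daily[[f]] <- as.numeric(v)
    }
    cbind(bear_year = d$bear_year[1], daily)
  }))
  rownames(out) <- NULL
  attr(out, "degenerate_features") <- degenerate
  out
}

#' Choose the number of clusters with the gap statistic
#'
#' K-means (multiple restarts) over k = 1..`k_max`; the gap statistic
#' compares within-cluster dispersion with `B` uniform reference sets over
#' each feature's range, and k is the smallest k with
#' `gap(k) >= gap(k+1) - se(k+1)`.
#'
#' @param features numeric matrix/data.frame of observations x features.
#' @param k_max maximum k (>= 2).
#' @param B reference sets (default 50).
#' @param seed integer seed.
#' @param nstart k-means restarts.
#' @return list: `k`, `gap` (per-k table with `logW, E.logW, gap, SE.sim`).
#' @export
choose_k_gap <- function(features, k_max = 6, B = 50, seed = 1, nstart = 10) {
  if (k_max < 2) stop("k_max must be at least 2")
  x <- as.matrix(features)
  if (nrow(x) < 50) stop("need at least 50 observations")
  set.seed(seed)
  cg <- cluster::clusGap(x, FUNcluster = function(xx, k)
    stats::kmeans(xx, k, nstart = nstart, iter.max = 100),
    K.max = k_max, B = B, verbose = FALSE)
  tab <- as.data.frame(cg$Tab)
  k <- cluster::maxSE(tab$gap, tab$SE.sim, method = "Tibs2001SEmax")
  list(k = k, gap = tab)
}

#' Pool cluster labels into a season date calendar
#'
#' Takes per-day cluster labels across bear-years, computes the modal label
#' per calendar day, smooths with a 7-day majority filter, and returns
#' contiguous intervals as a [season_calendar()]. When a label still
#' occupies several runs after smoothing, the longest run is kept with a
#' warning. With three seasons in chronological order the names
#' `spring`/`summer`/`fall` are used.
#'
#' @param labels data.frame `date, cluster`.
#' @param majority_window days for the majority filter (default 7).
#' @param use_default if TRUE, bypass the data and return the default
#'   den-emergence / June 15 / August 10 calendar verbatim.
#' @return a [season_calendar()].
#' @export
derive_season_dates <- function(labels, majority_window = 7,
                                use_default = FALSE) {
  if (use_default) return(season_calendar())
  doy <- as.integer(format(as.Date(labels$date), "%j"))
  modal <- function(v) as.integer(names(which.max(table(v))))
  days <- sort(unique(doy))
  lab <- vapply(days, function(d) modal(labels$cluster[doy == d]), 0L)
  ## 7-day majority filter over the observed day sequence
  h <- majority_window %/% 2
  sm <- vapply(seq_along(lab), function(i)
    modal(lab[max(1, i - h):min(length(lab), i + h)]), 0L)
  r <- rle(sm)
  if (length(unique(sm)) == 1)
    warning("labels constant over the year; a single season returned")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(label = r$values, start = days[starts], end = days[ends],
                     len = r$lengths)
  ## keep the longest run per label
  if (anyDuplicated(runs$label)) {
    warning("non-contiguous season labels after smoothing; keeping longest runs")
    runs <- do.call(rbind, lapply(split(runs, runs$label),
                                  function(d) d[which.max(d$len), ]))
  }
  runs <- runs[order(runs$start), ]
  md <- function(doy) format(as.Date(doy - 1, origin = "2019-01-01"), "%m-%d")
  nm <- if (nrow(runs) == 3) c("spring", "summer", "fall") else
    paste0("season", seq_len(nrow(runs)))
  b <- lapply(seq_len(nrow(runs)), function(i) c(md(runs$start[i]), md(runs$end[i])))
  names(b) <- nm
  ## stretch the first and last interval to cover the calendar year
  b[[1]][1] <- "01-01"
  b[[length(b)]][2] <- "12-31"
  season_calendar(b)
}
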