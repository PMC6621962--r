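#' Filter GPS fixes on dilution-of-precision and fix class
#'
#' Removes (1) unresolved fixes, (2) fixes with PDOP > 5 in the less
#' reliable classes (`qfp_uncertain`, `two_d`), and (3) fixes with
#' PDOP > 20 in the reliable classes (`qfp_certain`, `three_d`). A resolved
#' fix with missing PDOP cannot be vetted and is removed with a warning.
#'
#' @param fixes data.frame with `bear_id`, `pdop`, `fix_class` columns;
#'   `fix_class` one of `unresolved, qfp_uncertain, qfp_certain, two_d,
#'   three_d`.
#' @return list: `fixes` (retained rows), `report` (per bear: `n_fixes`,
#'   `n_removed`, `fraction_removed`) and `pooled_fraction_removed`.
#' @export
filter_fixes <- function(fixes) {
  stopifnot(all(c("bear_id", "pdop", "fix_class") %in% names(fixes)))
  cls <- fixes$fix_class
  pd <- fixes$pdop
  na_pdop <- is.na(pd) & cls != "unresolved"
  if (any(na_pdop))
    warning(sum(na_pdop), " resolved fixes with missing PDOP removed")
  pd[is.na(pd)] <- Inf
  drop <- cls == "unresolved" |
    (cls %in% c("qfp_uncertain", "two_d") & pd > 5) |
    (cls %in% c("qfp_certain", "three_d") & pd > 20)
  report <- do.call(rbind, lapply(split(drop, fixes$bear_id), function(d)
    data.frame(n_fixes = length(d), n_removed = sum(d),
               fraction_removed = mean(d))))
  report <- data.frame(bear_id = rownames(report), report,
                       row.names = NULL, stringsAsFactors = FALSE)
  list(fixes = fixes[!drop, , drop = FALSE], report = report,
       pooled_fraction_removed = mean(drop))
}

#' Detect the denning period of one bear-year
#'
#' Winter dens show up as long runs of days with essentially no
#' displacement. A day is called stationary when the diagonal of its fixes'
#' bounding box is below `threshold`; the longest run of at least
#' `min_days` consecutive stationary days whose dates fall in the search
#' months is taken as the den period. Automation of what is traditionally
#' done by eye on the fix map.
#'
#' @param track one bear's fixes (`timestamp`, `x`, `y`), spanning >= 60
#'   days.
#' @param threshold daily bounding-box diagonal below which a day counts as
#'   stationary (m, default 100).
#' @param min_days minimum run length in days (default 30).
#' @param search_months months (1-12) in which den days may fall (default
#'   October through May).
#' @return list `(den_entry, den_emergence)` of `Date`s — emergence is the
#'   first active day — or `NULL` when no qualifying run exists (bear
#'   treated as non-denning, with a warning).
#' @export
detect_den_period <- function(track, threshold = 100, min_days = 30,
                              search_months = c(10:12, 1:5)) {
  dates <- as.Date(track$timestamp)
  if (as.numeric(diff(range(dates))) < 60)
    stop("track must span at least 60 days")
  days <- sort(unique(dates))
  diag_of <- function(d) {
    i <- dates == d
    sqrt(diff(range(track$x[i]))^2 + diff(range(track$y[i]))^2)
  }
  stationary <- vapply(days, diag_of, 0) < threshold &
    as.integer(format(days, "%m")) %in% search_months
  r <- rle(stationary)
  ends <- cumsum(r$lengths)
  ok <- which(r$values & r$lengths >= min_days)
  if (!length(ok)) {
    warning("no denning period found; treating bear as non-denning")
    return(NULL)
  }
  best <- ok[which.max(r$lengths[ok])]
  run <- seq(ends[best] - r$lengths[best] + 1, ends[best])
  if (length(run) == length(days))
    warning("track stationary throughout; den period spans the search window")
  list(den_entry = days[run[1]], den_emergence = days[run[length(run)]] + 1)
}

#' Drop fixes inside a denning period
#' @param fixes one bear's fixes.
#' @param den list from [detect_den_period()] (or NULL, a no-op).
#' @export
exclude_den <- function(fixes, den) {
  if (is.null(den)) return(fixes)
  d <- as.Date(fixes$timestamp)
  fixes[d < den$den_entry | d >= den$den_emergence, , drop = FALSE]
}

#' Build movement steps from consecutive fixes
#'
#' A step joins two fixes whose spacing matches the nominal schedule within
#' `tolerance`; nothing is interpolated across gaps. The turning angle of a
#' step is the signed change of heading from the immediately preceding step
#' and is defined only when that step exists (shares its start fix with the
#' previous step's end fix).
#'
#' @param fixes filtered, den-excluded fixes for one or more bears
#'   (`bear_id`, `timestamp`, `x`, `y`, optionally `true_state`).
#' @param nominal_interval schedule spacing in minutes.
#' @param tolerance allowed deviation in minutes (default 2).
#' @return data.frame of steps: `bear_id, t_start, t_end, x1, y1, x2, y2,
#'   length, heading, turning_angle, duration_min` (+ `true_state` of the
#'   end fix when present).
#' @export
build_steps <- function(fixes, nominal_interval, tolerance = 2) {
  one <- function(fx) {
    if (nrow(fx) < 3) return(NULL)
    fx <- fx[order(fx$timestamp), ]
    dt <- as.numeric(difftime(fx$timestamp[-1], fx$timestamp[-nrow(fx)],
                              units = "mins"))
    ok <- abs(dt - nominal_interval) <= tolerance
    i <- which(ok)
    if (!length(i)) return(NULL)
    dx <- fx$x[i + 1] - fx$x[i]
    dy <- fx$y[i + 1] - fx$y[i]
    heading <- atan2(dy, dx)
    ## previous step exists iff the preceding fix pair was also consecutive
    prev <- c(NA_integer_, i[-length(i)])
    has_prev <- !is.na(prev) & prev == i - 1
    turn <- rep(NA_real_, length(i))
    turn[has_prev] <- wrap_angle(heading[has_prev] -
                                   heading[match(prev[has_prev], i)])
    st <- data.frame(bear_id = fx$bear_id[i], t_start = fx$timestamp[i],
                     t_end = fx$timestamp[i + 1],
                     x1 = fx$x[i], y1 = fx$y[i],
                     x2 = fx$x[i + 1], y2 = fx$y[i + 1],
                     length = sqrt(dx^2 + dy^2), heading = heading,
                     turning_angle = turn, duration_min = dt[i],
                     stringsAsFactors = FALSE)
    if ("true_state" %in% names(fx)) st$true_state <- fx$true_state[i + 1]
    st
  }
  out <- do.call(rbind, lapply(split(fixes, fixes$bear_id), one))
  if (is.null(out))
    out <- data.frame(bear_id = character(), t_start = as.POSIXct(character()),
                      t_end = as.POSIXct(character()), x1 = numeric(),
                      y1 = numeric(), x2 = numeric(), y2 = numeric(),
                      length = numeric(), heading = numeric(),
                      turning_angle = numeric(), duration_min = numeric())
  rownames(out) <- NULL
  out
}

#' Label steps with their diel period
#'
#' A step is `day` when its start time falls in `[sunrise, sunset)` for the
#' study site on that date (half-open so each step gets exactly one label),
#' otherwise `night`. Sunrise and sunset come from [sun_times()] unless a
#' lookup table is supplied.
#'
#' @param steps step data.frame (`t_start` in UTC).
#' @param lat,lon study-site latitude/longitude in decimal degrees
#'   (longitude positive east). Latitudes beyond +-66 are refused (polar
#'   day/night).
#' @param sun_table optional data.frame `date, sunrise, sunset` (POSIXct
#'   UTC) overriding the solar computation.
#' @return steps with a `diel` factor column.
#' @export
assign_diel <- function(steps, lat = 42.38, lon = -72.52, sun_table = NULL) {
  if (abs(lat) >= 66) stop("latitudes beyond +-66 degrees are unsupported")
  dates <- as.Date(steps$t_start)
  if (is.null(sun_table)) {
    ud <- sort(unique(dates))
    st <- sun_times(ud, lat, lon)
    sun_table <- data.frame(date = ud, sunrise = st$sunrise, sunset = st$sunset)
  }
  i <- match(dates, sun_table$date)
  day <- steps$t_start >= sun_table$sunrise[i] &
    steps$t_start < sun_table$sunset[i]
  steps$diel <- factor(ifelse(day, "day", "night"), levels = c("day", "night"))
  steps
}

#' Seasonal calendar
#'
#' Month-day season boundaries. The default is the ecologically derived
#' three-season calendar for Massachusetts black bears: spring from den
#' emergence to June 14, summer June 15 to August 9, fall August 10 to den
#' entry.
#'
#' @param boundaries named list of `c(start, end)` month-day strings.
#' @export
season_calendar <- function(boundaries = list(spring = c("01-01", "06-14"),
                                              summer = c("06-15", "08-09"),
                                              fall = c("08-10", "12-31"))) {
  structure(boundaries, class = "season_calendar")
}

#' Season of calendar dates
#' @param dates `Date` vector.
#' @param calendar a [season_calendar()].
#' @export
season_of_date <- function(dates, calendar = season_calendar()) {
  md <- format(as.Date(dates), "%m-%d")
  out <- rep(NA_character_, length(md))
  for (nm in names(calendar))
    out[md >= calendar[[nm]][1] & md <= calendar[[nm]][2]] <- nm
  factor(out, levels = names(calendar))
}

#' Label steps with their season
#'
#' Applies the calendar to each step's start date. When per-bear den dates
#' are supplied, steps before emergence or after entry are excluded and
#' counted (attribute `n_excluded`).
#'
#' @param steps step data.frame.
#' @param calendar a [season_calendar()].
#' @param den_dates optional named list (by bear id) of
#'   [detect_den_period()] results.
#' @return steps with a `season` factor column.
#' @export
assign_season <- function(steps, calendar = season_calendar(),
                          den_dates = NULL) {
  steps$season <- season_of_date(as.Date(steps$t_start), calendar)
  n_excluded <- 0L
  if (!is.null(den_dates)) {
    keep <- rep(TRUE, nrow(steps))
    for (id in names(den_dates)) {
      den <- den_dates[[id]]
      if (is.null(den)) next
      i <- steps$bear_id == id
      d <- as.Date(steps$t_start[i])
      keep[i] <- !(d >= den$den_entry & d < den$den_emergence)
    }
    n_excluded <- sum(!keep)
    steps <- steps[keep, , drop = FALSE]
  }
  attr(steps, "n_excluded") <- n_excluded
  steps
}
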