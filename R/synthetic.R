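#' Generate a synthetic landscape stack
#'
#' Builds spatially autocorrelated land-cover and terrain layers on a planar
#' 30 m grid. Categorical cover classes are carved from thresholded smoothed
#' Gaussian noise fields so patches are contiguous; classes listed in
#' `proportions` are mutually exclusive and realized at (almost) exactly the
#' requested proportions. Continuous layers: `impervious` (percent, 0-100,
#' elevated in and near residential cells), `slope` (degrees). A thin
#' band around a level set of a smoothed field gives curvilinear `roads`.
#'
#' @param dim grid dimension `c(nrow, ncol)` (>= 64 each).
#' @param resolution meters per cell (default 30).
#' @param proportions named vector of target cover proportions for mutually
#'   exclusive categorical classes (each in (0,1), sum <= 1). Default covers
#'   deciduous/coniferous/mixed forest, forested wetland, agriculture and
#'   low-density residential.
#' @param autocorr_range autocorrelation range in meters (Gaussian smoothing
#'   SD of the underlying noise fields).
#' @param road_proportion fraction of cells carrying road (default 0.02).
#' @param constant optional named vector forcing a layer to a constant value
#'   (e.g. `c(impervious = 0)`).
#' @param seed integer seed; the same seed reproduces the stack bit for bit.
#' @return a [landscape_stack()].
#' @export
make_landscape <- function(dim = c(200, 200), resolution = 30,
                           proportions = c(deciduous = 0.30, coniferous = 0.15,
                                           mixed = 0.15, forested_wetland = 0.08,
                                           agriculture = 0.12,
                                           residential_low = 0.05),
                           autocorr_range = 300, road_proportion = 0.02,
                           constant = NULL, seed = 1) {
  if (any(dim < 64)) stop("grid must be at least 64 x 64")
  if (any(proportions <= 0) || any(proportions >= 1))
    stop("proportions must lie in (0, 1)")
  if (sum(proportions) > 1)
    stop("configuration error: mutually exclusive proportions sum above 1")
  set.seed(seed)
  nr <- dim[1]; nc <- dim[2]; ncell <- nr * nc
  smooth_field <- function() {
    f <- gaussian_smooth(matrix(rnorm(ncell), nr, nc),
                         sigma = autocorr_range, resolution = resolution)
    (f - mean(f)) / stats::sd(f)
  }

  layers <- list()
  assigned <- matrix(FALSE, nr, nc)
  for (nm in names(proportions)) {
    f <- smooth_field()
    free <- which(!assigned)
    n_k <- round(proportions[[nm]] * ncell)
    take <- free[order(f[free], decreasing = TRUE)][seq_len(min(n_k, length(free)))]
    lay <- matrix(0, nr, nc)
    lay[take] <- 1
    assigned[take] <- TRUE
    layers[[nm]] <- lay
  }

  ## roads: a thin band around the zero level set of a smoothed field
  rf <- smooth_field()
  half_band <- stats::quantile(abs(rf), road_proportion)
  layers$roads <- matrix(as.numeric(abs(rf) < half_band), nr, nc)

  ## impervious rises with residential cover; slope is independent terrain
  imp_base <- smooth_field()
  res_density <- if (!is.null(layers$residential_low))
    gaussian_smooth(layers$residential_low, sigma = 2 * resolution,
                    resolution = resolution) else 0
  imp <- pmax(pmin(12 * imp_base + 60 * res_density + 8, 100), 0)
  imp[imp < 4] <- 0
  layers$impervious <- imp
  layers$slope <- pmin(8 * abs(smooth_field()), 45)

  if (!is.null(constant))
    for (nm in names(constant))
      layers[[nm]] <- matrix(constant[[nm]], nr, nc)

  kind <- setNames(rep("continuous", length(layers)), names(layers))
  kind[c(names(proportions), "roads")] <- "categorical"
  cat_cst <- intersect(names(constant), names(kind)[kind == "categorical"])
  kind[cat_cst[!vapply(cat_cst, function(n) all(layers[[n]] %in% 0:1), TRUE)]] <- "continuous"
  landscape_stack(layers, resolution = resolution, kind = kind)
}

#' Synthetic housing-density raster
#'
#' Houses per square kilometer, co-registered with a landscape; density
#' follows the impervious layer (plus smooth noise) so that developed areas
#' carry more housing.
#'
#' @param ls a `landscape` with an `impervious` layer.
#' @param max_density houses/km^2 at 100% impervious (default 400).
#' @param noise_sd additive smooth noise SD in houses/km^2.
#' @param seed integer seed.
#' @return matrix of houses/km^2 on the landscape grid.
#' @export
make_housing_density <- function(ls, max_density = 400, noise_sd = 10, seed = 1) {
  set.seed(seed)
  d <- ls_dim(ls)
  noise <- gaussian_smooth(matrix(rnorm(prod(d)), d[1], d[2]),
                           sigma = 10 * ls$resolution, resolution = ls$resolution)
  noise <- noise / stats::sd(noise) * noise_sd
  pmax(ls$layers$impervious / 100 * max_density + noise, 0)
}

#' Default three-state movement parameters
#'
#' Ground-truth emission and transition parameters for the simulator and a
#' natural starting point for model fitting: an encamped state (short steps,
#' diffuse reversing turns), a foraging state (moderate steps, weak
#' directionality) and a movement state (long, directed steps). Values are
#' plausible for black bears on a 45-minute fix schedule.
#'
#' @param step_mean,step_sd gamma step-length mean/SD per state (m).
#' @param angle_mean,angle_kappa von Mises turning-angle mean/concentration.
#' @param Gamma 3x3 transition matrix (rows sum to 1).
#' @return list with class `hmm_par`.
#' @export
hmm_par <- function(step_mean = c(20, 120, 450), step_sd = c(15, 80, 200),
                    angle_mean = c(pi, 0, 0), angle_kappa = c(0.3, 0.7, 4),
                    Gamma = matrix(c(0.85, 0.10, 0.05,
                                     0.10, 0.80, 0.10,
                                     0.05, 0.10, 0.85), 3, 3, byrow = TRUE)) {
  stopifnot(all(step_mean > 0), all(step_sd > 0), all(angle_kappa >= 0),
            nrow(Gamma) == length(step_mean),
            max(abs(rowSums(Gamma) - 1)) < 1e-9)
  structure(list(step_mean = step_mean, step_sd = step_sd,
                 angle_mean = wrap_angle(angle_mean), angle_kappa = angle_kappa,
                 Gamma = Gamma, delta = stationary_dist(Gamma)),
            class = "hmm_par")
}

## stationary distribution of a transition matrix
stationary_dist <- function(Gamma) {
  n <- nrow(Gamma)
  A <- rbind(t(diag(n) - Gamma), rep(1, n))
  tryCatch(as.numeric(qr.solve(A, c(rep(0, n), 1))),
           error = function(e) rep(1 / n, n))  # reducible chain: uniform
}

#' Per-bear simulation configuration
#'
#' Holds one bear's ground truth: home center, habitat-selection
#' coefficients (optionally split by season and diel period), movement-state
#' parameters, fix schedule, and den dates.
#'
#' @param bear_id character id.
#' @param home_center `c(x, y)` in meters.
#' @param coefficients either a named vector (constant selection) or a list
#'   by season (`spring`/`summer`/`fall`), each element a named vector or a
#'   `day`/`night` list of named vectors. Names are landscape layers;
#'   coefficients act on raw layer values.
#' @param hmm an [hmm_par()] object.
#' @param fix_interval_min minutes between fixes (15 or 45).
#' @param den_entry,den_emergence `Date`s (or NULL for a non-denning record).
#' @param home_bias,home_range_scale strength (0-1) and distance scale (m) of
#'   the homing bias that keeps the walk within a home range.
#' @return list with class `bear_config`.
#' @export
bear_config <- function(bear_id, home_center, coefficients = NULL,
                        hmm = hmm_par(), fix_interval_min = 45,
                        den_entry = NULL, den_emergence = NULL,
                        home_bias = 0.3, home_range_scale = 2500) {
  structure(list(bear_id = bear_id, home_center = as.numeric(home_center),
                 coefficients = coefficients, hmm = hmm,
                 fix_interval_min = fix_interval_min,
                 den_entry = den_entry, den_emergence = den_emergence,
                 home_bias = home_bias, home_range_scale = home_range_scale),
            class = "bear_config")
}

## resolve the coefficient vector active for a season/diel period
resolve_coef <- function(coefficients, season, diel) {
  if (is.null(coefficients)) return(NULL)
  co <- coefficients
  if (is.list(co) && !is.null(co[[season]])) co <- co[[season]]
  if (is.list(co) && !is.null(co[[diel]])) co <- co[[diel]]
  if (is.list(co)) co <- co[[1]]
  co
}

#' Assemble a synthetic study
#'
#' Binds a landscape, a housing raster and a set of bears, and imposes the
#' development-acclimation ground truth: each bear's percent-impervious
#' selection coefficient is the logistic `hrhd_curve` evaluated at the
#' housing density around its home center, plus Gaussian noise. The curve's
#' lower asymptote is the (strongly avoiding) rural response and its upper
#' asymptote the acclimated response.
#'
#' @param landscape a `landscape`.
#' @param housing_density matrix from [make_housing_density()].
#' @param bears list of [bear_config()]s.
#' @param hrhd_curve list `(lower, upper, x0, slope)`; default inflection 75
#'   houses/km^2.
#' @param coef_noise_sd SD of the per-bear deviation from the curve.
#' @param seed integer seed.
#' @return list with class `synthetic_study`.
#' @export
synthetic_study <- function(landscape, housing_density, bears,
                            hrhd_curve = list(lower = -3, upper = -0.2,
                                              x0 = 75, slope = 0.08),
                            coef_noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  ext <- ls_extent(landscape)
  for (b in bears) {
    hc <- b$home_center
    if (hc[1] < ext["xmin"] || hc[1] > ext["xmax"] ||
        hc[2] < ext["ymin"] || hc[2] > ext["ymax"])
      stop("bear ", b$bear_id, " home center outside the landscape")
  }
  bears <- lapply(bears, function(b) {
    b$hrhd_true <- local_housing_density(landscape, housing_density,
                                         b$home_center, radius = 1500)
    beta_imp <- eval_hrhd_curve(hrhd_curve, b$hrhd_true) +
      rnorm(1, 0, coef_noise_sd)
    b$impervious_coef <- beta_imp
    b$coefficients <- set_impervious_coef(b$coefficients, beta_imp)
    b
  })
  structure(list(landscape = landscape, housing_density = housing_density,
                 bears = bears, hrhd_curve = hrhd_curve,
                 coef_noise_sd = coef_noise_sd, rng_seed = seed),
            class = "synthetic_study")
}

#' Evaluate the four-parameter logistic acclimation curve
#' @param curve list `(lower, upper, x0, slope)`.
#' @param x housing density, houses/km^2.
#' @export
eval_hrhd_curve <- function(curve, x)
  curve$lower + (curve$upper - curve$lower) /
    (1 + exp(-curve$slope * (x - curve$x0)))

## mean housing density within `radius` m of a point
local_housing_density <- function(ls, housing, center, radius = 1500) {
  cc <- cell_xy(ls, as.vector(row(housing)), as.vector(col(housing)))
  inside <- (cc[, 1] - center[1])^2 + (cc[, 2] - center[2])^2 <= radius^2
  mean(housing[inside])
}

## write beta_imp into every (season, diel) slot of a coefficient structure;
## the simulator reads impervious on the 0-100 percent scale, so divide by
## 100 to express the coefficient per percentage point * 100 (i.e. per unit
## of impervious/100), keeping acceptance weights in a sane range.
set_impervious_coef <- function(coefficients, beta_imp) {
  put <- function(v) { v[["impervious"]] <- beta_imp / 100; v }
  if (is.null(coefficients)) return(put(c(impervious = 0)))
  if (!is.list(coefficients)) return(put(coefficients))
  lapply(coefficients, function(el)
    if (is.list(el)) lapply(el, put) else put(el))
}

#' Simulate GPS tracks for a synthetic study
#'
#' Each bear follows a state-switching biased correlated random walk. At
#' every fix interval the behavioral state is drawn from the transition
#' matrix, a step length from that state's gamma and a turning angle from
#' its von Mises distribution; the proposed heading is pulled toward the
#' home center with a bias that grows with displacement. Candidate endpoints
#' are then accepted with probability proportional to `exp(sum(beta * x))`
#' with covariates read at the endpoint and the coefficient set chosen by
#' the current season and diel period (day is `[sunrise_h, sunset_h)` local
#' hours). Between den entry and den emergence the bear sits at its den with
#' 5 m Gaussian jitter.
#'
#' @param study a [synthetic_study()].
#' @param duration_days days of tracking (>= 10).
#' @param start date (`Date` or string) of the first fix, 00:00 UTC.
#' @param seed integer seed.
#' @param max_tries rejection-sampling attempts per step before the best
#'   candidate so far is taken.
#' @param sunrise_h,sunset_h diel switch points (local hours) used by the
#'   generator's coefficient schedule.
#' @param calendar a [season_calendar()] used by the
#'   generator's coefficient schedule.
#' @return a data.frame of fixes: `bear_id, timestamp, x, y, true_state`
#'   (NA while denning).
#' @export
simulate_tracks <- function(study, duration_days = 60, start = "2020-06-01",
                            seed = 1, max_tries = 50,
                            sunrise_h = 6, sunset_h = 18,
                            calendar = season_calendar()) {
  if (duration_days < 10) stop("duration must be at least 10 days")
  set.seed(seed)
  ls <- study$landscape
  ext <- ls_extent(ls)
  start <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  out <- vector("list", length(study$bears))
  for (bi in seq_along(study$bears)) {
    b <- study$bears[[bi]]
    nfix <- duration_days * 24 * 60 / b$fix_interval_min
    times <- start + seq(0, length.out = nfix, by = b$fix_interval_min * 60)
    dates <- as.Date(times)
    hours <- as.numeric(format(times, "%H")) +
      as.numeric(format(times, "%M")) / 60
    diel <- ifelse(hours >= sunrise_h & hours < sunset_h, "day", "night")
    season <- season_of_date(dates, calendar)
    denning <- rep(FALSE, nfix)
    if (!is.null(b$den_entry) && !is.null(b$den_emergence))
      denning <- dates >= as.Date(b$den_entry) & dates < as.Date(b$den_emergence)

    par <- b$hmm
    x <- matrix(NA_real_, nfix, 2)
    state <- integer(nfix)
    x[1, ] <- b$home_center
    state[1] <- sample.int(3, 1, prob = par$delta)
    heading <- runif(1, -pi, pi)
    den_site <- NULL
    layers_used <- unique(unlist(lapply(c("spring", "summer", "fall"), function(s)
      lapply(c("day", "night"), function(d)
        names(resolve_coef(b$coefficients, s, d))))))
    rng <- lapply(setNames(layers_used, layers_used), function(nm)
      range(ls$layers[[nm]]))

    for (t in 2:nfix) {
      if (denning[t]) {
        if (is.null(den_site)) den_site <- x[t - 1, ]
        x[t, ] <- den_site + rnorm(2, 0, 5)
        state[t] <- 1L
        next
      }
      den_site <- NULL
      state[t] <- sample.int(3, 1, prob = par$Gamma[state[t - 1], ])
      beta <- resolve_coef(b$coefficients, season[t], diel[t])
      ## log of the maximum attainable selection weight, for rejection bound
      wmax <- if (is.null(beta)) 0 else
        sum(vapply(names(beta), function(nm)
          max(beta[[nm]] * rng[[nm]]), 0))
      best <- NULL; best_lw <- -Inf
      for (k in seq_len(max_tries)) {
        len <- rgamma(1, shape = gamma_shape(par$step_mean[state[t]],
                                             par$step_sd[state[t]]),
                      rate = gamma_rate(par$step_mean[state[t]],
                                        par$step_sd[state[t]]))
        turn <- rvonmises(1, par$angle_mean[state[t]],
                          par$angle_kappa[state[t]])
        h <- wrap_angle(heading + turn)
        ## homing bias toward the home center, growing with displacement
        dhome <- sqrt(sum((b$home_center - x[t - 1, ])^2))
        rho <- b$home_bias * min(1, dhome / b$home_range_scale)
        home_bearing <- atan2(b$home_center[2] - x[t - 1, 2],
                              b$home_center[1] - x[t - 1, 1])
        h <- atan2((1 - rho) * sin(h) + rho * sin(home_bearing),
                   (1 - rho) * cos(h) + rho * cos(home_bearing))
        cand <- x[t - 1, ] + len * c(cos(h), sin(h))
        if (cand[1] <= ext["xmin"] || cand[1] >= ext["xmax"] ||
            cand[2] <= ext["ymin"] || cand[2] >= ext["ymax"]) next
        lw <- 0
        if (!is.null(beta) && length(beta)) {
          xv <- extract_at_points(ls, cand[1], cand[2], names(beta))
          lw <- sum(beta * xv[1, ])
        }
        if (lw > best_lw) { best_lw <- lw; best <- c(cand, h) }
        if (log(runif(1)) < lw - wmax) { best <- c(cand, h); break }
      }
      if (is.null(best)) {          # cornered: nudge home
        best <- c(x[t - 1, ] + 0.1 * (b$home_center - x[t - 1, ]), heading)
      }
      x[t, ] <- best[1:2]
      heading <- best[3]
    }
    st <- state; st[denning] <- NA_integer_
    out[[bi]] <- data.frame(bear_id = b$bear_id, timestamp = times,
                            x = x[, 1], y = x[, 2], true_state = st,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate step series directly from movement-state parameters
#'
#' Draws a latent Markov state sequence and the matching step lengths and
#' turning angles, without any landscape. Ground truth for testing state
#' segmentation.
#'
#' @param par an [hmm_par()].
#' @param n number of steps.
#' @return data.frame `length, angle, state`.
#' @export
r_hmm_steps <- function(par, n) {
  s <- integer(n)
  s[1] <- sample.int(length(par$delta), 1, prob = par$delta)
  if (n > 1) for (t in 2:n)
    s[t] <- sample.int(ncol(par$Gamma), 1, prob = par$Gamma[s[t - 1], ])
  len <- rgamma(n, shape = gamma_shape(par$step_mean[s], par$step_sd[s]),
                rate = gamma_rate(par$step_mean[s], par$step_sd[s]))
  ang <- vapply(seq_len(n), function(i)
    rvonmises(1, par$angle_mean[s[i]], par$angle_kappa[s[i]]), 0)
  ang[1] <- NA_real_                      # first step has no previous heading
  data.frame(length = len, angle = ang, state = s)
}

#' Annotate tracks with GPS quality fields and schedule gaps
#'
#' Adds `pdop` (lognormal) and `fix_class` columns, and drops a configurable
#' fraction of fixes to create gaps. Class probabilities `unresolved`,
#' `qfp_uncertain` and `two_d` are as given; the remainder is split evenly
#' between `qfp_certain` and `three_d`.
#'
#' @param tracks fix data.frame from [simulate_tracks()].
#' @param rates list with elements `unresolved`, `qfp_uncertain`, `two_d`,
#'   `gap` (all in `[0,1]`).
#' @param pdop_meanlog,pdop_sdlog lognormal PDOP parameters.
#' @param seed integer seed.
#' @return tracks with `pdop` and `fix_class`; gap fixes removed.
#' @export
inject_fix_errors <- function(tracks,
                              rates = list(unresolved = 0.01,
                                           qfp_uncertain = 0.03, two_d = 0.05,
                                           gap = 0.02),
                              pdop_meanlog = 1.0, pdop_sdlog = 0.6, seed = 1) {
  stopifnot(all(unlist(rates) >= 0), all(unlist(rates) <= 1))
  p <- c(rates$unresolved, rates$qfp_uncertain, rates$two_d)
  if (sum(p) > 1) stop("configuration error: class rates sum above 1")
  set.seed(seed)
  n <- nrow(tracks)
  u <- runif(n)
  cls <- rep("three_d", n)
  cum <- cumsum(c(p, (1 - sum(p)) / 2))
  cls[u < cum[4]] <- "qfp_certain"
  cls[u < cum[3]] <- "two_d"
  cls[u < cum[2]] <- "qfp_uncertain"
  cls[u < cum[1]] <- "unresolved"
  tracks$pdop <- rlnorm(n, pdop_meanlog, pdop_sdlog)
  tracks$fix_class <- cls
  keep <- runif(n) >= (rates$gap %||% 0)
  tracks[keep, , drop = FALSE]
}

#' Expected fraction removed by the fix-quality filter
#'
#' Closed-form expectation of the removal fraction implied by an error
#' configuration, for calibrating [inject_fix_errors()].
#' @inheritParams inject_fix_errors
#' @export
expected_removal_fraction <- function(rates, pdop_meanlog = 1.0,
                                      pdop_sdlog = 0.6) {
  p_gt <- function(q) stats::plnorm(q, pdop_meanlog, pdop_sdlog,
                                    lower.tail = FALSE)
  p_rest <- 1 - rates$unresolved - rates$qfp_uncertain - rates$two_d
  rates$unresolved +
    (rates$qfp_uncertain + rates$two_d) * p_gt(5) +
    p_rest * p_gt(20)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
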