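## One-call orchestration of the full analysis: synthesize -> preprocess ->
## movement HMM -> seasons -> diel selection -> SSF -> housing-density
## acclimation -> predictive surfaces. Stages hand off through flat CSV /
## ASCII-grid files in the output directory so every intermediate is
## inspectable, and a manifest records seeds and file hashes.

#' Write / read GPS tracks as CSV (ISO-8601 UTC timestamps)
#' @param tracks fix data.frame.
#' @param path file path.
#' @export
write_tracks_csv <- function(tracks, path) {
  tracks$timestamp <- format(tracks$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
  utils::write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  tr$timestamp <- as.POSIXct(tr$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
  tr
}

#' Pipeline configuration
#'
#' Defaults describe the packaged demonstration study: five bears on a
#' 200 x 200-cell synthetic landscape (30 m), 60 summer-fall days at a
#' 45-minute schedule.
#'
#' @param ... overrides of the default fields (see the function body for
#'   the full list: study dimensions, seeds, stage toggles, restart and
#'   bootstrap counts, season mode `"default"` or `"cluster"`, SSF scale
#'   horizons, timezone offset).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    n_bears = 5,
    duration_days = 60,
    start = "2020-06-20",
    fix_interval_min = 45,
    landscape_dim = c(200, 200),
    resolution = 30,
    error_rates = list(unresolved = 0.01, qfp_uncertain = 0.03,
                       two_d = 0.05, gap = 0.02),
    lat = 42.38, lon = -72.52, tz_offset_hours = -5,
    season_mode = "default",      # or "cluster"
    hmm_restarts = 3,
    n_boot = 200,
    ## horizons up to 3 h: on the 6 km demo landscape, longer horizons give
    ## availability kernels wider than a third of the study area
    scale_horizons_min = c(45, 90, 135, 180),
    ssf_layers = c("deciduous", "coniferous", "mixed", "forested_wetland",
                   "agriculture", "residential_low", "roads", "impervious",
                   "slope"),
    hrhd_min_bears = 8,
    boyce_bins = 10,
    stages = c("synth", "preprocess", "hmm", "seasons", "diel", "ssf",
               "hrhd", "surfaces"))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown configuration fields: ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  known <- c("synth", "preprocess", "hmm", "seasons", "diel", "ssf",
             "hrhd", "surfaces")
  if (length(setdiff(cfg$stages, known)))
    stop("unknown stage name: ", paste(setdiff(cfg$stages, known),
                                       collapse = ", "))
  cfg
}

## default demo bear population: shared movement parameters, season/diel
## varying selection (forest by day, agriculture at night in fall, road and
## residential avoidance by day only)
demo_bears <- function(cfg, ext) {
  span_x <- ext["xmax"] - ext["xmin"]; span_y <- ext["ymax"] - ext["ymin"]
  centers <- cbind(ext["xmin"] + span_x * seq(0.22, 0.78,
                                              length.out = cfg$n_bears),
                   ext["ymin"] + span_y * rep(c(0.3, 0.7),
                                              length.out = cfg$n_bears))
  day_beta <- c(deciduous = 0.8, forested_wetland = 0.8, agriculture = -1,
                roads = -0.8)
  night_beta <- c(deciduous = 0.5, forested_wetland = 0.3, agriculture = -0.5,
                  roads = 0.2)
  fall_night <- c(deciduous = 0.3, forested_wetland = 0.3, agriculture = 0.8,
                  roads = 0.3)
  co <- list(spring = list(day = day_beta, night = night_beta),
             summer = list(day = day_beta, night = night_beta),
             fall = list(day = day_beta, night = fall_night))
  lapply(seq_len(cfg$n_bears), function(i)
    bear_config(sprintf("B%02d", i), centers[i, ], coefficients = co,
                fix_interval_min = cfg$fix_interval_min))
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order, writing each stage's
#' outputs under `out_dir` and returning a manifest (seeds, stage outputs,
#' MD5 hashes). A rerun with the same configuration reproduces the outputs
#' bit for bit. A stage failure halts the run with the stage name; outputs
#' of completed stages are retained.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return manifest list (invisibly also written to `manifest.csv`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = character(), files = list(),
                   notes = character())
  env <- new.env()
  run_stage <- function(name, fun) {
    if (!(name %in% config$stages)) return(invisible())
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages <<- c(manifest$stages, name)
    invisible(res)
  }
  note <- function(...) manifest$notes <<- c(manifest$notes, paste0(...))
  outfile <- function(f) file.path(out_dir, f)

  run_stage("synth", function() {
    env$ls <- make_landscape(dim = config$landscape_dim,
                             resolution = config$resolution,
                             seed = config$seed)
    env$housing <- make_housing_density(env$ls, seed = config$seed + 1)
    env$study <- synthetic_study(env$ls, env$housing,
                                 demo_bears(config, ls_extent(env$ls)),
                                 seed = config$seed + 2)
    tracks <- simulate_tracks(env$study, duration_days = config$duration_days,
                              start = config$start, seed = config$seed + 3)
    tracks <- inject_fix_errors(tracks, rates = config$error_rates,
                                seed = config$seed + 4)
    write_tracks_csv(tracks, outfile("tracks.csv"))
    for (nm in names(env$ls$layers))
      write_ascii_grid(env$ls, nm, outfile(paste0("layer_", nm, ".asc")))
    truth <- data.frame(bear_id = vapply(env$study$bears, `[[`, "", "bear_id"),
                        hrhd_true = vapply(env$study$bears, `[[`, 0, "hrhd_true"),
                        impervious_coef = vapply(env$study$bears, `[[`, 0,
                                                 "impervious_coef"))
    utils::write.csv(truth, outfile("truth_bears.csv"), row.names = FALSE)
  })

  run_stage("preprocess", function() {
    tracks <- read_tracks_csv(outfile("tracks.csv"))
    filt <- filter_fixes(tracks)
    utils::write.csv(filt$report, outfile("removal_report.csv"),
                     row.names = FALSE)
    dens <- lapply(split(filt$fixes, filt$fixes$bear_id), function(tr)
      tryCatch(suppressWarnings(detect_den_period(tr)),
               error = function(e) NULL))
    fixes <- do.call(rbind, lapply(split(filt$fixes, filt$fixes$bear_id),
                                   function(tr) exclude_den(tr, dens[[tr$bear_id[1]]])))
    steps <- build_steps(fixes, config$fix_interval_min)
    steps <- assign_diel(steps, config$lat, config$lon)
    steps <- assign_season(steps, den_dates = dens)
    env$steps <- steps
    utils::write.csv(steps, outfile("steps.csv"), row.names = FALSE)
  })

  run_stage("hmm", function() {
    fits <- list(); decoded <- list()
    for (id in unique(env$steps$bear_id)) {
      st <- env$steps[env$steps$bear_id == id, ]
      fit <- fit_hmm(st, n_restarts = config$hmm_restarts,
                     seed = config$seed + 10)
      fits[[id]] <- fit
      decoded[[id]] <- decode_states(fit, st)
    }
    env$hmm_fits <- fits
    env$steps <- do.call(rbind, decoded)
    rownames(env$steps) <- NULL
    summ <- do.call(rbind, lapply(names(fits), function(id) {
      f <- fits[[id]]
      data.frame(bear_id = id,
                 t(setNames(f$par$step_mean, paste0("step_mean_", 1:3))),
                 t(setNames(f$par$step_sd, paste0("step_sd_", 1:3))),
                 loglik = f$loglik, AIC = f$AIC, converged = f$convergence)
    }))
    utils::write.csv(summ, outfile("hmm_summary.csv"), row.names = FALSE)
    utils::write.csv(env$steps, outfile("steps_decoded.csv"),
                     row.names = FALSE)
    env$move_steps <- extract_movement_steps(env$steps)
  })

  run_stage("seasons", function() {
    if (identical(config$season_mode, "cluster")) {
      feats <- build_season_features(env$steps, env$ls)
      fc <- grep("bear_year|date", names(feats), invert = TRUE)
      gap <- choose_k_gap(feats[fc], seed = config$seed + 20)
      utils::write.csv(gap$gap, outfile("gap_curve.csv"), row.names = FALSE)
      km <- stats::kmeans(as.matrix(feats[fc]), gap$k, nstart = 10)
      cal <- derive_season_dates(data.frame(date = feats$date,
                                            cluster = km$cluster))
      env$steps$season <- season_of_date(as.Date(env$steps$t_start), cal)
      env$move_steps <- extract_movement_steps(env$steps)
      note("seasons: k = ", gap$k)
      env$calendar <- cal
    } else env$calendar <- season_calendar()
    cal_df <- do.call(rbind, lapply(names(env$calendar), function(nm)
      data.frame(season = nm, start = env$calendar[[nm]][1],
                 end = env$calendar[[nm]][2])))
    utils::write.csv(cal_df, outfile("season_calendar.csv"),
                     row.names = FALSE)
  })

  run_stage("diel", function() {
    env$hr <- list()
    for (id in unique(env$steps$bear_id)) {
      env$hr[[id]] <- list()
      st <- env$steps[env$steps$bear_id == id, ]
      for (sea in levels(droplevels(st$season))) {
        ss <- st[st$season == sea, ]
        if (nrow(ss) < 30) next
        env$hr[[id]][[sea]] <- estimate_kde_home_range(
          data.frame(x = ss$x2, y = ss$y2), env$ls,
          bear_id = id, season = sea)
      }
    }
    bl <- bootstrap_step_lengths(env$move_steps, n_boot = config$n_boot,
                                 seed = config$seed + 30,
                                 tz_offset_hours = config$tz_offset_hours)
    utils::write.csv(bl, outfile("step_length_bins.csv"), row.names = FALSE)
    cats <- list(forest = intersect(c("deciduous", "coniferous", "mixed"),
                                    names(env$ls$layers)),
                 wetland = "forested_wetland",
                 agriculture = "agriculture",
                 roads = "roads",
                 residential = "residential_low")
    sr <- selection_ratio_by_bin(env$move_steps, env$hr, env$ls, cats,
                                 n_boot = config$n_boot,
                                 seed = config$seed + 31,
                                 tz_offset_hours = config$tz_offset_hours)
    utils::write.csv(sr, outfile("selection_ratios.csv"), row.names = FALSE)
    env$ratios <- sr
  })

  run_stage("ssf", function() {
    env$scales <- compute_scales(env$move_steps,
                                 horizons_min = config$scale_horizons_min,
                                 fix_interval_min = config$fix_interval_min)
    env$ssf <- list()
    rows <- list()
    for (id in unique(env$move_steps$bear_id)) {
      st <- env$move_steps[env$move_steps$bear_id == id, ]
      m <- tryCatch(fit_ssf(st, env$ls, env$scales,
                            layers = config$ssf_layers, bear_id = id),
                    error = function(e) NULL)
      if (is.null(m)) { note("ssf: bear ", id, " skipped"); next }
      env$ssf[[id]] <- m
      if (length(m$variables))
        rows[[id]] <- data.frame(bear_id = id, variable = m$variables,
                                 scale_m = unname(m$scales),
                                 beta = unname(m$beta), se = unname(m$se),
                                 aicc = m$aicc, n = m$n)
    }
    utils::write.csv(do.call(rbind, rows), outfile("ssf_models.csv"),
                     row.names = FALSE)
  })

  run_stage("hrhd", function() {
    rows <- do.call(rbind, lapply(names(env$ssf), function(id) {
      m <- env$ssf[[id]]
      if (!("impervious" %in% m$variables)) return(NULL)
      hr <- env$hr[[id]][[1]]
      if (is.null(hr)) return(NULL)
      data.frame(bear_id = id,
                 hrhd = housing_density_in_home_range(hr, env$housing),
                 beta = unname(m$beta[["impervious"]]))
    }))
    if (is.null(rows) || nrow(rows) < config$hrhd_min_bears) {
      note("hrhd: skipped (", if (is.null(rows)) 0 else nrow(rows),
           " bears with an impervious coefficient, need ",
           config$hrhd_min_bears, ")")
    } else {
      env$hrhd <- fit_coefficient_curves(rows,
                                         min_bears = config$hrhd_min_bears,
                                         seed = config$seed + 40)
      utils::write.csv(data.frame(model = names(env$hrhd$aicc),
                                  aicc = unname(env$hrhd$aicc)),
                       outfile("hrhd_aicc.csv"), row.names = FALSE)
      utils::write.csv(rows, outfile("hrhd_bears.csv"), row.names = FALSE)
    }
  })

  run_stage("surfaces", function() {
    ids <- names(env$ssf)
    if (!length(ids)) stop("no fitted SSF models")
    surfs <- lapply(ids, function(id)
      predict_bear_surface(env$ssf[[id]], env$ls))
    cents <- t(vapply(ids, function(id)
      env$hr[[id]][[1]]$centroid, numeric(2)))
    comb <- weight_and_combine(surfs, cents)
    utils::write.table(comb$values, outfile("surface_combined.txt"),
                       row.names = FALSE, col.names = FALSE)
    ## validation against fresh hold-out bears simulated from the same
    ## study conditions (new home ranges, coefficients from the same
    ## population schedule)
    ext <- ls_extent(env$ls)
    set.seed(config$seed + 60)
    hb <- lapply(1:12, function(i)
      bear_config(sprintf("H%02d", i),
                  c(runif(1, ext["xmin"] + 0.15 * diff(ext[1:2]),
                          ext["xmin"] + 0.85 * diff(ext[1:2])),
                    runif(1, ext["ymin"] + 0.15 * diff(ext[3:4]),
                          ext["ymin"] + 0.85 * diff(ext[3:4]))),
                  coefficients = demo_bears(config, ext)[[1]]$coefficients,
                  fix_interval_min = config$fix_interval_min,
                  home_bias = 0.1, home_range_scale = 4000))
    hstudy <- synthetic_study(env$ls, env$housing, hb,
                              seed = config$seed + 61)
    htr <- simulate_tracks(hstudy, duration_days = 30,
                           start = config$start, seed = config$seed + 62)
    hst <- build_steps(htr, config$fix_interval_min)
    bi <- tryCatch(boyce_index(comb, data.frame(x = hst$x2, y = hst$y2),
                               n_bins = config$boyce_bins),
                   error = function(e) NULL)
    env$boyce <- bi
    if (!is.null(bi))
      utils::write.csv(data.frame(boyce = bi$correlation,
                                  n_points = bi$n_points),
                       outfile("boyce.csv"), row.names = FALSE)
    env$surface <- comb
  })

  files <- list.files(out_dir, full.names = TRUE)
  manifest$files <- data.frame(file = basename(files),
                               md5 = unname(tools::md5sum(files)),
                               row.names = NULL)
  utils::write.csv(manifest$files, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest$env <- env
  invisible(manifest)
}
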