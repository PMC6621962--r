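test_that("used extraction matches brute-force cell enumeration", {
  set.seed(4)
  m <- matrix(runif(50 * 50), 50, 50)
  ls <- toy_landscape(m, res = 10)
  steps <- data.frame(x1 = c(105, 230, 17), y1 = c(120, 310, 52),
                      x2 = c(160, 120, 28), y2 = c(180, 295, 40))
  got <- extract_used(steps, ls, buffer = 30)
  ## oracle: enumerate every cell center, point-to-segment distance by hand
  for (i in seq_len(nrow(steps))) {
    vals <- c()
    for (r in 1:50) for (cc in 1:50) {
      px <- (cc - 0.5) * 10; py <- (r - 0.5) * 10
      vx <- steps$x2[i] - steps$x1[i]; vy <- steps$y2[i] - steps$y1[i]
      tt <- ((px - steps$x1[i]) * vx + (py - steps$y1[i]) * vy) /
        (vx^2 + vy^2)
      tt <- min(1, max(0, tt))
      d <- sqrt((px - (steps$x1[i] + tt * vx))^2 +
                  (py - (steps$y1[i] + tt * vy))^2)
      if (d <= 30) vals <- c(vals, m[r, cc])
    }
    expect_equal(unname(got[i, "v"]), mean(vals), tolerance = 1e-9)
  }
})

test_that("used extraction handles constants, patches and off-raster steps", {
  ls <- toy_landscape(matrix(2.5, 40, 40), res = 30)
  st <- data.frame(x1 = 300, y1 = 300, x2 = 500, y2 = 400)
  expect_equal(unname(extract_used(st, ls)[1, "v"]), 2.5)
  ## a step wholly inside a wide categorical patch has proportion 1
  patch <- matrix(0, 40, 40); patch[10:30, 10:30] <- 1
  lsp <- toy_landscape(patch, res = 30, kind = "categorical")
  stp <- data.frame(x1 = 500, y1 = 500, x2 = 650, y2 = 600)
  expect_equal(unname(extract_used(stp, lsp)[1, "v"]), 1)
  off <- data.frame(x1 = -500, y1 = -500, x2 = -400, y2 = -400)
  res <- extract_used(off, ls)
  expect_true(is.na(res[1, "v"]))
  expect_equal(attr(res, "n_dropped"), 1)
})

test_that("available extraction matches the weighted brute force", {
  set.seed(5)
  m <- matrix(runif(25), 5, 5)
  ls <- toy_landscape(m, res = 1)
  st <- data.frame(x1 = 2.5, y1 = 2.5, x2 = 2.5, y2 = 2.5)
  got <- unname(extract_available(st, ls, sigma = 1)[1, "v"])
  ## oracle: direct sum over all cells with per-axis truncation at 3 sd
  w <- num <- 0
  for (r in 1:5) for (cc in 1:5) {
    dx <- (cc - 0.5) - 2.5; dy <- (r - 0.5) - 2.5
    if (abs(dx) > 3 || abs(dy) > 3) next
    wi <- exp(-(dx^2 + dy^2) / 2)
    w <- w + wi; num <- num + wi * m[r, cc]
  }
  expect_equal(got, num / w, tolerance = 1e-10)
  ## constant layer -> the constant at any scale
  lsc <- toy_landscape(matrix(7, 30, 30), res = 30)
  stc <- data.frame(x1 = 450, y1 = 450, x2 = 460, y2 = 450)
  for (s in c(30, 300, 900))
    expect_equal(unname(extract_available(stc, lsc, s)[1, "v"]), 7)
  ## sigma much larger than the raster approaches the global mean
  set.seed(6)
  mr <- matrix(runif(900), 30, 30)
  lsr <- toy_landscape(mr, res = 30)
  big <- extract_available(data.frame(x1 = 450, y1 = 450, x2 = 450,
                                      y2 = 450), lsr, 50000)[1, "v"] |> unname()
  expect_lt(abs(big - mean(mr)), 0.001)
})

test_that("per-step and smoothed-raster availability agree", {
  set.seed(8)
  m <- matrix(runif(60 * 60), 60, 60)
  ls <- toy_landscape(m, res = 30)
  st <- data.frame(x1 = runif(20, 200, 1600), y1 = runif(20, 200, 1600),
                   x2 = runif(20, 200, 1600), y2 = runif(20, 200, 1600))
  a <- extract_available(st, ls, 90)
  b <- bearmove:::extract_available_smoothed(st, ls, 90)
  expect_equal(a, b, tolerance = 1e-10)
})

test_that("movement-distance scales behave like the motion that made them", {
  t0 <- as.POSIXct("2020-07-01", tz = "UTC")
  ## straight line at 8 m/min: 45-min displacement is exactly 360 m
  n <- 200
  fx <- data.frame(bear_id = "A", t_start = t0 + (0:(n - 1)) * 2700,
                   x1 = 8 * 45 * (0:(n - 1)), y1 = 0)
  fx$x2 <- fx$x1 + 360; fx$y2 <- 0; fx$t_end <- fx$t_start + 2700
  sc <- compute_scales(fx)
  expect_equal(unname(attr(sc, "horizon_means")["45"]), 360)
  expect_equal(unname(attr(sc, "horizon_means")["360"]), 2880)
  ## a pure random walk grows like the square root of the horizon
  set.seed(3)
  nrw <- 4000
  dx <- rnorm(nrw, 0, 100); dy <- rnorm(nrw, 0, 100)
  rw <- data.frame(bear_id = "A", t_start = t0 + (0:(nrw - 1)) * 2700,
                   x1 = cumsum(dx), y1 = cumsum(dy))
  rw$x2 <- c(rw$x1[-1], NA); rw$y2 <- c(rw$y1[-1], NA)
  rw$t_end <- rw$t_start + 2700
  hm <- attr(compute_scales(rw[-nrw, ]), "horizon_means")
  ratio <- unname(hm["180"] / hm["45"])
  expect_lt(abs(ratio - 2), 0.15)       # sqrt(4) = 2, within sampling error
  expect_error(compute_scales(fx, horizons_min = 30), "shorter")
  ## the six characteristic distances can also be supplied directly
  sset <- scale_set(c(360, 650, 837, 1007, 1288, 1523))
  expect_length(sset, 6)
  expect_error(scale_set(c(650, 360)))
})

test_that("z-scored design pairs have the documented properties", {
  set.seed(9)
  u <- runif(200, 10, 40); a <- runif(200, 10, 40)
  z <- bearmove:::standardize_pair(u, a)
  expect_lt(abs(mean(c(z$u, z$a))), 1e-12)
  expect_lt(abs(sd(c(z$u, z$a)) - 1), 1e-12)
  ## round trip
  expect_equal(z$u * z$sd + z$mean, u, tolerance = 1e-9)
  expect_null(bearmove:::standardize_pair(rep(2, 5), rep(2, 5)))
})

test_that("conditional-logit MLE matches a brute-force likelihood search", {
  u <- matrix(c(0.8, 0.1, 0.6), 3, 1, dimnames = list(NULL, "x"))
  a <- matrix(c(0.2, 0.4, 0.3), 3, 1, dimnames = list(NULL, "x"))
  fit <- fit_conditional_logit(u, a, min_strata = 1)
  grid <- seq(-10, 10, by = 1e-3)
  ll <- vapply(grid, function(b) paired_loglik(b, u, a), 0)
  expect_lt(abs(fit$beta - grid[which.max(ll)]), 1e-3)
  expect_equal(fit$loglik, max(ll), tolerance = 1e-4)
})

test_that("conditional-logit recovers coefficients and degenerate cases", {
  pairs <- sim_clogit_pairs(5000, c(0.8, -0.5), seed = 2)
  fit <- fit_conditional_logit(pairs$u, pairs$a)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta[1] - 0.8), 3 * fit$se[1])
  expect_lt(abs(fit$beta[2] + 0.5), 3 * fit$se[2])
  ## identical used and available: beta 0, loglik n log(1/2)
  x <- matrix(rnorm(50), 50, 1)
  f0 <- fit_conditional_logit(x, x)
  expect_equal(unname(f0$beta), 0)
  expect_equal(f0$loglik, 50 * log(0.5))
  ## swapping used/available negates the estimate exactly
  fswap <- fit_conditional_logit(pairs$a, pairs$u)
  expect_equal(unname(fswap$beta), -unname(fit$beta), tolerance = 1e-6)
  ## complete separation is flagged
  us <- matrix(1:20 + 0.5, 20, 1); av <- matrix(1:20 - 0.5, 20, 1)
  colnames(us) <- colnames(av) <- "x"
  fs <- fit_conditional_logit(us, av)
  expect_true(fs$separated)
  expect_false(is.finite(fs$beta[1]))
})

test_that("the hand-rolled paired likelihood agrees with survival::clogit", {
  skip_if_not_installed("survival")
  pairs <- sim_clogit_pairs(400, c(0.6, -0.9), seed = 7)
  fit <- fit_conditional_logit(pairs$u, pairs$a)
  df <- data.frame(y = rep(c(1, 0), each = 400),
                   rbind(pairs$u, pairs$a),
                   stratum = rep(1:400, 2))
  cf <- survival::coxph(survival::Surv(rep(1, nrow(df)), y) ~
    v1 + v2 + survival::strata(stratum), data = df, method = "exact")
  expect_equal(unname(fit$beta), unname(coef(cf)), tolerance = 1e-5)
})

test_that("AICc follows the closed form", {
  expect_equal(aicc(-10, 2, 20), 24.70588, tolerance = 1e-5)
  expect_equal(aicc(-10, 0, 20), 20)
  ## the correction is nonnegative and vanishes with n
  expect_gte(aicc(-10, 3, 30), -2 * -10 + 2 * 3)
  expect_lt(aicc(-10, 3, 1e7) - (-2 * -10 + 2 * 3), 1e-5)
  expect_error(aicc(-10, 19, 20), "undefined")
})

test_that("characteristic-scale ties and singletons resolve as documented", {
  set.seed(10)
  m <- matrix(runif(80 * 80), 80, 80)
  ls <- toy_landscape(gaussian_smooth(m, 90, 30), res = 30)
  st <- data.frame(x1 = runif(60, 300, 2100), y1 = runif(60, 300, 2100))
  st$x2 <- st$x1 + rnorm(60, 0, 50); st$y2 <- st$y1 + rnorm(60, 0, 50)
  d1 <- build_ssf_design(st, ls, scale_set(150))
  cs1 <- select_characteristic_scales(d1)
  expect_equal(cs1$chosen$scale, 150)
  ## duplicated scale values give identical designs; smaller label wins
  d2 <- build_ssf_design(st, ls, scale_set(c(150, 151)))
  d2$avail[["151"]] <- d2$avail[["150"]]
  cs2 <- select_characteristic_scales(d2)
  expect_equal(cs2$chosen$scale, 150)
})

test_that("correlation pruning drops the weaker of colinear variables", {
  set.seed(11)
  x <- rnorm(300)
  das <- list(u = cbind(a = x, b = x, c = rnorm(300)),
              a = cbind(a = x + rnorm(300, 0, 2), b = x + rnorm(300, 0, 2),
                        c = rnorm(300)))
  chosen <- data.frame(variable = c("a", "b", "c"), scale = 360,
                       aicc = c(10, 12, 11), stringsAsFactors = FALSE)
  ## duplicate variable: the higher-AICc copy goes
  das_dup <- list(u = cbind(a = x, b = x, c = rnorm(300)),
                  a = cbind(a = -x, b = -x, c = rnorm(300)))
  kept <- prune_correlated(das_dup, chosen)
  expect_true("a" %in% kept && !("b" %in% kept))
  ## r exactly at the threshold keeps both (strict inequality)
  y1 <- c(1, 2, 3, 4); y2 <- c(1, 3, 2, 4)
  r <- cor(y1, y2)
  das_thr <- list(u = cbind(a = y1, b = y2), a = cbind(a = y1, b = y2))
  chosen2 <- chosen[1:2, ]
  expect_equal(prune_correlated(das_thr, chosen2, r_max = r),
               c("a", "b"))
  ## uncorrelated set unchanged
  das_ok <- list(u = cbind(a = rnorm(100), b = rnorm(100)),
                 a = cbind(a = rnorm(100), b = rnorm(100)))
  expect_length(prune_correlated(das_ok, chosen2), 2)
})

test_that("stepwise selection is deterministic and respects the null", {
  pairs <- sim_clogit_pairs(800, c(1, 0), seed = 3)
  das <- list(u = pairs$u, a = pairs$a)
  s1 <- stepwise_select(das, c("v1", "v2"))
  s2 <- stepwise_select(das, c("v1", "v2"))
  expect_identical(s1$variables, s2$variables)
  expect_true("v1" %in% s1$variables)
  expect_lte(s1$aicc, s1$null_aicc)
  ## a pure-noise candidate only enters when it beats the null on AICc
  noise <- sim_clogit_pairs(500, 0, seed = 4)
  dn <- list(u = noise$u, a = noise$a)
  sn <- stepwise_select(dn, "v1")
  f1 <- fit_conditional_logit(noise$u, noise$a)
  expect_equal("v1" %in% sn$variables,
               aicc(f1$loglik, 1, 500) < sn$null_aicc)
})

test_that("a full single-bear SSF fit recovers known selection", {
  ## selection for a smoothed continuous resource, fitted end to end
  set.seed(20)
  nr <- 120; res <- 30
  f <- gaussian_smooth(matrix(rnorm(nr * nr), nr, nr), 200, res)
  f <- (f - mean(f)) / sd(f)
  junk <- gaussian_smooth(matrix(rnorm(nr * nr), nr, nr), 200, res)
  ls <- landscape_stack(list(resource = f, junk = junk), resolution = res)
  g <- f - gaussian_smooth(f, 650, res)
  w <- exp(1.5 * (g - mean(g)) / sd(g))
  cells <- sample.int(length(w), 600, replace = TRUE, prob = as.numeric(w))
  px <- ((cells - 1) %/% nr + runif(600)) * res
  py <- ((cells - 1) %% nr + runif(600)) * res
  st <- data.frame(x1 = px, y1 = py, x2 = px, y2 = py)
  m <- fit_ssf(st, ls, scale_set(c(360, 650, 1007)), bear_id = "B1")
  expect_s3_class(m, "bear_ssf")
  expect_true("resource" %in% m$variables)
  expect_gt(m$beta[["resource"]], 0)
  expect_lt(m$aicc, m$null_aicc)
})
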