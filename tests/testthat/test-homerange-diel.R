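test_that("the 95% isopleth holds just over 95% of the kernel mass", {
  ls <- make_landscape(dim = c(100, 100), seed = 2)
  set.seed(1)
  fx <- data.frame(x = rnorm(500, 1500, 250), y = rnorm(500, 1500, 250))
  hr <- estimate_kde_home_range(fx, ls)
  expect_gte(hr$mass_inside, 0.95)
  expect_lte(hr$mass_inside, 0.96)
  expect_true(all(hr$availability >= 0 & hr$availability <= 1 |
                    names(hr$availability) %in% c("impervious", "slope")))
  expect_error(estimate_kde_home_range(fx[rep(1, 40), ], ls), "identical|degenerate")
})

test_that("a symmetric ring of fixes centers the home range", {
  ls <- make_landscape(dim = c(100, 100), seed = 2)
  th <- seq(0, 2 * pi, length.out = 200)
  fx <- data.frame(x = 1500 + 500 * cos(th), y = 1500 + 500 * sin(th))
  hr <- estimate_kde_home_range(fx, ls)
  expect_lt(abs(hr$centroid["x"] - 1500), 30)
  expect_lt(abs(hr$centroid["y"] - 1500), 30)
  ## two distant clusters: isopleth may be disjoint, mass still >= 95%
  fx2 <- data.frame(x = c(rnorm(250, 700, 80), rnorm(250, 2300, 80)),
                    y = rnorm(500, 1500, 80))
  hr2 <- estimate_kde_home_range(fx2, ls)
  expect_gte(hr2$mass_inside, 0.95)
})

test_that("home-range housing density is total houses over area", {
  mask <- matrix(FALSE, 40, 40)
  mask[10:20, 10:29] <- TRUE                  # 11 x 20 cells
  hr <- structure(list(mask = mask), class = "home_range")
  housing <- matrix(75, 40, 40)               # 75 houses/km^2 everywhere
  expect_equal(housing_density_in_home_range(hr, housing), 75)
  expect_equal(housing_density_in_home_range(hr, housing * 0), 0)
  ## a 2 km^2 range at 75 houses/km^2 holds 150 houses
  area_km2 <- sum(mask) * (30 / 1000)^2
  expect_equal(75 * 2, 150)
  expect_equal(housing_density_in_home_range(hr, housing) * area_km2,
               75 * area_km2)
})

test_that("HRHD is robust to raster resolution", {
  dens_fun <- function(x, y) 50 + 40 * sin(x / 500) * cos(y / 700)
  mk <- function(n, res) {
    m <- outer(seq_len(n), seq_len(n),
               function(r, c) dens_fun((c - 0.5) * res, (r - 0.5) * res))
    toy_landscape(m, res = res, name = "deciduous")
  }
  ls30 <- mk(100, 30); ls15 <- mk(200, 15)
  set.seed(9)
  fx <- data.frame(x = rnorm(300, 1500, 300), y = rnorm(300, 1500, 300))
  h30 <- housing_density_in_home_range(estimate_kde_home_range(fx, ls30),
                                       ls30$layers$deciduous)
  h15 <- housing_density_in_home_range(estimate_kde_home_range(fx, ls15),
                                       ls15$layers$deciduous)
  expect_lt(abs(h30 - h15) / h30, 0.01)
})

test_that("bootstrapped bin means are consistent and degenerate-safe", {
  t0 <- as.POSIXct("2020-07-01 00:00:00", tz = "UTC")
  steps <- data.frame(bear_id = rep(c("A", "B", "C"), each = 40),
                      t_start = t0 + rep(seq(0, 39) * 2700, 3),
                      length = 200, season = "summer")
  out <- bootstrap_step_lengths(steps, n_boot = 200, seed = 1)
  expect_true(all(out$mean_length == 200))
  expect_true(all(out$ci_low == 200 & out$ci_high == 200))
  ## seeded reruns identical
  expect_identical(out, bootstrap_step_lengths(steps, n_boot = 200, seed = 1))
  ## bootstrap mean close to the point estimate with real variation
  set.seed(2)
  steps$length <- rgamma(nrow(steps), 2, 1 / 150)
  out2 <- bootstrap_step_lengths(steps, n_boot = 2000, seed = 3)
  bears <- split(steps, steps$bear_id)
  for (b in unique(out2$bin)) {
    sub <- steps[bearmove:::diel_bin(steps$t_start) == b, ]
    pt <- mean(tapply(sub$length, sub$bear_id, mean))
    est <- out2$mean_length[out2$bin == b]
    expect_lt(abs(est - pt) / pt, 0.01)
  }
  ## single-bear bins are flagged with no interval
  one <- steps[steps$bear_id == "A", ]
  out3 <- bootstrap_step_lengths(one, n_boot = 50, seed = 1)
  expect_true(all(out3$ci_flagged))
  expect_true(all(is.na(out3$ci_low)))
})

test_that("selection ratios equal use over availability", {
  ## landscape whose right half is agriculture
  m <- matrix(0, 60, 60); m[, 31:60] <- 1
  ls <- toy_landscape(m, res = 30, kind = "categorical", name = "agriculture")
  mask <- matrix(TRUE, 60, 60)
  hr <- structure(list(mask = mask), class = "home_range")
  t0 <- as.POSIXct("2020-07-01 12:00:00", tz = "UTC")
  mid <- 30 * 30                           # category boundary at x = 900
  steps <- data.frame(bear_id = "A", t_start = t0,
                      x1 = mid - 150, y1 = 900, x2 = mid + 150, y2 = 900,
                      length = 300, season = "summer")
  frac <- step_path_fraction(ls, steps, "agriculture")
  expect_lt(abs(frac - 0.5), 0.03)
  out <- selection_ratio_by_bin(steps, list(A = list(summer = hr)), ls,
                                list(agriculture = "agriculture"),
                                n_boot = 10, seed = 1)
  expect_lt(abs(out$mean_ratio - frac / 0.5), 1e-9)
  ## category covering everything gives ratio exactly 1
  m1 <- matrix(1, 60, 60)
  ls1 <- toy_landscape(m1, res = 30, kind = "categorical", name = "agriculture")
  out1 <- selection_ratio_by_bin(steps, list(A = list(summer = hr)), ls1,
                                 list(agriculture = "agriculture"),
                                 n_boot = 10, seed = 1)
  expect_equal(out1$mean_ratio, 1)
  ## zero availability excludes the bear with a warning
  m0 <- matrix(0, 60, 60)
  ls0 <- toy_landscape(m0, res = 30, kind = "categorical", name = "agriculture")
  expect_warning(
    out0 <- selection_ratio_by_bin(steps, list(A = list(summer = hr)), ls0,
                                   list(agriculture = "agriculture"),
                                   n_boot = 10, seed = 1),
    "unavailable")
  expect_true(is.null(out0) || nrow(out0) == 0)
})

test_that("ratios are unchanged by rescaling steps inside uniform habitat", {
  m <- matrix(0, 60, 60); m[, 1:30] <- 1
  ls <- toy_landscape(m, res = 30, kind = "categorical", name = "forest")
  hr <- structure(list(mask = matrix(TRUE, 60, 60)), class = "home_range")
  t0 <- as.POSIXct("2020-07-01 12:00:00", tz = "UTC")
  st1 <- data.frame(bear_id = "A", t_start = t0, x1 = 300, y1 = 300,
                    x2 = 400, y2 = 300, length = 100, season = "summer")
  st2 <- within(st1, { x2 <- 500; length <- 200 })  # doubled, still in class
  r1 <- selection_ratio_by_bin(st1, list(A = list(summer = hr)), ls,
                               list(forest = "forest"), n_boot = 5, seed = 1)
  r2 <- selection_ratio_by_bin(st2, list(A = list(summer = hr)), ls,
                               list(forest = "forest"), n_boot = 5, seed = 1)
  expect_equal(r1$mean_ratio, r2$mean_ratio)
})
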