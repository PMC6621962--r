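## a minimal fitted-model stub for surface prediction
stub_ssf <- function(variables, beta, scales, z_mean, z_sd, bear = "B1") {
  structure(list(bear_id = bear, season = "all", diel = "all",
                 variables = variables,
                 scales = setNames(scales, variables),
                 beta = setNames(beta, variables),
                 z = data.frame(variable = variables, scale = scales,
                                mean = z_mean, sd = z_sd,
                                stringsAsFactors = FALSE)),
            class = "bear_ssf")
}

test_that("surface prediction is the exponentiated standardized predictor", {
  set.seed(2)
  m <- gaussian_smooth(matrix(runif(50 * 50), 50, 50), 60, 30)
  ls <- toy_landscape(m, res = 30, name = "resource")
  ## null model: surface identically one
  s0 <- predict_bear_surface(stub_ssf(character(), numeric(), numeric(),
                                      numeric(), numeric()), ls)
  expect_true(all(s0$values == 1))
  ## single positive coefficient: ranks follow the smoothed covariate
  mod <- stub_ssf("resource", 1.2, 90, 0.5, 0.1)
  s1 <- predict_bear_surface(mod, ls)
  sm <- gaussian_smooth(m, 90, 30)
  expect_equal(order(s1$values), order(sm))
  ## hand spot-check of one pixel
  pix <- c(17, 23)
  expect_equal(s1$values[pix[1], pix[2]],
               exp(1.2 * (sm[pix[1], pix[2]] - 0.5) / 0.1),
               tolerance = 1e-9)
  expect_error(predict_bear_surface(stub_ssf("missing", 1, 90, 0, 1), ls),
               "lacks")
})

test_that("inverse-distance combination is a per-pixel convex mixture", {
  ls <- toy_landscape(matrix(0, 40, 40), res = 30, name = "v")
  sA <- bearmove:::movement_surface(matrix(1, 40, 40), ls, "A")
  sB <- bearmove:::movement_surface(matrix(3, 40, 40), ls, "B")
  cents <- rbind(c(300, 600), c(900, 600))
  comb <- weight_and_combine(list(sA, sB), cents)
  w <- attr(comb, "weights")
  total <- w[[1]] + w[[2]]
  expect_true(max(abs(total - 1)) < 1e-9)
  ## pixels equidistant from both centroids average the two surfaces
  cx <- ls$origin[1] + (col(total) - 0.5) * 30
  cy <- ls$origin[2] + (row(total) - 0.5) * 30
  dA <- sqrt((cx - 300)^2 + (cy - 600)^2)
  dB <- sqrt((cx - 900)^2 + (cy - 600)^2)
  mid <- abs(dA - dB) < 1e-9
  expect_true(all(abs(comb$values[mid] - 2) < 1e-9))
  ## bounded by the per-bear extremes everywhere
  expect_true(all(comb$values >= 1 - 1e-12 & comb$values <= 3 + 1e-12))
  ## single surface passes through unchanged
  alone <- weight_and_combine(list(sB), cents[2, , drop = FALSE])
  expect_equal(alone$values, sB$values)
  expect_error(weight_and_combine(list(sA), rbind(c(-5000, 0))), "outside")
})

test_that("combination respects min/max bounds with varying surfaces", {
  set.seed(5)
  ls <- toy_landscape(matrix(0, 30, 30), res = 30, name = "v")
  vals <- lapply(1:3, function(i)
    matrix(exp(rnorm(900)), 30, 30))
  surfs <- lapply(vals, function(v) bearmove:::movement_surface(v, ls, "x"))
  cents <- cbind(runif(3, 100, 800), runif(3, 100, 800))
  comb <- weight_and_combine(surfs, cents)
  lo <- pmin(vals[[1]], pmin(vals[[2]], vals[[3]]))
  hi <- pmax(vals[[1]], pmax(vals[[2]], vals[[3]]))
  expect_true(all(comb$values >= lo - 1e-12 & comb$values <= hi + 1e-12))
})

test_that("the Boyce index separates calibrated from uninformative surfaces", {
  set.seed(9)
  m <- gaussian_smooth(matrix(runif(80 * 80), 80, 80), 120, 30)
  v <- matrix(rank(m) / length(m), 80, 80)
  ls <- toy_landscape(v, res = 30, name = "v")
  surf <- bearmove:::movement_surface(0.1 + v, ls, "x")
  set.seed(10)
  pts <- sample_points_from_surface(surf, 2000)
  b <- boyce_index(surf, pts, n_bins = 20)
  expect_gte(b$correlation, 0.9)
  unif <- sample_points_from_surface(surf, 2000, uniform = TRUE)
  b0 <- boyce_index(surf, unif, n_bins = 20)
  expect_lt(abs(b0$correlation), 0.6)
  ## strictly increasing predicted-to-expected ratios give exactly 1
  fake <- list(correlation = cor(1:5, c(0.1, 0.5, 1, 2, 5),
                                 method = "spearman"))
  expect_equal(fake$correlation, 1)
  expect_error(boyce_index(surf, pts[1:10, ]), "at least 50")
})

test_that("surface comparison matches hand-computed Pearson and masks", {
  ls3 <- toy_landscape(matrix(0, 3, 3), res = 30, name = "v")
  A <- bearmove:::movement_surface(matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                                          3, 3), ls3, "a")
  B <- bearmove:::movement_surface(matrix(c(2, 1, 3, 5, 4, 6, 8, 7, 10),
                                          3, 3), ls3, "b")
  cmp <- compare_surfaces(A, B)
  expect_equal(cmp$pearson,
               cor(as.numeric(A$values), as.numeric(B$values)),
               tolerance = 1e-12)
  expect_equal(cmp$diff, A$values - B$values)
  ## identical surfaces: r = 1, zero differences, empty masks
  same <- compare_surfaces(A, A)
  expect_equal(same$pearson, 1)
  expect_true(all(same$diff == 0))
  expect_false(any(same$pos_mask) || any(same$neg_mask))
  ## scaling invariance of the correlation
  B2 <- bearmove:::movement_surface(2 * A$values, ls3, "b2")
  expect_equal(compare_surfaces(A, B2)$pearson, 1)
  ## constant surface flags an undefined correlation
  C <- bearmove:::movement_surface(matrix(1, 3, 3), ls3, "c")
  expect_warning(cc <- compare_surfaces(A, C), "constant")
  expect_true(is.na(cc$pearson))
})
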