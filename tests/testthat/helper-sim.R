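## Shared fixtures and independent oracles, all built in code.

## tiny single-layer landscape from an explicit matrix
toy_landscape <- function(m, res = 30, kind = "continuous", name = "v") {
  layers <- setNames(list(m), name)
  landscape_stack(layers, resolution = res,
                  kind = setNames(kind, name))
}

## Independent oracle: HMM log-likelihood by brute-force enumeration over
## all S^n state paths (no forward recursion).
enum_hmm_loglik <- function(par, length, angle) {
  S <- base::length(par$step_mean)
  n <- base::length(length)
  dens <- matrix(0, n, S)
  for (s in seq_len(S)) {
    dens[, s] <- dgamma(length,
                        shape = (par$step_mean[s] / par$step_sd[s])^2,
                        rate = par$step_mean[s] / par$step_sd[s]^2)
    ok <- !is.na(angle)
    vm <- exp(par$angle_kappa[s] * (cos(angle[ok] - par$angle_mean[s]) - 1)) /
      (2 * pi * besselI(par$angle_kappa[s], 0, expon.scaled = TRUE))
    dens[ok, s] <- dens[ok, s] * vm
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), n)))
  total <- 0
  for (i in seq_len(nrow(paths))) {
    p <- paths[i, ]
    lik <- par$delta[p[1]] * dens[1, p[1]]
    if (n > 1) for (t in 2:n)
      lik <- lik * par$Gamma[p[t - 1], p[t]] * dens[t, p[t]]
    total <- total + lik
  }
  log(total)
}

## simulate 1:1 matched conditional-logit pairs at the design level:
## two candidates per stratum, the used one drawn by the paired logit
sim_clogit_pairs <- function(n, beta, seed = 1) {
  set.seed(seed)
  p <- length(beta)
  xa <- matrix(rnorm(n * p), n, p)
  xb <- matrix(rnorm(n * p), n, p)
  pr_a <- plogis(drop((xa - xb) %*% beta))
  pick_a <- runif(n) < pr_a
  u <- ifelse(matrix(pick_a, n, p), xa, xb)
  a <- ifelse(matrix(pick_a, n, p), xb, xa)
  colnames(u) <- colnames(a) <- paste0("v", seq_len(p))
  list(u = u, a = a)
}

## Independent oracle: paired conditional-logit log-likelihood evaluated at
## an arbitrary beta (direct from the definition, not the fitting code)
paired_loglik <- function(beta, u, a) {
  lu <- drop(as.matrix(u) %*% beta)
  la <- drop(as.matrix(a) %*% beta)
  sum(lu - log(exp(lu) + exp(la)))
}

## one replicate of the characteristic-scale recovery experiment: a
## two-scale landscape (fine + coarse structure), point locations selected
## on the local-minus-650 m-neighborhood contrast, characteristic scale
## chosen from the six-scale ladder
scale_recovery_rep <- function(seed, beta = 2, n_steps = 2000,
                               true_scale = 650,
                               scales = scale_set(c(360, 650, 837, 1007,
                                                    1288, 1523))) {
  set.seed(seed)
  nr <- 150; nc <- 150; res <- 30
  fine <- gaussian_smooth(matrix(rnorm(nr * nc), nr, nc), 100, res)
  coarse <- gaussian_smooth(matrix(rnorm(nr * nc), nr, nc), 900, res)
  f <- fine / sd(fine) + coarse / sd(coarse)
  f <- (f - mean(f)) / sd(f)
  ls <- landscape_stack(list(resource = f), resolution = res)
  g <- f - gaussian_smooth(f, true_scale, res)
  g <- (g - mean(g)) / sd(g)
  w <- exp(beta * g)
  cells <- sample.int(length(w), n_steps, replace = TRUE,
                      prob = as.numeric(w))
  rr <- (cells - 1) %% nr + 1; cc <- (cells - 1) %/% nr + 1
  px <- (cc - 1 + runif(n_steps)) * res
  py <- (rr - 1 + runif(n_steps)) * res
  sdf <- data.frame(x1 = px, y1 = py, x2 = px, y2 = py)
  des <- build_ssf_design(sdf, ls, scales)
  cs <- select_characteristic_scales(des)
  sc <- cs$chosen$scale[cs$chosen$variable == "resource"]
  if (length(sc) != 1) NA_real_ else sc
}

## small single-bear synthetic study on a compact landscape
small_study <- function(seed = 1, dim = c(100, 100), coefficients = NULL,
                        n_bears = 1, ...) {
  ls <- make_landscape(dim = dim, seed = seed)
  h <- make_housing_density(ls, seed = seed + 1)
  ext <- ls_extent(ls)
  centers <- cbind(seq(0.35, 0.65, length.out = n_bears) *
                     (ext["xmax"] - ext["xmin"]),
                   seq(0.65, 0.35, length.out = n_bears) *
                     (ext["ymax"] - ext["ymin"]))
  bears <- lapply(seq_len(n_bears), function(i)
    bear_config(sprintf("B%02d", i), centers[i, ],
                coefficients = coefficients, ...))
  synthetic_study(ls, h, bears, seed = seed + 2)
}
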