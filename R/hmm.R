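## Three-state hidden Markov movement model: gamma step lengths, von Mises
## turning angles, shared transition matrix. Likelihood is the scaled
## forward recursion (C++); estimation is direct numerical maximization in
## an unconstrained working parameterization with multiple restarts, the
## approach the movement-HMM literature standardizes on.

## --- working parameterization -------------------------------------------

hmm_pack <- function(par) {
  G <- par$Gamma
  off <- log(sweep(G, 1, diag(G), "/"))
  c(log(par$step_mean), log(par$step_sd), par$angle_mean,
    log(pmax(par$angle_kappa, 1e-8)),
    off[row(off) != col(off)])
}

hmm_unpack <- function(w, S = 3) {
  step_mean <- exp(w[1:S])
  step_sd <- exp(w[S + 1:S])
  angle_mean <- wrap_angle(w[2 * S + 1:S])
  kappa <- exp(w[3 * S + 1:S])
  off <- w[4 * S + seq_len(S * (S - 1))]
  G <- diag(S) * 0
  G[row(G) != col(G)] <- exp(off)
  diag(G) <- 1
  G <- G / rowSums(G)
  hmm_par(step_mean, step_sd, angle_mean, kappa, G)
}

## accept either column name for the turning angle
step_angles <- function(steps)
  if (!is.null(steps$turning_angle)) steps$turning_angle else steps$angle

## replace exact zeros by half the minimum positive length (gamma density
## is undefined at zero; collars round very short displacements to zero)
prep_lengths <- function(len) {
  if (any(len == 0)) {
    halfmin <- min(len[len > 0]) / 2
    len[len == 0] <- halfmin
  }
  len
}

## n x S log emission densities; the angular term is omitted where the
## turning angle is undefined (first step of a burst)
log_emission <- function(length, angle, par) {
  S <- length(par$step_mean)
  n <- length(length)
  ld <- matrix(0, n, S)
  has_a <- !is.na(angle)
  for (s in seq_len(S)) {
    ld[, s] <- dgamma(length, shape = gamma_shape(par$step_mean[s], par$step_sd[s]),
                      rate = gamma_rate(par$step_mean[s], par$step_sd[s]),
                      log = TRUE)
    ld[has_a, s] <- ld[has_a, s] +
      dvonmises(angle[has_a], par$angle_mean[s], par$angle_kappa[s], log = TRUE)
  }
  ld
}

#' Forward log-likelihood of a step sequence under a movement HMM
#'
#' @param par an [hmm_par()].
#' @param length,angle step lengths (m) and turning angles (radians, NA
#'   where undefined).
#' @export
hmm_loglik <- function(par, length, angle) {
  forward_loglik_cpp(log_emission(prep_lengths(length), angle, par),
                     par$Gamma, par$delta)
}

#' Fit a three-state movement HMM
#'
#' Maximum-likelihood fit of gamma step lengths and von Mises turning
#' angles with a full 3x3 transition matrix, by BFGS on the forward
#' log-likelihood with `n_restarts` perturbed quantile-based starting
#' points. The initial state distribution is tied to the stationary
#' distribution of the transition matrix. States are relabeled in
#' increasing order of mean step length, so state 3 is the long-step
#' directed *movement* state.
#'
#' @param steps step data.frame (needs `length` and `turning_angle`), or any
#'   data.frame with those columns; typically one bear.
#' @param par0 optional [hmm_par()] starting values.
#' @param n_restarts random restarts (default 10).
#' @param seed integer seed for the restart draws.
#' @param maxit optimizer iteration cap per restart.
#' @return object of class `bear_hmm`: fitted `par`, `loglik`, `AIC`,
#'   `convergence`, the per-restart log-likelihood `restart_loglik`, and
#'   the data the model was fitted to.
#' @export
fit_hmm <- function(steps, par0 = NULL, n_restarts = 10, seed = NULL,
                    maxit = 300) {
  len <- prep_lengths(steps$length)
  ang <- step_angles(steps)
  if (sum(!is.na(ang)) < 200)
    stop("need at least 200 steps with defined turning angles")
  if (!is.null(seed)) set.seed(seed)

  nll <- function(w) {
    p <- try(hmm_unpack(w), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    ll <- forward_loglik_cpp(log_emission(len, ang, p), p$Gamma, p$delta)
    if (!is.finite(ll)) 1e10 else -ll
  }

  q <- unname(quantile(len, c(0.25, 0.5, 0.8)))
  starts <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    p0 <- if (!is.null(par0) && r == 1) par0 else
      hmm_par(step_mean = q * exp(rnorm(3, 0, 0.3)),
              step_sd = q * exp(rnorm(3, 0, 0.3)),
              angle_mean = c(runif(1, -pi, pi), 0, 0),
              angle_kappa = exp(rnorm(3, log(c(0.5, 1, 1)), 0.5)))
    starts[[r]] <- hmm_pack(p0)
  }

  best <- NULL
  restart_ll <- rep(NA_real_, n_restarts)
  for (r in seq_len(n_restarts)) {
    fit <- try(optim(starts[[r]], nll, method = "BFGS",
                     control = list(maxit = maxit, reltol = 1e-10)),
               silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$value) ||
        fit$value >= 1e10) next
    restart_ll[r] <- -fit$value
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("HMM did not converge in any restart")

  par <- hmm_unpack(best$par)
  o <- order(par$step_mean)            # canonical labels: movement = 3
  par <- hmm_par(par$step_mean[o], par$step_sd[o], par$angle_mean[o],
                 par$angle_kappa[o], par$Gamma[o, o, drop = FALSE])
  structure(list(par = par, loglik = -best$value,
                 n = length(len), n_par = length(best$par),
                 AIC = 2 * best$value + 2 * length(best$par),
                 convergence = best$convergence == 0,
                 restart_loglik = restart_ll,
                 data = data.frame(length = len, angle = ang)),
            class = "bear_hmm")
}

#' @export
print.bear_hmm <- function(x, ...) {
  cat("3-state movement HMM  (logLik", format(x$loglik, digits = 8),
      " n =", x$n, ")\n")
  s <- cbind(`step mean (m)` = x$par$step_mean, `step sd` = x$par$step_sd,
             `angle mean` = x$par$angle_mean, kappa = x$par$angle_kappa)
  rownames(s) <- c("encamped", "foraging", "movement")
  print(round(s, 3))
  cat("transition matrix:\n")
  print(round(x$par$Gamma, 3))
  invisible(x)
}

#' @export
summary.bear_hmm <- function(object, ...) {
  print(object)
  cat("AIC:", format(object$AIC, digits = 8),
      " converged:", object$convergence, "\n")
  invisible(object)
}

#' @export
logLik.bear_hmm <- function(object, ...)
  structure(object$loglik, df = object$n_par, nobs = object$n,
            class = "logLik")

#' @export
simulate.bear_hmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  r_hmm_steps(object$par, nsim)
}

## Viterbi most-probable state path (log space)
viterbi_path <- function(par, length, angle) {
  ld <- log_emission(prep_lengths(length), angle, par)
  n <- nrow(ld); S <- ncol(ld)
  lG <- log(par$Gamma)
  phi <- matrix(-Inf, n, S)
  bp <- matrix(0L, n, S)
  phi[1, ] <- log(par$delta) + ld[1, ]
  for (t in 2:n) {
    for (s in seq_len(S)) {
      v <- phi[t - 1, ] + lG[, s]
      bp[t, s] <- which.max(v)
      phi[t, s] <- v[bp[t, s]] + ld[t, s]
    }
  }
  path <- integer(n)
  path[n] <- which.max(phi[n, ])
  for (t in (n - 1):1) path[t] <- bp[t + 1, path[t + 1]]
  path
}

#' Decode behavioral states
#'
#' Labels each step with its Viterbi most-probable state under a fitted
#' model. The step set must be the one the model was fitted to.
#'
#' @param fit a `bear_hmm`.
#' @param steps the same steps passed to [fit_hmm()].
#' @return steps with a `behavior_state` factor
#'   (`encamped`/`foraging`/`movement`).
#' @export
decode_states <- function(fit, steps) {
  len <- prep_lengths(steps$length)
  if (nrow(steps) != fit$n || max(abs(len - fit$data$length)) > 1e-9)
    stop("step set differs from the one the model was fitted to")
  path <- viterbi_path(fit$par, len, step_angles(steps))
  steps$behavior_state <- factor(c("encamped", "foraging", "movement")[path],
                                 levels = c("encamped", "foraging", "movement"))
  steps
}

#' Keep only movement-state steps
#' @param steps decoded steps.
#' @export
extract_movement_steps <- function(steps)
  steps[steps$behavior_state == "movement", , drop = FALSE]
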