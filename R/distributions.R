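## Circular (von Mises) density and sampler, plus gamma mean/sd helpers.
## The von Mises sampler is Best & Fisher's (1979) rejection algorithm, the
## standard method; base R has no circular distributions.

#' Von Mises density
#' @param theta angles in radians.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0; 0 is the circular uniform).
#' @param log return log-density?
#' @export
dvonmises <- function(theta, mu = 0, kappa = 1, log = FALSE) {
  stopifnot(kappa >= 0)
  ## besselI overflows for large kappa; use the exponentially scaled form
  ld <- kappa * (cos(theta - mu) - 1) -
    log(2 * pi) - log(besselI(kappa, 0, expon.scaled = TRUE))
  if (log) ld else exp(ld)
}

#' Von Mises random deviates
#' @param n number of draws.
#' @inheritParams dvonmises
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) break
    }
    out[i] <- sign(u[3] - 0.5) * acos(f)
  }
  wrap_angle(out + mu)
}

## wrap radians into (-pi, pi]
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

## gamma mean/sd <-> shape/rate
gamma_shape <- function(mean, sd) (mean / sd)^2
gamma_rate <- function(mean, sd) mean / sd^2
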