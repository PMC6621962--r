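#' Model impervious-surface selection against home-range housing density
#'
#' Tests development acclimation: bears with more housing in their home
#' ranges are expected to show weaker avoidance (a less negative
#' standardized coefficient) of percent impervious surface. Three forms are
#' fitted to the per-bear (HRHD, beta) pairs under Gaussian error and
#' ranked by AICc: a four-parameter logistic
#' `L0 + (L1 - L0) / (1 + exp(-s (x - x0)))`, a linear model, and an
#' intercept-only model. AICc counts the error variance as a parameter.
#'
#' @param rows data.frame with `bear_id`, `hrhd` (houses/km^2) and `beta`
#'   (standardized impervious coefficient); at least `min_bears` rows.
#' @param min_bears minimum bears required (default 8; with fewer bears the
#'   seasonal fits are not attempted).
#' @param n_starts multi-start perturbations for the logistic fit.
#' @param seed integer seed for the start perturbations.
#' @return object of class `hrhd_fit`: `models` (per-model parameters,
#'   logLik, AICc), `best` (model name), `data`.
#' @export
fit_coefficient_curves <- function(rows, min_bears = 8, n_starts = 5,
                                   seed = 1) {
  stopifnot(all(c("hrhd", "beta") %in% names(rows)))
  rows <- rows[is.finite(rows$hrhd) & is.finite(rows$beta), ]
  n <- nrow(rows)
  if (n < min_bears)
    stop("need at least ", min_bears, " bears with an impervious coefficient")
  set.seed(seed)
  x <- rows$hrhd; y <- rows$beta
  gauss_ll <- function(rss) -n / 2 * (log(2 * pi * rss / n) + 1)

  models <- list()
  ## intercept-only
  rss0 <- sum((y - mean(y))^2)
  models$intercept <- list(par = c(c = mean(y)), loglik = gauss_ll(rss0),
                           aicc = aicc(gauss_ll(rss0), 1 + 1, n))
  ## linear
  lf <- lm(y ~ x)
  rss1 <- sum(residuals(lf)^2)
  models$linear <- list(par = c(a = unname(coef(lf)[1]),
                                b = unname(coef(lf)[2])),
                        loglik = gauss_ll(rss1),
                        aicc = aicc(gauss_ll(rss1), 2 + 1, n))
  ## 4-parameter logistic, quantile-based multi-start
  best_nls <- NULL
  for (k in seq_len(n_starts)) {
    st <- list(L0 = quantile(y, 0.1, names = FALSE),
               L1 = quantile(y, 0.9, names = FALSE),
               x0 = quantile(x, runif(1, 0.3, 0.7), names = FALSE),
               s = exp(runif(1, log(0.02), log(0.3))))
    f <- try(suppressWarnings(minpack.lm::nlsLM(
      y ~ L0 + (L1 - L0) / (1 + exp(-s * (x - x0))),
      start = st, control = minpack.lm::nls.lm.control(maxiter = 200))),
      silent = TRUE)
    if (inherits(f, "try-error")) next
    rss <- sum(residuals(f)^2)
    if (is.null(best_nls) || rss < best_nls$rss)
      best_nls <- list(fit = f, rss = rss)
  }
  if (!is.null(best_nls)) {
    rss2 <- best_nls$rss
    models$logistic <- list(par = coef(best_nls$fit),
                            loglik = gauss_ll(rss2),
                            aicc = aicc(gauss_ll(rss2), 4 + 1, n))
  } else {
    warning("logistic fit failed to converge; excluded from ranking")
  }
  aiccs <- vapply(models, function(m) m$aicc, 0)
  structure(list(models = models, aicc = aiccs,
                 best = names(models)[which.min(aiccs)],
                 data = rows, n = n),
            class = "hrhd_fit")
}

#' @export
print.hrhd_fit <- function(x, ...) {
  cat("impervious-coefficient ~ home-range housing density (", x$n,
      "bears )\n")
  for (nm in names(x$models))
    cat(sprintf("  %-10s AICc %8.2f  %s\n", nm, x$models[[nm]]$aicc,
                paste(names(x$models[[nm]]$par),
                      round(x$models[[nm]]$par, 3),
                      sep = "=", collapse = " ")))
  cat("best model:", x$best, "\n")
  invisible(x)
}

#' @export
summary.hrhd_fit <- function(object, ...) print(object)

#' @export
coef.hrhd_fit <- function(object, model = object$best, ...)
  object$models[[model]]$par

#' @export
predict.hrhd_fit <- function(object, newdata = object$data,
                             model = object$best, ...) {
  x <- newdata$hrhd
  p <- object$models[[model]]$par
  switch(model,
         intercept = rep(p[["c"]], length(x)),
         linear = p[["a"]] + p[["b"]] * x,
         logistic = p[["L0"]] + (p[["L1"]] - p[["L0"]]) /
           (1 + exp(-p[["s"]] * (x - p[["x0"]]))))
}
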