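#' Conditional least squares estimates for PoINAR(1)
#'
#' `alpha` is the least-squares slope of `x_t` on `x_{t-1}` and `lambda`
#' the mean of `x_t - alpha * x_{t-1}` over `t = 2..n`. When used as a
#' sampler initialiser (`clip = TRUE`, the default) `alpha` is clipped to
#' `(0.001, 0.999)` and `lambda` floored at 0.001 so the Gibbs sampler
#' starts inside the parameter space.
#'
#' @param x count series, length >= 3, not constant (a `censored_series`
#'   is accepted and treated as fully observed).
#' @param clip clip estimates into the interior of the parameter space.
#' @return Named vector `c(alpha, lambda)`.
#' @export
cls_poinar <- function(x, clip = TRUE) {
  if (inherits(x, "censored_series")) x <- x$values
  x <- .check_counts(x, min_len = 3L, arg = "x")
  n <- length(x)
  x1 <- x[-n]; x2 <- x[-1L]
  sxx <- sum((x1 - mean(x1))^2)
  if (sxx == 0) stop("degenerate lagged variance: series is constant")
  ah <- sum((x1 - mean(x1)) * (x2 - mean(x2))) / sxx
  lh <- mean(x2 - ah * x1)
  if (clip) {
    ah <- min(max(ah, 0.001), 0.999)
    lh <- max(mean(x2 - ah * x1), 0.001)
  }
  c(alpha = ah, lambda = lh)
}

#' Conditional maximum likelihood estimates for PoINAR(1)
#'
#' Numerically maximises the conditional log-likelihood [cloglik()] of an
#' (assumed uncensored) PoINAR(1) model over `(alpha, lambda)`, on the
#' unconstrained scale `(logit(alpha), log(lambda))`, starting from the
#' conditional least squares estimates. Applied to a censored series this
#' is the censoring-blind fit: with appreciable censoring it overestimates
#' `alpha` and underestimates `lambda`.
#'
#' @param x count series, length >= 3 (a `censored_series` is accepted and
#'   treated as fully observed).
#' @param init optional numeric `c(alpha, lambda)` start; default CLS.
#' @return A list with `estimate` (named vector), `loglik` at the optimum,
#'   and the `optim` convergence code/counts.
#' @export
cml_poinar <- function(x, init = NULL) {
  if (inherits(x, "censored_series")) x <- x$values
  x <- .check_counts(x, min_len = 3L, arg = "x")
  start <- if (is.null(init)) cls_poinar(x) else
    c(alpha = min(max(init[1], 0.001), 0.999), lambda = max(init[2], 0.001))
  nll <- function(p)
    -poinar_cloglik_cpp(x, plogis(p[1]), exp(p[2]))
  opt <- optim(c(qlogis(start[1]), log(start[2])), nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  if (opt$convergence != 0)
    stop("conditional ML optimiser did not converge (code ",
         opt$convergence, ")")
  est <- c(alpha = unname(plogis(opt$par[1])), lambda = unname(exp(opt$par[2])))
  list(estimate = est, loglik = -opt$value,
       loglik_start = poinar_cloglik_cpp(x, start[1], start[2]),
       convergence = opt$convergence, counts = opt$counts)
}
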