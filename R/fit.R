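#' Fit a (censored) Poisson INAR(1) model
#'
#' Front end to the package's estimators for a count series observed under
#' a known detection limit. The model is the Poisson INAR(1)
#' \deqn{X_t = \alpha \circ X_{t-1} + e_t, \quad e_t \sim Po(\lambda),}
#' observed as `y_t = min(x_t, L)` (right censoring) or `max(x_t, L)`
#' (left). Methods:
#' \describe{
#'   \item{`"gda"`}{Gibbs sampler with data augmentation, imputing limit
#'     observations by the MMS rule ([gda_poinar()]) — the recommended
#'     censoring-aware estimator.}
#'   \item{`"abc"`}{rejection Approximate Bayesian Computation
#'     ([abc_poinar()]) — censoring-aware, likelihood-free.}
#'   \item{`"cml"`}{conditional maximum likelihood ignoring censoring
#'     ([cml_poinar()]) — baseline; biased under censoring.}
#'   \item{`"cls"`}{conditional least squares ignoring censoring
#'     ([cls_poinar()]) — baseline/initialiser.}
#'   \item{`"naive"`}{Gibbs sampler with the censored series treated as
#'     complete ([naive_gibbs_poinar()]) — baseline; biased under
#'     censoring.}
#' }
#'
#' @param y observed series: a `censored_series` from [censor()], or a
#'   plain non-negative integer vector (with `limit` for the
#'   censoring-aware methods; without a limit only the baselines apply).
#' @param limit known censoring limit `L` (integer), if `y` is a plain
#'   vector.
#' @param side `"right"` (default) or `"left"`.
#' @param method estimation method, see Details.
#' @param seed optional integer seed set before fitting (the Bayesian
#'   methods are stochastic).
#' @param ... passed on to the underlying estimator, e.g.
#'   `control = gda_control(...)` for `"gda"`/`"naive"`, or `n_draws`,
#'   `accept_q`, `lam_max` for `"abc"`.
#' @return An object of class `"censinar"` (with a method-specific
#'   subclass) supporting `print`, `summary`, `coef`, `plot`, `simulate`,
#'   `predict`, `residuals`, `fitted` and `logLik`.
#' @examples
#' set.seed(11)
#' x <- rccid(350, ccid_params("poisson", 0.5, 5))
#' y <- censor(x, 11)
#' fit <- censinar(y, method = "gda",
#'                 control = gda_control(n_iter = 1000, burn_in = 200,
#'                                       thin = 5))
#' coef(fit)
#' @export
censinar <- function(y, limit = NULL, side = "right",
                     method = c("gda", "abc", "cml", "cls", "naive"),
                     seed = NULL, ...) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  cl <- match.call()
  needs_limit <- method %in% c("gda", "abc", "naive")
  if (needs_limit) {
    y <- as_censored_series(y, limit, side)
  }
  fit <- switch(method,
    gda = gda_poinar(y, ...),
    abc = abc_poinar(y, ...),
    naive = naive_gibbs_poinar(y, ...),
    cml = {
      res <- cml_poinar(if (inherits(y, "censored_series")) y$values else y, ...)
      structure(list(coefficients = res$estimate, method = "cml",
                     loglik = res$loglik, optim = res[c("convergence", "counts")],
                     y = y,
                     n = if (inherits(y, "censored_series")) length(y$values)
                         else length(y),
                     limit = limit, side = side),
                class = c("censinar_cml", "censinar"))
    },
    cls = {
      est <- cls_poinar(if (inherits(y, "censored_series")) y$values else y, ...)
      structure(list(coefficients = est, method = "cls", y = y,
                     n = if (inherits(y, "censored_series")) length(y$values)
                         else length(y),
                     limit = limit, side = side),
                class = c("censinar_cls", "censinar"))
    })
  fit$call <- cl
  fit$seed <- seed
  fit
}

.obs_values <- function(object) {
  if (inherits(object$y, "censored_series")) object$y$values else object$y
}

#' @export
coef.censinar <- function(object, ...) object$coefficients

#' @export
print.censinar <- function(x, ...) {
  lab <- c(gda = "GDA-MMS (Gibbs with data augmentation)",
           abc = "rejection ABC",
           cml = "conditional maximum likelihood (censoring-blind)",
           cls = "conditional least squares (censoring-blind)",
           naive = "Gibbs sampler without imputation (censoring-blind)")
  cat("Censored PoINAR(1) fit --", lab[[x$method]], "\n")
  cat(sprintf("  n = %d%s\n", x$n,
              if (!is.null(x$limit) && !is.null(x$y) &&
                  inherits(x$y, "censored_series"))
                sprintf(", limit L = %d (%s), %.1f%% at L", x$limit, x$side,
                        100 * mean(x$y$censored)) else ""))
  cat("  estimates:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.censinar <- function(object, ...) {
  out <- list(method = object$method, coefficients = object$coefficients,
              n = object$n, limit = object$limit)
  if (!is.null(object$draws)) {
    d <- object$draws
    out$posterior <- t(apply(d, 2, function(v)
      c(mean = mean(v), sd = sd(v),
        quantile(v, c(0.025, 0.5, 0.975)))))
    if (object$method == "abc") {
      out$n_accept <- object$n_accept
      out$n_total <- object$n_total
    } else {
      out$kept <- nrow(d)
    }
  }
  if (!is.null(object$loglik)) out$loglik <- object$loglik
  class(out) <- "summary.censinar"
  out
}

#' @export
print.summary.censinar <- function(x, ...) {
  cat("Censored PoINAR(1) fit, method:", x$method, "\n")
  if (!is.null(x$posterior)) {
    cat("Posterior summary",
        if (!is.null(x$kept)) sprintf("(%d kept draws):", x$kept)
        else sprintf("(%d of %d draws accepted):", x$n_accept, x$n_total),
        "\n")
    print(round(x$posterior, 4))
  } else {
    print(round(x$coefficients, 4))
    if (!is.null(x$loglik))
      cat("conditional log-likelihood:", format(x$loglik), "\n")
  }
  invisible(x)
}

#' @export
logLik.censinar <- function(object, ...) {
  v <- .obs_values(object)
  ll <- poinar_cloglik_cpp(as.integer(v), object$coefficients[1],
                           object$coefficients[2])
  structure(ll, df = 2L, nobs = length(v) - 1L, class = "logLik")
}

#' @export
fitted.censinar <- function(object, ...) {
  v <- .obs_values(object)
  a <- object$coefficients[1]; l <- object$coefficients[2]
  c(NA_real_, a * v[-length(v)] + l)
}

#' @export
residuals.censinar <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  v <- .obs_values(object)
  a <- object$coefficients[1]; l <- object$coefficients[2]
  r <- v[-1L] - (a * v[-length(v)] + l)
  if (type == "pearson")
    r <- r / sqrt(a * (1 - a) * v[-length(v)] + l)
  c(NA_real_, r)
}

#' @export
predict.censinar <- function(object, h = 1, ...) {
  v <- .obs_values(object)
  a <- object$coefficients[1]; l <- object$coefficients[2]
  xn <- v[length(v)]
  hs <- seq_len(h)
  # h-step conditional mean of the latent process given X_n = xn; if the
  # last observation sits at the limit this conditions on the censored value
  unname(a^hs * xn + l * (1 - a^hs) / (1 - a))
}

#' @export
simulate.censinar <- function(object, nsim = 1, seed = NULL, n = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n)) n <- object$n
  p <- ccid_params("poisson", alpha = object$coefficients[1],
                   lam = object$coefficients[2])
  out <- replicate(nsim, {
    x <- rccid(n, p)
    if (!is.null(object$limit) && inherits(object$y, "censored_series"))
      censor(x, object$limit, object$side) else x
  }, simplify = FALSE)
  if (nsim == 1) out[[1]] else out
}

#' @export
plot.censinar <- function(x, ...) {
  if (!is.null(x$draws) && x$method != "abc") {
    op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
    on.exit(par(op))
    for (j in 1:2) {
      nm <- colnames(x$draws)[j]
      plot(x$kept_iterations, x$draws[, j], type = "l", xlab = "iteration",
           ylab = nm, main = paste("trace:", nm))
      hist(x$draws[, j], breaks = 30, main = paste("posterior:", nm),
           xlab = nm)
      abline(v = x$coefficients[j], col = 2, lwd = 2)
    }
  } else if (x$method == "abc") {
    op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    on.exit(par(op))
    for (j in 1:2) {
      nm <- colnames(x$accepted)[j]
      hist(x$accepted[, j], breaks = 30, main = paste("accepted:", nm),
           xlab = nm)
      abline(v = x$coefficients[j], col = 2, lwd = 2)
    }
  } else {
    v <- .obs_values(x)
    plot(v, type = "l", xlab = "t", ylab = "count",
         main = "observed series and one-step fitted mean")
    lines(fitted(x), col = 2)
    if (!is.null(x$limit)) abline(h = x$limit, lty = 2)
  }
  invisible(x)
}
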