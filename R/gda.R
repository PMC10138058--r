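#' Truncated Poisson sampler
#'
#' i.i.d. draws from `Poisson(mean)` conditioned on the value being at least
#' `lower` (inverse-CDF on the renormalised tail; `lower = 0` gives plain
#' Poisson draws). Errors when the tail mass below the truncation point is
#' numerically zero (below 1e-300), i.e. the limit is unreachable at this
#' mean.
#'
#' @param n number of draws.
#' @param mean Poisson mean, positive.
#' @param lower integer lower truncation point.
#' @return Integer vector of draws, all `>= lower`.
#' @export
rtpois <- function(n, mean, lower = 0) {
  if (!is.numeric(mean) || length(mean) != 1L || mean <= 0)
    stop("'mean' must be a single positive number")
  lower <- as.integer(lower)
  if (lower <= 0L) return(rpois(n, mean))
  tail <- ppois(lower - 1L, mean, lower.tail = FALSE)
  if (tail < 1e-300)
    stop("truncation point ", lower, " is unreachable at mean ", mean)
  q <- qpois(tail * (1 - runif(n)), mean, lower.tail = FALSE)
  as.integer(pmax(q, lower))
}

#' Impute a censored entry from multiple truncated draws
#'
#' The MMS (median of multiple simulations) rule: the integer ceiling of the
#' sample median of the draws. With an even number of draws a half-integer
#' median rounds up.
#'
#' @param w non-empty numeric vector of draws from the truncated marginal.
#' @return A single integer.
#' @examples
#' mms_impute(c(11, 12, 13))    # 12
#' mms_impute(c(11, 11, 12, 12)) # median 11.5 -> 12
#' @export
mms_impute <- function(w) {
  if (length(w) == 0L) stop("'w' must be non-empty")
  as.integer(ceiling(median(w)))
}

#' Log full conditional of the innovation mean lambda
#'
#' Up to an additive constant, the log posterior density of `lambda` given
#' `alpha` and the augmented series `z` under a Gamma(shape, rate) prior:
#' \deqn{-(d + (n-1))\lambda + (c-1)\log\lambda +
#'   \sum_{t=2}^n \log \sum_i C(t,i)\, \lambda^{z_t - i},}
#' with \eqn{C(t,i) = \binom{z_{t-1}}{i} \alpha^i (1-\alpha)^{z_{t-1}-i} /
#' (z_t - i)!}. Inner sums are evaluated by log-sum-exp.
#'
#' @param lam evaluation point, positive (vectorised).
#' @param alpha current thinning probability in (0, 1).
#' @param z augmented (complete) integer series.
#' @param shape,rate Gamma prior hyperparameters (defaults 0.1, 0.1).
#' @return Log density values up to a constant.
#' @export
log_fc_lambda <- function(lam, alpha, z, shape = 0.1, rate = 0.1) {
  z <- .check_counts(z, min_len = 2L, arg = "z")
  if (any(lam <= 0)) stop("'lam' must be positive")
  n <- length(z)
  zt <- z[-1L]; zp <- z[-n]
  vapply(lam, function(l) {
    ll <- 0
    for (t in seq_along(zt)) {
      i <- 0:min(zt[t], zp[t])
      lc <- -lgamma(zt[t] - i + 1) + lchoose(zp[t], i) +
        i * log(alpha) + (zp[t] - i) * log1p(-alpha)
      lt <- lse(lc + (zt[t] - i) * log(l))
      if (!is.finite(lt))
        stop("non-finite full-conditional term at t = ", t + 1L)
      ll <- ll + lt
    }
    -(rate + (n - 1)) * l + (shape - 1) * log(l) + ll
  }, numeric(1))
}

#' Log full conditional of the thinning probability alpha
#'
#' Up to an additive constant, the log posterior density of `alpha` given
#' `lambda` and the augmented series `z` under a Beta(a, b) prior:
#' \deqn{(a-1)\log\alpha + (b-1)\log(1-\alpha) +
#'   \sum_{t=2}^n \log \sum_i K(t,i)\, \alpha^i (1-\alpha)^{z_{t-1}-i},}
#' with \eqn{K(t,i) = \lambda^{z_t-i} \binom{z_{t-1}}{i} / (z_t - i)!}.
#'
#' @param alpha evaluation point in (0, 1) (vectorised).
#' @param lam current innovation mean, positive.
#' @param z augmented (complete) integer series.
#' @param a,b Beta prior hyperparameters (defaults 2, 2).
#' @return Log density values up to a constant.
#' @export
log_fc_alpha <- function(alpha, lam, z, a = 2, b = 2) {
  z <- .check_counts(z, min_len = 2L, arg = "z")
  if (any(alpha <= 0 | alpha >= 1)) stop("'alpha' must lie in (0, 1)")
  n <- length(z)
  zt <- z[-1L]; zp <- z[-n]
  vapply(alpha, function(al) {
    ll <- 0
    for (t in seq_along(zt)) {
      i <- 0:min(zt[t], zp[t])
      lk <- (zt[t] - i) * log(lam) - lgamma(zt[t] - i + 1) + lchoose(zp[t], i)
      lt <- lse(lk + i * log(al) + (zp[t] - i) * log1p(-al))
      if (!is.finite(lt))
        stop("non-finite full-conditional term at t = ", t + 1L)
      ll <- ll + lt
    }
    (a - 1) * log(al) + (b - 1) * log1p(-al) + ll
  }, numeric(1))
}

#' Univariate slice sampler on a bounded interval
#'
#' Draws from a univariate density known up to a constant through its log
#' density, by the shrinkage slice sampler: a slice level is drawn under the
#' current point, then uniform proposals on the support interval are
#' shrunk towards the current point until one lands inside the slice. The
#' stationary distribution is exactly the normalised density. Successive
#' draws form a Markov chain (they are not independent).
#'
#' @param logf function returning the log density (finite on the interior
#'   of the support).
#' @param lower,upper support interval.
#' @param n number of (sequential) draws.
#' @param init starting point; defaults to the interval midpoint.
#' @return Numeric vector of `n` draws.
#' @examples
#' set.seed(1)
#' x <- slice_sample_uni(function(u) dbeta(u, 2, 2, log = TRUE), 0, 1, 500)
#' mean(x)  # ~ 0.5
#' @export
slice_sample_uni <- function(logf, lower, upper, n = 1, init = NULL) {
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
    stop("'lower' and 'upper' must be finite with lower < upper")
  x0 <- if (is.null(init)) (lower + upper) / 2 else init
  g0 <- logf(x0)
  if (!is.finite(g0)) {
    grid <- seq(lower, upper, length.out = 101)[-c(1, 101)]
    gv <- vapply(grid, logf, numeric(1))
    if (all(!is.finite(gv))) stop("log density is -Inf on the whole support")
    x0 <- grid[which.max(gv)]
    g0 <- logf(x0)
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    y <- g0 - rexp(1)
    L <- lower; R <- upper
    repeat {
      x1 <- runif(1, L, R)
      g1 <- logf(x1)
      if (is.finite(g1) && g1 >= y) break
      if (x1 < x0) L <- x1 else R <- x1
      if (R - L < 1e-14) { x1 <- x0; g1 <- g0; break }
    }
    x0 <- x1; g0 <- g1
    out[i] <- x1
  }
  out
}

#' Settings for the Gibbs sampler with data augmentation
#'
#' @param n_iter total Gibbs iterations (default 15000).
#' @param burn_in iterations discarded (default 5000, must be < `n_iter`).
#' @param thin keep every `thin`-th post-burn-in iteration (default 30).
#' @param m truncated-marginal draws per imputed entry (default 10).
#' @param a,b Beta prior hyperparameters for `alpha` (default 2, 2).
#' @param shape,rate Gamma prior hyperparameters for `lambda`
#'   (default 0.1, 0.1).
#' @param eps numerical margin keeping `alpha` in `(eps, 1-eps)` and
#'   `lambda` above `eps` (default 1e-9).
#' @param lam_max upper bound of the `lambda` slice support; `NULL` (the
#'   default) adapts it to 10 times the initial estimate, at least 10.
#' @return A validated list of class `"gda_control"`.
#' @export
gda_control <- function(n_iter = 15000, burn_in = 5000, thin = 30, m = 10,
                        a = 2, b = 2, shape = 0.1, rate = 0.1,
                        eps = 1e-9, lam_max = NULL) {
  ctl <- list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
              thin = as.integer(thin), m = as.integer(m),
              a = a, b = b, shape = shape, rate = rate,
              eps = eps, lam_max = lam_max)
  if (ctl$burn_in >= ctl$n_iter) stop("'burn_in' must be < 'n_iter'")
  if (ctl$thin < 1L) stop("'thin' must be >= 1")
  if (ctl$m < 1L) stop("'m' must be >= 1")
  if (any(c(a, b, shape, rate) <= 0)) stop("prior hyperparameters must be positive")
  class(ctl) <- "gda_control"
  ctl
}

# shared chain driver for gda_poinar / naive_gibbs_poinar (internal)
.run_gibbs <- function(y, init, control, engine, impute, method) {
  stopifnot(inherits(control, "gda_control"))
  n <- length(y$values)
  if (is.character(init) && identical(init, "cls")) {
    init <- cls_poinar(y$values)
  } else {
    init <- c(alpha = as.numeric(init[1]), lambda = as.numeric(init[2]))
  }
  a0 <- min(max(init[1], 0.001), 0.999)
  l0 <- max(init[2], 0.001)
  lam_max <- if (is.null(control$lam_max)) max(10, 10 * l0) else control$lam_max
  cens <- if (impute) y$censored else rep(FALSE, n)
  kept_idx <- seq.int(control$burn_in + control$thin, control$n_iter,
                      by = control$thin)
  if (length(kept_idx) < 10L)
    stop("chain settings keep fewer than 10 draws; increase n_iter or ",
         "decrease thin")

  if (engine == "cpp") {
    res <- gda_chain_cpp(y$values, cens, y$limit, y$side == "left",
                         a0, l0, control$a, control$b, control$shape,
                         control$rate, control$n_iter, control$m,
                         control$eps, lam_max)
    draws <- res$draws
    z <- res$z
  } else {
    z <- y$values
    draws <- matrix(NA_real_, control$n_iter, 2L)
    alpha <- a0; lam <- l0
    for (k in seq_len(control$n_iter)) {
      lam <- slice_sample_uni(function(l)
        log_fc_lambda(l, alpha, z, control$shape, control$rate),
        control$eps, lam_max, init = lam)
      alpha <- slice_sample_uni(function(al)
        log_fc_alpha(al, lam, z, control$a, control$b),
        control$eps, 1 - control$eps, init = alpha)
      if (any(cens)) {
        mu <- lam / (1 - alpha)
        for (t in which(cens)) {
          w <- if (y$side == "left") {
            mass <- ppois(y$limit, mu)
            pmin(qpois(runif(control$m) * mass, mu), y$limit)
          } else rtpois(control$m, mu, y$limit)
          z[t] <- mms_impute(w)
        }
      }
      draws[k, ] <- c(alpha, lam)
    }
  }
  kept <- draws[kept_idx, , drop = FALSE]
  colnames(kept) <- c("alpha", "lambda")
  est <- colMeans(kept)
  structure(list(coefficients = est,
                 method = method,
                 draws = kept,
                 kept_iterations = kept_idx,
                 init = c(alpha = unname(a0), lambda = unname(l0)),
                 control = control,
                 augmented = list(values = as.integer(z),
                                  source = ifelse(cens, "imputed", "observed")),
                 y = y, n = n, limit = y$limit, side = y$side),
            class = c(paste0("censinar_", method), "censinar"))
}

#' Gibbs sampler with data augmentation (GDA-MMS) for censored PoINAR(1)
#'
#' Bayesian estimation of `(alpha, lambda)` from a series censored at a
#' known limit. Each sweep samples `lambda` from its full conditional
#' ([log_fc_lambda()]), then `alpha` ([log_fc_alpha()]), both by a
#' slice sampler, and then rebuilds the augmented series: observed entries
#' are copied, entries at the limit are replaced by the ceiling of the
#' median of `m` draws from the `Poisson(lambda/(1-alpha))` marginal
#' truncated at the limit, using the current iteration's parameters. After
#' burn-in and thinning, point estimates are the posterior means of the
#' kept draws.
#'
#' @param y observed censored series (a `censored_series`, or plain vector
#'   with `limit`).
#' @param limit censoring limit if `y` is a plain vector.
#' @param side `"right"` (default) or `"left"`.
#' @param init `"cls"` (default) initialises at the conditional least
#'   squares estimates of the censored series; or a numeric
#'   `c(alpha, lambda)`.
#' @param control a [gda_control()] list.
#' @param engine `"cpp"` (compiled sweep, default) or `"r"` (reference
#'   implementation built from the exported pieces; identical model, much
#'   slower).
#' @return An object of class `c("censinar_gda", "censinar")` with the kept
#'   draws, posterior-mean `coefficients`, the final augmented series, and
#'   the settings.
#' @examples
#' set.seed(7)
#' y <- censor(rccid(200, ccid_params("poisson", 0.5, 5)), 11)
#' fit <- gda_poinar(y, control = gda_control(n_iter = 600, burn_in = 100,
#'                                            thin = 5))
#' coef(fit)
#' @export
gda_poinar <- function(y, limit = NULL, side = "right", init = "cls",
                       control = gda_control(), engine = c("cpp", "r")) {
  y <- as_censored_series(y, limit, side)
  engine <- match.arg(engine)
  .run_gibbs(y, init, control, engine, impute = TRUE, method = "gda")
}

#' Censoring-blind Gibbs sampler (no imputation)
#'
#' The same parameter sweeps as [gda_poinar()] but with the augmented series
#' fixed to the observed censored values: the Bayesian fit one would obtain
#' by ignoring censoring altogether. On uncensored input it is
#' distributionally identical to [gda_poinar()]. Used as a baseline to
#' quantify censoring bias.
#'
#' @inheritParams gda_poinar
#' @return An object of class `c("censinar_naive", "censinar")`.
#' @export
naive_gibbs_poinar <- function(y, limit = NULL, side = "right", init = "cls",
                               control = gda_control(),
                               engine = c("cpp", "r")) {
  y <- as_censored_series(y, limit, side)
  engine <- match.arg(engine)
  .run_gibbs(y, init, control, engine, impute = FALSE, method = "naive")
}
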