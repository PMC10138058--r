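#' Empirical probability mass function
#'
#' Sample proportions over the observed support of a count series.
#'
#' @param x count series (or `censored_series`).
#' @return Named numeric vector of proportions (names are the support
#'   values), summing to 1.
#' @export
empirical_pmf <- function(x) {
  if (inherits(x, "censored_series")) x <- x$values
  x <- .check_counts(x, arg = "x")
  tab <- table(x)
  p <- as.numeric(tab) / length(x)
  names(p) <- names(tab)
  p
}

#' Kullback-Leibler divergence between two empirical pmfs
#'
#' \eqn{d_{KL}(\hat p^0, \hat p) = \sum_j \hat p^0_j
#' \ln(\hat p^0_j / \hat p_j)} over the union support. Terms with
#' \eqn{\hat p^0_j = 0} contribute zero (the limit of `p log p`); a support
#' value with \eqn{\hat p^0_j > 0} but \eqn{\hat p_j = 0} makes the
#' divergence `+Inf`.
#'
#' @param p0 reference (observed) pmf, a named vector as returned by
#'   [empirical_pmf()].
#' @param p comparison (simulated) pmf, same format.
#' @return Non-negative number, possibly `Inf`.
#' @export
kl_div <- function(p0, p) {
  for (nm in c("p0", "p")) {
    v <- get(nm)
    if (is.null(names(v)) || abs(sum(v) - 1) > 1e-6 || any(v < 0))
      stop("'", nm, "' must be a named, normalised pmf")
  }
  sup <- names(p0)[p0 > 0]
  q <- p[sup]
  q[is.na(q)] <- 0
  w <- p0[sup]
  if (any(q == 0)) return(Inf)
  sum(w * (log(w) - log(q)))
}

#' Lag-1 sample autocorrelation
#'
#' Autocovariance at lag 1 divided by the sample variance, both with
#' denominator `n` (the standard correlogram estimate).
#'
#' @param x numeric series, length >= 2, not constant.
#' @return A number in \[-1, 1\].
#' @export
acf1 <- function(x) {
  if (inherits(x, "censored_series")) x <- x$values
  if (!is.numeric(x) || length(x) < 2L) stop("'x' must have length >= 2")
  n <- length(x)
  xb <- mean(x)
  c0 <- sum((x - xb)^2) / n
  if (c0 == 0) stop("lag-1 autocorrelation undefined for a constant series")
  c1 <- sum((x[-1L] - xb) * (x[-n] - xb)) / n
  c1 / c0
}

# Streaming block simulation of censored PoINAR(1) replicates. Simulates K
# paths of length n in lock-step (vectorised over replicates), censors each
# step, and accumulates only what the summary statistics need: per-replicate
# counts at the observed support values, running sums for the lag-1
# autocorrelation, and the count at the limit. Returns S1, S2, S3.
.abc_block_stats <- function(K, n, alpha, lam, limit, side,
                             sup, lp0, p0v, s3_needed = TRUE) {
  maxsup <- max(sup)
  lookup <- rep(NA_integer_, maxsup + 2L)
  lookup[sup + 1L] <- seq_along(sup)
  mu <- lam / (1 - alpha)
  x <- rpois(K, mu)
  ycur <- if (side == "right") pmin(x, limit) else pmax(x, limit)
  counts <- matrix(0L, K, length(sup))
  nL <- as.integer(ycur == limit)
  idx <- lookup[pmin(ycur, maxsup + 1L) + 1L]
  selv <- which(!is.na(idx))
  counts[cbind(selv, idx[selv])] <- 1L
  S <- as.numeric(ycur); SS <- as.numeric(ycur)^2
  Cc <- numeric(K); y1 <- ycur; yprev <- ycur
  for (t in 2:n) {
    x <- rbinom(K, x, alpha) + rpois(K, lam)
    ycur <- if (side == "right") pmin(x, limit) else pmax(x, limit)
    S <- S + ycur; SS <- SS + as.numeric(ycur)^2
    Cc <- Cc + as.numeric(yprev) * ycur
    nL <- nL + (ycur == limit)
    idx <- lookup[pmin(ycur, maxsup + 1L) + 1L]
    selv <- which(!is.na(idx))
    ii <- cbind(selv, idx[selv])
    counts[ii] <- counts[ii] + 1L
    yprev <- ycur
  }
  ybar <- S / n
  c0 <- SS / n - ybar^2
  c1 <- (Cc - ybar * (S - y1) - ybar * (S - yprev) + (n - 1) * ybar^2) / n
  S2 <- ifelse(c0 > 0, c1 / c0, NA_real_)
  # KL divergence of observed vs simulated pmf, restricted to the observed
  # support (zero-probability observed values contribute nothing)
  P <- counts / n
  bad <- rowSums(P == 0) > 0L
  S1 <- rep(Inf, K)
  if (any(!bad)) {
    klconst <- sum(p0v * lp0)
    S1[!bad] <- klconst - as.vector(log(P[!bad, , drop = FALSE]) %*% p0v)
  }
  list(S1 = S1, S2 = S2, S3 = nL / n)
}

#' Rejection ABC for the censored Poisson INAR(1) model
#'
#' Likelihood-free posterior sampling: draws `(alpha, lambda)` from the
#' priors `alpha ~ U(0, 1)` and `lambda ~ U(0, lam_max)`, simulates a
#' censored PoINAR(1) path of the observed length for each draw, and
#' summarises every path by three statistics: `S1`, the Kullback-Leibler
#' divergence of the observed from the simulated empirical pmf; `S2`, the
#' lag-1 sample autocorrelation; `S3`, the fraction of entries at the limit.
#' After all draws the composite distance
#' \deqn{d_S = S_1^2/V(S_1) + \sum_{i=2,3} (S_i(y^0)-S_i(y))^2 /
#'   V(S_i(y^0)-S_i(y))}
#' is formed, with `V` the sample variances across the replications
#' (a two-pass scheme: the scalings are only available once every replicate
#' has been simulated; infinite `S1` values are excluded from the variance
#' of `S1` and such draws are rejected outright). The draws in the lowest
#' `accept_q` quantile of the distance are accepted (ties broken by draw
#' index) and the point estimate is their mean.
#'
#' @param y observed censored series (a `censored_series`, or a plain
#'   vector together with `limit`).
#' @param limit censoring limit, required if `y` is a plain vector.
#' @param side `"right"` (default) or `"left"`.
#' @param n_draws number of prior draws (1e6 in the full-scale study;
#'   smaller values give a coarser posterior approximation).
#' @param accept_q acceptance quantile in (0, 1); the default 0.001 keeps
#'   the 0.1\% closest draws.
#' @param lam_max upper bound of the uniform prior on `lambda` (default 10,
#'   suited to small counts; widen for larger-mean data).
#' @param block_size replicates simulated per vectorised block.
#' @return An object of class `c("censinar_abc", "censinar")` with the
#'   accepted draws, their distances, the point estimate (mean of accepted
#'   draws), the summary-statistic variances, and the settings used.
#' @examples
#' set.seed(42)
#' y <- censor(rccid(300, ccid_params("poisson", 0.5, 5)), 11)
#' fit <- abc_poinar(y, n_draws = 2000, accept_q = 0.01)
#' coef(fit)
#' @export
abc_poinar <- function(y, limit = NULL, side = "right",
                       n_draws = 1e5, accept_q = 0.001, lam_max = 10,
                       block_size = 2e4) {
  y <- as_censored_series(y, limit, side)
  if (!is.numeric(accept_q) || accept_q <= 0 || accept_q >= 1)
    stop("'accept_q' must lie in (0, 1)")
  n_draws <- as.integer(n_draws)
  n <- length(y$values)
  p0 <- empirical_pmf(y$values)
  sup <- as.integer(names(p0))
  s2_obs <- acf1(y$values)
  s3_obs <- mean(y$censored)

  alpha <- runif(n_draws)
  lam <- runif(n_draws, 0, lam_max)
  S1 <- S2 <- S3 <- numeric(n_draws)
  done <- 0L
  while (done < n_draws) {
    K <- min(as.integer(block_size), n_draws - done)
    ii <- done + seq_len(K)
    st <- .abc_block_stats(K, n, alpha[ii], lam[ii], y$limit, y$side,
                           sup, log(p0), p0)
    S1[ii] <- st$S1; S2[ii] <- st$S2; S3[ii] <- st$S3
    done <- done + K
  }

  v1 <- var(S1[is.finite(S1)])
  d2 <- s2_obs - S2
  d3 <- s3_obs - S3
  v2 <- var(d2, na.rm = TRUE)
  v3 <- var(d3)
  vs <- c(S1 = v1, S2 = v2, S3 = v3)
  deg <- !is.finite(vs) | vs == 0
  if (any(deg))
    stop("degenerate summary statistic (zero variance across replications): ",
         paste(names(vs)[deg], collapse = ", "))
  dS <- S1^2 / v1 + d2^2 / v2 + d3^2 / v3
  dS[is.na(dS)] <- Inf
  if (all(!is.finite(dS)))
    stop("no acceptance: all composite distances are infinite")
  n_acc <- as.integer(ceiling(accept_q * n_draws))
  ord <- order(dS, seq_along(dS))[seq_len(n_acc)]
  accepted <- cbind(alpha = alpha[ord], lambda = lam[ord])
  est <- colMeans(accepted)
  structure(list(coefficients = est,
                 method = "abc",
                 accepted = accepted,
                 draws = accepted,
                 distances = dS[ord],
                 min_rejected_distance = if (n_acc < n_draws)
                   min(dS[-ord]) else Inf,
                 n_total = n_draws,
                 quantile = accept_q,
                 n_accept = n_acc,
                 n_finite = sum(is.finite(dS)),
                 variances = vs,
                 stats_obs = c(S2 = s2_obs, S3 = s3_obs),
                 prior = c(alpha_max = 1, lam_max = lam_max),
                 y = y, n = n, limit = y$limit, side = y$side),
            class = c("censinar_abc", "censinar"))
}
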