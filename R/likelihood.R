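# log-sum-exp (internal)
lse <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

#' One-step transition probability of a CCID(1) process
#'
#' Evaluates \eqn{P(X_t = k \mid X_{t-1} = l) =
#' \sum_{j=0}^{\min(k,l)} g(j|l)\, P(e_t = k - j)}, the convolution of the
#' thinning pmf and the innovation pmf. With `l = 0` there are no survivors
#' to thin and the transition reduces to the innovation pmf.
#'
#' @param k target counts (vectorised, non-negative integers).
#' @param l previous count (single non-negative integer).
#' @param params a [ccid_params()] object.
#' @return Probabilities of the same length as `k`.
#' @examples
#' p <- ccid_params("poisson", 0.5, 5)
#' sum(trans_pmf(0:100, 3, p))  # rows sum to 1
#' @export
trans_pmf <- function(k, l, params) {
  stopifnot(inherits(params, "ccid_params"))
  k <- .check_counts(k, arg = "k")
  l <- .check_counts(l, arg = "l")
  if (length(l) != 1L) stop("'l' must be a single count")
  if (l == 0L) return(innov_pmf(k, params))
  g <- thin_pmf(0:l, l, params)
  vapply(k, function(ki) {
    j <- 0:min(ki, l)
    sum(g[j + 1L] * innov_pmf(ki - j, params))
  }, numeric(1))
}

#' Conditional log-likelihood of a CCID(1) path
#'
#' Log-likelihood conditional on the first observation,
#' \eqn{\sum_{t=2}^n \log f(x_t \mid x_{t-1})}; the marginal of `x_1` does
#' not enter. Each transition term is evaluated in the log domain. The
#' Poisson family uses a compiled kernel; other families go through
#' [thin_pmf()]/[innov_pmf()] with log-sum-exp.
#'
#' @param x integer series of length >= 2.
#' @param params a [ccid_params()] object.
#' @return A single finite number (or an error naming the offending time
#'   point if a transition probability underflows to zero).
#' @export
cloglik <- function(x, params) {
  stopifnot(inherits(params, "ccid_params"))
  x <- .check_counts(x, min_len = 2L, arg = "x")
  if (params$family == "poisson")
    return(poinar_cloglik_cpp(x, params$alpha, params$lam))
  n <- length(x)
  ll <- 0
  for (t in 2:n) {
    k <- x[t]; l <- x[t - 1L]
    j <- 0:min(k, l)
    lt <- lse(log(thin_pmf(j, l, params)) + log(innov_pmf(k - j, params)))
    if (!is.finite(lt))
      stop("non-finite transition log-probability at t = ", t)
    ll <- ll + lt
  }
  ll
}
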