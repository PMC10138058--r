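#' Parameters of a CCID(1) count model
#'
#' Bundles and validates the parameters of a first-order convolution-closed
#' infinitely-divisible (CCID(1)) count process
#' \deqn{X_t = R_t(X_{t-1}) + e_t,}
#' where `R_t` is a random thinning operator with survival probability
#' `alpha` and the innovations `e_t` are i.i.d. with mean `lam`. The three
#' supported families pair a marginal distribution with its thinning
#' operator: Poisson marginal with binomial thinning (PoINAR(1)), negative
#' binomial marginal, and generalised Poisson marginal with quasi-binomial
#' thinning. The stationary marginal mean is the derived quantity
#' `mu = lam / (1 - alpha)`; `lam` is the canonical parameter throughout.
#'
#' For `family = "negbin"` the thinning probability mass function used is the
#' binomial one (as for the Poisson family). The table this family is taken
#' from labels the operator "beta binomial thinning" while printing the
#' binomial pmf; the printed formula is exposed as is, and the negative
#' binomial family is supported for simulation and transition probabilities
#' only, not estimation. Innovations are parameterised by their mean:
#' `NB(lam, xi)` has mean `lam` and size `xi`
#' (variance `lam + lam^2/xi`); `GP(lam, xi)` is the generalised Poisson
#' with mean `lam` and dispersion `0 <= xi < 1`
#' (pmf \eqn{\theta(\theta+\xi x)^{x-1} e^{-\theta-\xi x}/x!} with
#' \eqn{\theta = \lambda(1-\xi)}).
#'
#' @param family one of `"poisson"`, `"negbin"`, `"genpoisson"`.
#' @param alpha thinning survival probability, in (0, 1).
#' @param lam innovation mean, positive.
#' @param xi dispersion parameter; required (non-negative) for the negative
#'   binomial and generalised Poisson families, ignored for Poisson.
#' @return An object of class `"ccid_params"`: a list with elements
#'   `family`, `alpha`, `lam`, `xi` and the derived marginal mean `mu`.
#' @examples
#' p <- ccid_params("poisson", alpha = 0.5, lam = 5)
#' p$mu  # marginal mean 10
#' @export
ccid_params <- function(family = c("poisson", "negbin", "genpoisson"),
                        alpha, lam, xi = NULL) {
  family <- match.arg(family)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single number in (0, 1)")
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0)
    stop("'lam' must be a single positive number")
  if (family != "poisson") {
    if (is.null(xi) || !is.numeric(xi) || length(xi) != 1L ||
        !is.finite(xi) || xi < 0)
      stop("'xi' must be a single non-negative number for family '",
           family, "'")
    if (family == "genpoisson" && xi >= 1)
      stop("'xi' must be < 1 for the generalised Poisson family")
    if (family == "negbin" && xi == 0)
      stop("'xi' must be positive for the negative binomial family")
  } else {
    xi <- NULL
  }
  structure(list(family = family, alpha = alpha, lam = lam, xi = xi,
                 mu = lam / (1 - alpha)),
            class = "ccid_params")
}

#' @export
print.ccid_params <- function(x, ...) {
  cat("CCID(1) parameters [", x$family, "]\n", sep = "")
  cat("  alpha =", format(x$alpha), " lam =", format(x$lam),
      if (!is.null(x$xi)) paste(" xi =", format(x$xi)), "\n")
  cat("  marginal mean mu = lam/(1-alpha) =", format(x$mu), "\n")
  invisible(x)
}

.check_counts <- function(x, min_len = 1L, arg = "x") {
  if (!is.numeric(x) || length(x) < min_len)
    stop("'", arg, "' must be a numeric vector of length >= ", min_len)
  if (anyNA(x) || any(x < 0) || any(x != floor(x)))
    stop("'", arg, "' must contain non-negative integers")
  as.integer(x)
}

#' Innovation probability mass function
#'
#' pmf of the innovation distribution `e_t` of a CCID(1) model: Poisson(lam),
#' NB(mean lam, size xi) or generalised Poisson(mean lam, dispersion xi).
#'
#' @param k non-negative integer values (vectorised).
#' @param params a [ccid_params()] object.
#' @return Probabilities of the same length as `k`.
#' @export
innov_pmf <- function(k, params) {
  stopifnot(inherits(params, "ccid_params"))
  k <- .check_counts(k, arg = "k")
  switch(params$family,
         poisson = dpois(k, params$lam),
         negbin = dnbinom(k, mu = params$lam, size = params$xi),
         genpoisson = {
           th <- params$lam * (1 - params$xi)
           lp <- log(th) + (k - 1) * log(th + params$xi * k) -
             th - params$xi * k - lgamma(k + 1)
           exp(lp)
         })
}

#' Thinning probability mass function g(s | x)
#'
#' Conditional pmf of the thinning operator `R(X)` given `X = x`: binomial
#' for the Poisson (and, as printed in the source family table, negative
#' binomial) families, quasi-binomial
#' \eqn{\binom{x}{s}\alpha(\alpha+s\theta)^{s-1}(1-\alpha-s\theta)^{x-s}},
#' \eqn{\theta = \xi/\mu}, for the generalised Poisson family.
#'
#' @param s number of survivors, vectorised over `0..x`.
#' @param x previous count (single non-negative integer).
#' @param params a [ccid_params()] object.
#' @return Probabilities of the same length as `s`.
#' @export
thin_pmf <- function(s, x, params) {
  stopifnot(inherits(params, "ccid_params"))
  x <- .check_counts(x, arg = "x")
  if (length(x) != 1L) stop("'x' must be a single count")
  s <- .check_counts(s, arg = "s")
  if (any(s > x)) stop("'s' cannot exceed 'x'")
  if (params$family != "genpoisson")
    return(dbinom(s, x, params$alpha))
  th <- params$xi / params$mu
  bad <- 1 - params$alpha - (0:x) * th < 0
  if (any(bad))
    stop("quasi-binomial support violated: 1 - alpha - s*xi/mu < 0 at s = ",
         which(bad)[1] - 1L)
  a <- params$alpha
  p <- exp(lchoose(x, s) + log(a) + (s - 1) * log(a + s * th)) *
    (1 - a - s * th)^(x - s)
  p[s == 0] <- (1 - a)^x  # a * a^(-1) cancels at s = 0
  p
}

#' Sample the thinning operator
#'
#' Draws `n` replicates of `R(x_prev)`, the number of survivors of `x_prev`
#' under the family's thinning operator: `Binomial(x_prev, alpha)` for the
#' Poisson family, quasi-binomial (sampled by enumeration of its pmf) for
#' the generalised Poisson family. `x_prev = 0` always yields 0 (empty sum).
#'
#' @param n number of draws.
#' @param x_prev previous count (single non-negative integer).
#' @param params a [ccid_params()] object.
#' @return Integer vector of length `n`, each entry in `0..x_prev`.
#' @export
rthin <- function(n, x_prev, params) {
  stopifnot(inherits(params, "ccid_params"))
  x_prev <- .check_counts(x_prev, arg = "x_prev")
  if (length(x_prev) != 1L) stop("'x_prev' must be a single count")
  if (x_prev == 0L) return(integer(n) )
  if (params$family != "genpoisson")
    return(rbinom(n, x_prev, params$alpha))
  pr <- thin_pmf(0:x_prev, x_prev, params)
  sample.int(x_prev + 1L, n, replace = TRUE, prob = pr) - 1L
}

# innovation sampler (internal)
rinnov <- function(n, params) {
  switch(params$family,
         poisson = rpois(n, params$lam),
         negbin = rnbinom(n, mu = params$lam, size = params$xi),
         genpoisson = {
           # inversion from the pmf table, truncated when the tail mass
           # drops below 1e-12
           kmax <- 10L
           repeat {
             p <- innov_pmf(0:kmax, params)
             if (sum(p) > 1 - 1e-12 || kmax > 1e6) break
             kmax <- kmax * 2L
           }
           sample.int(kmax + 1L, n, replace = TRUE, prob = p) - 1L
         })
}

#' Simulate a CCID(1) path
#'
#' Generates a stationary path of `X_t = R_t(X_{t-1}) + e_t`. For the
#' Poisson family `X_1` is drawn exactly from the stationary marginal
#' `Po(lam/(1-alpha))`, so no burn-in is needed; for the negative binomial
#' and generalised Poisson families the chain is started at the rounded
#' marginal mean and a burn-in (default 500) is discarded.
#'
#' @param n series length, at least 2.
#' @param params a [ccid_params()] object.
#' @param burn_in iterations discarded before recording; defaults to 0 for
#'   the Poisson family and 500 otherwise.
#' @return Integer vector of length `n`.
#' @examples
#' set.seed(1)
#' x <- rccid(500, ccid_params("poisson", 0.5, 5))
#' mean(x)  # close to mu = 10
#' @export
rccid <- function(n, params, burn_in = NULL) {
  stopifnot(inherits(params, "ccid_params"))
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != floor(n))
    stop("'n' must be a single integer >= 2")
  n <- as.integer(n)
  if (is.null(burn_in))
    burn_in <- if (params$family == "poisson") 0L else 500L
  burn_in <- as.integer(burn_in)
  x0 <- if (params$family == "poisson") rpois(1L, params$mu)
        else as.integer(round(params$mu))
  for (i in seq_len(burn_in))
    x0 <- rthin(1L, x0, params) + rinnov(1L, params)
  x <- integer(n)
  x[1L] <- x0
  for (t in 2:n)
    x[t] <- rthin(1L, x[t - 1L], params) + rinnov(1L, params)
  x
}
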