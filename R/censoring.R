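#' Apply exogenous (type-1) censoring at a known limit
#'
#' Right censoring observes `y_t = min(x_t, L)`; left censoring (the mirror
#' case) observes `y_t = max(x_t, L)`. Entries exactly equal to the limit
#' are flagged as censored: a true value of exactly `L` is indistinguishable
#' from a censored one, and all downstream algorithms treat it as censored
#' (the truncated imputation distribution has support `[L, Inf)`, which
#' includes `L` itself).
#'
#' @param x integer series (non-negative counts) or a `censored_series`
#'   (re-censoring at the same limit is the identity).
#' @param limit known integer censoring limit `L >= 0`.
#' @param side `"right"` (default) or `"left"`.
#' @return An object of class `"censored_series"`: a list with `values`
#'   (the censored counts), `limit`, `side`, and logical `censored` marking
#'   entries at the limit.
#' @examples
#' censor(c(3, 7, 12, 11), limit = 11)
#' @export
censor <- function(x, limit, side = c("right", "left")) {
  side <- match.arg(side)
  if (inherits(x, "censored_series")) x <- x$values
  x <- .check_counts(x, min_len = 1L, arg = "x")
  if (!is.numeric(limit) || length(limit) != 1L || limit < 0 ||
      limit != floor(limit))
    stop("'limit' must be a single non-negative integer")
  limit <- as.integer(limit)
  y <- if (side == "right") pmin(x, limit) else pmax(x, limit)
  structure(list(values = y, limit = limit, side = side,
                 censored = y == limit),
            class = "censored_series")
}

# coerce a plain vector + limit into a censored_series, validating the
# side constraint (internal)
as_censored_series <- function(y, limit = NULL, side = "right") {
  if (inherits(y, "censored_series")) return(y)
  if (is.null(limit))
    stop("'limit' must be supplied when 'y' is a plain vector")
  y <- .check_counts(y, arg = "y")
  if (side == "right" && any(y > limit))
    stop("right-censored series cannot exceed the limit")
  if (side == "left" && any(y < limit))
    stop("left-censored series cannot fall below the limit")
  censor(y, limit, side)
}

#' @export
print.censored_series <- function(x, ...) {
  cat(sprintf("%s-censored count series: n = %d, limit L = %d, %.1f%% at L\n",
              x$side, length(x$values), x$limit,
              100 * mean(x$censored)))
  print(x$values)
  invisible(x)
}

#' @export
length.censored_series <- function(x) length(x$values)

#' Fraction of observations at the censoring limit
#'
#' The summary statistic `mean(I(y_t = L))`, i.e. the proportion of entries
#' flagged as (potentially) censored. Note that because true values exactly
#' equal to `L` are included, this indicator-based rate exceeds the tail
#' probability `P(X > L)` that nominal censoring-percentage labels usually
#' refer to.
#'
#' @param y a `censored_series` (or plain vector with `limit`).
#' @param limit limit, required if `y` is a plain vector.
#' @return A proportion in \[0, 1\].
#' @export
censoring_fraction <- function(y, limit = NULL) {
  y <- as_censored_series(y, limit)
  mean(y$censored)
}
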