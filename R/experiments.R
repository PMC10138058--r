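#' Define a simulation-study scenario
#'
#' A scenario fixes true parameters, series length, censoring limit, the
#' estimation method and its settings, the number of independent
#' repetitions, and a master seed. The default grid of the accompanying
#' study uses `(alpha, lam)` in {(0.2, 3), (0.5, 5)},
#' `n` in {100, 350, 1000} and limits chosen so that roughly 30% or 5% of
#' the latent values exceed `L`.
#'
#' @param alpha,lam true PoINAR(1) parameters.
#' @param n series length.
#' @param limit censoring limit `L`.
#' @param side `"right"` (default) or `"left"`.
#' @param method one of `"gda"`, `"abc"`, `"cml"`, `"cls"`, `"naive"`.
#' @param n_reps number of independent repetitions (default 10, the
#'   reduced desk scale; the full study uses 50).
#' @param settings named list of method settings: for `"gda"`/`"naive"`
#'   arguments of [gda_control()]; for `"abc"` any of `n_draws`,
#'   `accept_q`, `lam_max`.
#' @param master_seed per-repetition seeds are `master_seed + rep`.
#' @return A validated list of class `"censinar_scenario"`.
#' @export
censinar_scenario <- function(alpha, lam, n, limit, side = "right",
                              method = c("gda", "abc", "cml", "cls", "naive"),
                              n_reps = 10, settings = list(),
                              master_seed = 1) {
  method <- match.arg(method)
  params <- ccid_params("poisson", alpha, lam)  # validates alpha/lam
  structure(list(alpha = alpha, lam = lam, n = as.integer(n),
                 limit = as.integer(limit), side = side, method = method,
                 n_reps = as.integer(n_reps), settings = settings,
                 master_seed = as.integer(master_seed), params = params),
            class = "censinar_scenario")
}

# reduced-scale method defaults for desk runs (internal); the full-scale
# study settings are gda_control() defaults and n_draws = 1e6
.scenario_fit <- function(sc, y) {
  s <- sc$settings
  switch(sc$method,
    gda = coef(gda_poinar(y, control = do.call(gda_control, c(
      list(n_iter = s$n_iter %||% 4000, burn_in = s$burn_in %||% 1000,
           thin = s$thin %||% 10),
      s[setdiff(names(s), c("n_iter", "burn_in", "thin"))])))),
    naive = coef(naive_gibbs_poinar(y, control = do.call(gda_control, c(
      list(n_iter = s$n_iter %||% 4000, burn_in = s$burn_in %||% 1000,
           thin = s$thin %||% 10),
      s[setdiff(names(s), c("n_iter", "burn_in", "thin"))])))),
    abc = coef(abc_poinar(y, n_draws = s$n_draws %||% 2e4,
                          accept_q = s$accept_q %||% 0.001,
                          lam_max = s$lam_max %||% 10)),
    cml = cml_poinar(y$values)$estimate,
    cls = cls_poinar(y$values))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a simulation-study scenario
#'
#' For each repetition: simulate a latent PoINAR(1) path, censor it at the
#' scenario limit, estimate `(alpha, lambda)` with the scenario method, and
#' record the point estimates. Aggregates per parameter are the mean,
#' bias (mean minus truth), standard deviation, coefficient of variation
#' (sd/mean) and RMSE. Failed repetitions are caught, counted and excluded
#' with a warning.
#'
#' @param scenario a [censinar_scenario()].
#' @param verbose print a line per repetition.
#' @return An object of class `"scenario_result"`: the scenario, a
#'   per-repetition data frame of estimates and empirical censoring rates,
#'   an aggregate `summary` data frame, and the failure count.
#' @export
run_scenario <- function(scenario, verbose = FALSE) {
  stopifnot(inherits(scenario, "censinar_scenario"))
  sc <- scenario
  rows <- vector("list", sc$n_reps)
  n_failed <- 0L
  for (r in seq_len(sc$n_reps)) {
    set.seed(sc$master_seed + r)
    x <- rccid(sc$n, sc$params)
    y <- censor(x, sc$limit, sc$side)
    est <- tryCatch(.scenario_fit(sc, y), error = function(e) {
      warning("repetition ", r, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(est)) { n_failed <- n_failed + 1L; next }
    rows[[r]] <- data.frame(rep = r, alpha = unname(est[1]),
                            lambda = unname(est[2]),
                            cens_rate = mean(y$censored))
    if (verbose)
      cat(sprintf("rep %2d: alpha = %.4f lambda = %.4f\n", r, est[1], est[2]))
  }
  est_df <- do.call(rbind, rows)
  if (is.null(est_df)) stop("all repetitions failed")
  agg <- function(v, true) {
    m <- mean(v)
    s <- if (length(v) > 1L) sd(v) else 0
    data.frame(mean = m, bias = m - true, sd = s, cv = s / m,
               rmse = sqrt(mean((v - true)^2)))
  }
  summ <- rbind(cbind(parameter = "alpha", true = sc$alpha,
                      agg(est_df$alpha, sc$alpha)),
                cbind(parameter = "lambda", true = sc$lam,
                      agg(est_df$lambda, sc$lam)))
  structure(list(scenario = sc, estimates = est_df, summary = summ,
                 n_failed = n_failed,
                 single_rep = sc$n_reps == 1L),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf(
    "Scenario: alpha = %g, lambda = %g, n = %d, L = %d (%s), method = %s\n",
    sc$alpha, sc$lam, sc$n, sc$limit, sc$side, sc$method))
  cat(sprintf("  %d repetitions (%d failed), mean empirical rate at L: %.3f\n",
              sc$n_reps, x$n_failed, mean(x$estimates$cens_rate)))
  if (x$single_rep)
    cat("  single repetition: sd/cv reported as 0\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a reproducible synthetic fixture to disk
#'
#' Simulates one latent path and its censored version under a fixed seed
#' and writes three files to `dir`: `latent.csv` and `censored.csv`
#' (single-column headerless integer series) and `meta.json` (parameters,
#' seed and the realised censoring rate). Identical inputs produce
#' identical files.
#'
#' @param alpha,lam,n,limit,side scenario fields as in
#'   [censinar_scenario()].
#' @param seed RNG seed.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
generate_fixture <- function(alpha, lam, n, limit, side = "right",
                             seed = 1, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(seed)
  x <- rccid(n, ccid_params("poisson", alpha, lam))
  y <- censor(x, limit, side)
  paths <- c(latent = file.path(dir, "latent.csv"),
             censored = file.path(dir, "censored.csv"),
             meta = file.path(dir, "meta.json"))
  write_series(x, paths[["latent"]])
  write_series(y$values, paths[["censored"]])
  jsonlite::write_json(
    list(alpha = alpha, lam = lam, n = n, limit = limit, side = side,
         seed = seed, cens_rate = mean(y$censored)),
    paths[["meta"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a fixture written by [generate_fixture()]
#'
#' @param dir fixture directory.
#' @return A list with the `latent` series, the `censored` series (as a
#'   `censored_series`), and the `meta` list.
#' @export
read_fixture <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  latent <- read_series(file.path(dir, "latent.csv"))
  cens <- as_censored_series(read_series(file.path(dir, "censored.csv")),
                             meta$limit, meta$side)
  list(latent = latent, censored = cens, meta = meta)
}

#' Read / write a single-column headerless count series
#'
#' Plain-text interchange format: one non-negative integer per line. The
#' round trip is exact.
#'
#' @param x integer series (for `write_series`).
#' @param path file path.
#' @return `read_series` returns an integer vector; `write_series` returns
#'   the path invisibly.
#' @export
read_series <- function(path) {
  v <- scan(path, what = integer(), quiet = TRUE)
  .check_counts(v, arg = "series file")
}

#' @rdname read_series
#' @export
write_series <- function(x, path) {
  if (inherits(x, "censored_series")) x <- x$values
  x <- .check_counts(x, arg = "x")
  writeLines(as.character(x), path)
  invisible(path)
}
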