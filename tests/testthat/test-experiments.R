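test_that("scenario aggregates are internally consistent", {
  sc <- censinar_scenario(0.5, 5, 200, 11, method = "cls", n_reps = 12,
                          master_seed = 3)
  res <- run_scenario(sc)
  expect_equal(nrow(res$estimates), 12)
  s <- res$summary
  # RMSE^2 = bias^2 + sd^2 * (n-1)/n
  for (i in 1:2)
    expect_equal(s$rmse[i]^2,
                 s$bias[i]^2 + s$sd[i]^2 * 11 / 12, tolerance = 1e-10)
  expect_equal(s$cv, s$sd / s$mean, tolerance = 1e-12)
})

test_that("a single-repetition scenario reports the lone estimate", {
  sc <- censinar_scenario(0.5, 5, 200, 11, method = "cls", n_reps = 1,
                          master_seed = 4)
  res <- run_scenario(sc)
  expect_true(res$single_rep)
  expect_equal(res$summary$sd, c(0, 0))
  expect_equal(res$summary$mean,
               c(res$estimates$alpha, res$estimates$lambda))
})

test_that("fixtures are reproducible and carry their metadata", {
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  generate_fixture(0.5, 5, 350, 11, seed = 9, dir = d1)
  generate_fixture(0.5, 5, 350, 11, seed = 9, dir = d2)
  for (f in c("latent.csv", "censored.csv", "meta.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  fx <- read_fixture(d1)
  expect_equal(fx$meta$alpha, 0.5)
  expect_equal(length(fx$latent), 350)
  expect_identical(censor(fx$latent, 11)$values, fx$censored$values)
  # about P(X >= 11) = 0.417 of the entries sit at the limit
  frac <- censoring_fraction(fx$censored)
  expect_gt(frac, 0.20); expect_lt(frac, 0.45)
})

test_that("series files round-trip exactly", {
  set.seed(12)
  x <- rpois(100, 7)
  f <- tempfile(fileext = ".csv")
  write_series(x, f)
  expect_identical(read_series(f), as.integer(x))
})

test_that("bias falls with sample size and rises with censoring (GDA)", {
  cells <- expand.grid(n = c(100, 350), L = c(11, 14))
  ctl <- list(n_iter = 1500, burn_in = 500, thin = 5)
  res <- lapply(seq_len(nrow(cells)), function(i)
    run_scenario(censinar_scenario(0.5, 5, cells$n[i], cells$L[i],
                                   method = "gda", n_reps = 6,
                                   settings = ctl, master_seed = 42)))
  getb <- function(r, p) abs(r$summary$bias[r$summary$parameter == p])
  getr <- function(r, p) r$summary$rmse[r$summary$parameter == p]
  # larger n shrinks |bias| in at least 3 of the 4 (L, parameter) cells
  improved <- c(
    getb(res[[2]], "alpha") <= getb(res[[1]], "alpha"),
    getb(res[[2]], "lambda") <= getb(res[[1]], "lambda"),
    getb(res[[4]], "alpha") <= getb(res[[3]], "alpha"),
    getb(res[[4]], "lambda") <= getb(res[[3]], "lambda"))
  expect_gte(sum(improved), 3)
  # heavier censoring (L = 11) never beats lighter (L = 14) on RMSE;
  # 6-rep RMSEs are noisy, hence the slack factor
  for (p in c("alpha", "lambda")) {
    expect_gte(getr(res[[1]], p), getr(res[[3]], p) * 0.75)
    expect_gte(getr(res[[2]], p), getr(res[[4]], p) * 0.75)
  }
})
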