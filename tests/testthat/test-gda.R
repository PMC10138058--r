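test_that("truncated Poisson draws live on the tail with the right mean", {
  set.seed(1)
  w0 <- rtpois(5e4, 10, lower = 0)
  expect_lt(abs(mean(w0) - 10), 3 * sqrt(10 / 5e4))
  w <- rtpois(1e5, 10, lower = 11)
  expect_true(all(w >= 11))
  tm <- tpois_mean_oracle(10, 11)
  expect_lt(abs(mean(w) - tm), 3 * sd(w) / sqrt(1e5))
  expect_error(rtpois(1, 1, lower = 300), "unreachable")
})

test_that("MMS imputation takes the ceiling of the median", {
  expect_identical(mms_impute(c(11, 12, 13)), 12L)
  expect_identical(mms_impute(c(11, 12, 13, 14, 15, 15, 16, 16, 17, 18)), 15L)
  expect_identical(mms_impute(c(11, 11, 12, 12)), 12L)  # 11.5 rounds up
  expect_error(mms_impute(numeric(0)), "non-empty")
})

test_that("full conditionals are the likelihood-plus-prior up to a constant", {
  set.seed(21)
  y <- censor(rccid(80, ccid_params("poisson", 0.5, 5)), 11)
  z <- y$values
  z[y$censored] <- 11L + rpois(sum(y$censored), 2)  # an augmented series
  lam_grid <- seq(2, 9, length.out = 20)
  diff_l <- log_fc_lambda(lam_grid, 0.45, z) -
    (vapply(lam_grid,
            function(l) cloglik(z, ccid_params("poisson", 0.45, l)),
            numeric(1)) + dgamma(lam_grid, 0.1, 0.1, log = TRUE))
  expect_lt(max(diff_l) - min(diff_l), 1e-8)
  a_grid <- seq(0.05, 0.95, length.out = 20)
  diff_a <- log_fc_alpha(a_grid, 5.2, z) -
    (vapply(a_grid, function(a) cloglik(z, ccid_params("poisson", a, 5.2)),
            numeric(1)) + dbeta(a_grid, 2, 2, log = TRUE))
  expect_lt(max(diff_a) - min(diff_a), 1e-8)
})

test_that("full conditionals collapse to their priors on an all-zero series", {
  z <- integer(20)
  l <- c(0.5, 1, 2)
  expect_equal(log_fc_lambda(l, 0.4, z, shape = 1, rate = 0.1),
               -(0.1 + 19) * l)
  a <- c(0.2, 0.5, 0.9)
  expect_equal(log_fc_alpha(a, 5, z, a = 2, b = 2), log(a) + log1p(-a))
  # the Beta(2,2) kernel is symmetric but the full conditional on real data
  # is not
  set.seed(3)
  z2 <- rccid(40, ccid_params("poisson", 0.5, 5))
  expect_false(isTRUE(all.equal(log_fc_alpha(0.3, 5, z2),
                                log_fc_alpha(0.7, 5, z2))))
})

test_that("full conditional of lambda decreases beyond its mode", {
  set.seed(22)
  z <- rccid(150, ccid_params("poisson", 0.5, 5))
  g <- seq(0.5, 20, length.out = 80)
  v <- log_fc_lambda(g, 0.5, z)
  mode_i <- which.max(v)
  expect_true(all(diff(v[mode_i:length(v)]) < 0))
})

test_that("slice sampler targets the stated distributions", {
  set.seed(31)
  x <- slice_sample_uni(function(u) -u^2 / 2, -10, 10, 4e4)
  expect_lt(abs(mean(x)), 4 * batch_se(x))
  expect_lt(abs(sd(x) - 1), 0.02)
  b <- slice_sample_uni(function(u) log(u) + log1p(-u), 0, 1, 4e4)
  ks <- suppressWarnings(ks.test(b, function(q) pbeta(q, 2, 2)))
  expect_gt(ks$p.value, 1e-4)  # correlated draws: loose KS check
  g <- slice_sample_uni(function(u) dgamma(u, 0.1, 0.1, log = TRUE),
                        1e-12, 500, 4e4)
  expect_lt(abs(mean(g) - 1), 4 * batch_se(g))
})

test_that("chain bookkeeping: kept size, reproducibility, augmentation", {
  y <- sim_censored(0.5, 5, 150, 11, seed = 41)
  ctl <- gda_control(n_iter = 900, burn_in = 300, thin = 7)
  set.seed(5); f1 <- gda_poinar(y, control = ctl)
  set.seed(5); f2 <- gda_poinar(y, control = ctl)
  expect_identical(f1$draws, f2$draws)
  expect_equal(nrow(f1$draws), floor((900 - 300) / 7))
  expect_true(all(f1$draws[, "alpha"] > 0 & f1$draws[, "alpha"] < 1))
  expect_true(all(f1$draws[, "lambda"] > 0))
  aug <- f1$augmented
  expect_true(all(aug$values[aug$source == "imputed"] >= 11))
  expect_identical(aug$values[aug$source == "observed"],
                   y$values[!y$censored])
  expect_error(gda_poinar(y, control = gda_control(n_iter = 200,
                                                   burn_in = 150, thin = 30)),
               "fewer than 10")
})

test_that("with no entries at the limit the sampler needs no imputation", {
  set.seed(51)
  x <- rccid(800, ccid_params("poisson", 0.5, 5))
  y <- censor(x, max(x) + 1L)  # limit above the sample maximum
  expect_false(any(y$censored))
  set.seed(6); fg <- gda_poinar(y, control = fast_ctl())
  set.seed(6); fn <- naive_gibbs_poinar(y, control = fast_ctl())
  expect_identical(fg$draws, fn$draws)  # same sweeps, nothing to impute
  # posterior recovers the truth on uncensored data
  pm <- coef(fg)
  ps <- apply(fg$draws, 2, sd)
  expect_lt(abs(pm["alpha"] - 0.5), 3 * ps["alpha"])
  expect_lt(abs(pm["lambda"] - 5), 3 * ps["lambda"])
})

test_that("compiled and reference engines draw from the same posterior", {
  y <- sim_censored(0.5, 5, 100, 11, seed = 61)
  set.seed(7)
  fr <- gda_poinar(y, control = gda_control(n_iter = 700, burn_in = 200,
                                            thin = 2), engine = "r")
  set.seed(7)
  fc <- gda_poinar(y, control = gda_control(n_iter = 3000, burn_in = 500,
                                            thin = 2), engine = "cpp")
  for (p in c("alpha", "lambda")) {
    se <- sqrt(batch_se(fr$draws[, p])^2 + batch_se(fc$draws[, p])^2)
    expect_lt(abs(coef(fr)[p] - coef(fc)[p]), 4 * se)
  }
})

test_that("kept halves of the chain agree (stationarity smoke test)", {
  y <- sim_censored(0.5, 5, 200, 11, seed = 71)
  set.seed(8)
  fit <- gda_poinar(y, control = fast_ctl(n_iter = 4000, burn_in = 1000))
  d <- fit$draws[, "alpha"]
  h <- length(d) %/% 2
  a <- d[1:h]; b <- d[(h + 1):(2 * h)]
  se <- sqrt(batch_se(a, 20)^2 + batch_se(b, 20)^2)
  expect_lt(abs(mean(a) - mean(b)), 3 * se)
})

test_that("GDA-MMS bias at the study conditions is small in magnitude", {
  # Censoring-blind fits at this cell are off by ~+0.12 (alpha) and ~-1.6
  # (lambda); the data-augmented sampler must stay an order of magnitude
  # closer to the truth. (The sign of its residual bias is not asserted:
  # at these scales it is statistically indistinguishable from zero, see
  # the vignette.)
  reps <- 10
  est <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    y <- sim_censored(0.5, 5, 350, 11, seed = 500 + r)
    set.seed(600 + r)
    est[r, ] <- coef(gda_poinar(y, control = fast_ctl()))
  }
  bias <- colMeans(est) - c(0.5, 5)
  expect_lt(abs(bias[1]), 0.04)
  expect_lt(abs(bias[2]), 0.45)
})
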