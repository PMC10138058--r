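test_that("parameter objects validate their domain", {
  p <- ccid_params("poisson", 0.5, 5)
  expect_equal(p$mu, 10)
  expect_null(p$xi)
  expect_error(ccid_params("poisson", 0, 5), "alpha")
  expect_error(ccid_params("poisson", 1, 5), "alpha")
  expect_error(ccid_params("poisson", 0.5, -1), "lam")
  expect_error(ccid_params("negbin", 0.5, 5), "xi")
  expect_error(ccid_params("genpoisson", 0.5, 5, xi = 1.2), "xi")
})

test_that("thinning operator has binomial behaviour and degenerate limits", {
  p <- ccid_params("poisson", 0.5, 5)
  expect_identical(rthin(5, 0L, p), integer(5))
  set.seed(1)
  draws <- rthin(2e4, 10L, p)
  expect_true(all(draws >= 0 & draws <= 10))
  se <- sqrt(10 * 0.5 * 0.5 / 2e4)
  expect_lt(abs(mean(draws) - 5), 3 * se)
  p1 <- ccid_params("poisson", 1 - 1e-9, 5)
  expect_true(all(rthin(100, 7L, p1) == 7L))
})

test_that("quasi-binomial thinning is a pmf and flags support violations", {
  p <- ccid_params("genpoisson", 0.3, 3, xi = 0.2)
  for (x in c(1L, 4L, 9L))
    expect_equal(sum(thin_pmf(0:x, x, p)), 1, tolerance = 1e-12)
  # alpha close to 1 pushes 1 - alpha - s*xi/mu below zero for s >= 1
  pbad <- ccid_params("genpoisson", 0.95, 3, xi = 0.9)
  expect_error(thin_pmf(0:8, 8L, pbad), "s = ")
})

test_that("simulated paths reproduce the stationary moments", {
  set.seed(42)
  p <- ccid_params("poisson", 0.5, 5)
  x <- rccid(1e5, p)
  n <- length(x)
  # SE of the mean of an AR(1)-correlated series: var * (1+a)/(1-a) inflation
  se_mean <- sqrt(10 * (1 + 0.5) / (1 - 0.5) / n)
  expect_lt(abs(mean(x) - 10), 3 * se_mean)
  expect_lt(abs(var(x) - 10), 4 * 10 * sqrt(2 / n) * 2)
  expect_lt(abs(acf1(x) - 0.5), 4 * sqrt((1 - 0.25) / n))

  x2 <- rccid(1e5, ccid_params("poisson", 0.2, 3))
  se2 <- sqrt(3.75 * (1 + 0.2) / (1 - 0.2) / n)
  expect_lt(abs(mean(x2) - 3.75), 3 * se2)
})

test_that("simulation is reproducible under a fixed seed", {
  p <- ccid_params("negbin", 0.4, 3, xi = 2)
  set.seed(7); a <- rccid(200, p)
  set.seed(7); b <- rccid(200, p)
  expect_identical(a, b)
})

test_that("transition pmf reduces to the innovation pmf at l = 0", {
  p <- ccid_params("poisson", 0.5, 5)
  expect_equal(trans_pmf(0:20, 0L, p), dpois(0:20, 5))
  pg <- ccid_params("genpoisson", 0.3, 3, xi = 0.15)
  expect_equal(trans_pmf(0:20, 0L, pg), innov_pmf(0:20, pg))
})

test_that("transition pmf matches exhaustive convolution and normalises", {
  p <- ccid_params("poisson", 0.5, 5)
  expect_equal(trans_pmf(4, 3L, p), trans_oracle(4, 3, p), tolerance = 1e-12)
  for (prm in list(p, ccid_params("negbin", 0.3, 3, xi = 2),
                   ccid_params("genpoisson", 0.3, 3, xi = 0.15))) {
    for (l in c(0L, 2L, 7L))
      expect_equal(sum(trans_pmf(0:300, l, prm)), 1, tolerance = 1e-10)
  }
})

test_that("conditional log-likelihood agrees with transition products", {
  p <- ccid_params("poisson", 0.5, 5)
  expect_equal(cloglik(c(0L, 0L), p), -5)  # log Po(5) pmf at 0
  set.seed(3)
  x <- rccid(60, p)
  ll <- cloglik(x, p)
  ll_prod <- sum(log(vapply(2:60, function(t) trans_pmf(x[t], x[t - 1], p),
                            numeric(1))))
  expect_equal(ll, ll_prod, tolerance = 1e-10)
  # general (non-compiled) family path agrees with its transition pmf too
  pn <- ccid_params("negbin", 0.4, 3, xi = 2)
  set.seed(4)
  xn <- rccid(30, pn)
  lln <- sum(log(vapply(2:30, function(t) trans_pmf(xn[t], xn[t - 1], pn),
                        numeric(1))))
  expect_equal(cloglik(xn, pn), lln, tolerance = 1e-10)
  # conditioning starts at t = 2: a 2-point series only uses one transition
  expect_equal(cloglik(c(3L, 4L), p), log(trans_pmf(4, 3L, p)))
})

test_that("conditional log-likelihood peaks near the truth on a long path", {
  set.seed(11)
  x <- rccid(3000, ccid_params("poisson", 0.5, 5))
  grid <- expand.grid(alpha = c(0.3, 0.4, 0.5, 0.6, 0.7),
                      lam = c(3, 4, 5, 6, 7))
  ll <- mapply(function(a, l) cloglik(x, ccid_params("poisson", a, l)),
               grid$alpha, grid$lam)
  best <- grid[which.max(ll), ]
  expect_equal(best$alpha, 0.5)
  expect_equal(best$lam, 5)
})
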