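# Independent oracles used across tests.

# Distribution of R(l) + e by exhaustive enumeration of all
# (survivors, innovation) pairs; independent of the j-sum in trans_pmf().
trans_oracle <- function(k, l, params, emax = 400) {
  g <- thin_pmf(0:l, l, params)
  pe <- innov_pmf(0:emax, params)
  pr <- as.vector(outer(g, pe))
  tot <- as.vector(outer(0:l, 0:emax, "+"))
  vapply(k, function(ki) sum(pr[tot == ki]), numeric(1))
}

# E[X | X >= lo] for X ~ Poisson(mu), by direct summation of the pmf.
tpois_mean_oracle <- function(mu, lo, kmax = 500) {
  ks <- lo:kmax
  sum(ks * dpois(ks, mu)) / ppois(lo - 1, mu, lower.tail = FALSE)
}

# Monte-Carlo standard error of the mean of a correlated chain, by batch
# means.
batch_se <- function(x, n_batch = 40) {
  bs <- floor(length(x) / n_batch)
  bm <- colMeans(matrix(x[seq_len(bs * n_batch)], nrow = bs))
  sd(bm) / sqrt(n_batch)
}

# small censored PoINAR(1) realisation shared by several tests
sim_censored <- function(alpha, lam, n, limit, seed) {
  set.seed(seed)
  censor(rccid(n, ccid_params("poisson", alpha, lam)), limit)
}

fast_ctl <- function(n_iter = 2000, burn_in = 500, thin = 5, ...)
  gda_control(n_iter = n_iter, burn_in = burn_in, thin = thin, ...)
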