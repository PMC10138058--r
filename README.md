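# censinar

Bayesian estimation for count time series observed under a known detection
limit (type-1 censoring).

## The problem

Counts recorded by a capped process — calls answered by a fixed pool of
operators, events truncated at a device's detection limit — follow a latent
integer-valued autoregression but are observed as

```
Y_t = min(X_t, L),      X_t = α ∘ X_{t-1} + e_t,   e_t ~ Po(λ),
```

where `α ∘ X = Σ Bernoulli(α)` is binomial thinning and `L` is a known
integer limit (the Poisson INAR(1) model; left censoring is the mirror
case). Fitting the INAR(1) model to the censored series as if it were
complete inflates the estimated dependence `α` and deflates the innovation
mean `λ`. `censinar` is for analysts who need unbiased `(α, λ)` inference
from such series: it implements two censoring-aware Bayesian estimators and
the censoring-blind baselines that quantify the bias they remove.

* **GDA-MMS** (`method = "gda"`): a Gibbs sampler with data augmentation.
  Each sweep samples `λ` and `α` from their full conditionals (slice
  sampling within Gibbs, compiled sweep) and re-imputes every entry at the
  limit by the ceiling of the median of `m = 10` draws from the
  `Po(λ/(1-α))` marginal truncated to `[L, ∞)`. Priors `α ~ Beta(2,2)`,
  `λ ~ Gamma(0.1, 0.1)`; chains start at conditional least squares.
* **Rejection ABC** (`method = "abc"`): draws `(α, λ)` from uniform
  priors, simulates censored paths, summarises each by the KL divergence
  of empirical pmfs, the lag-1 autocorrelation and the fraction of entries
  at the limit, and accepts the lowest quantile of a variance-scaled
  composite distance.
* **Baselines**: conditional least squares (`"cls"`), conditional maximum
  likelihood (`"cml"`) and a no-imputation Gibbs sampler (`"naive"`), all
  ignoring the limit.

Simulators for the wider convolution-closed family (Poisson, negative
binomial, generalised Poisson marginals) and a scenario harness for
repetition studies are included.

## A worked example

```r
library(censinar)
set.seed(42)
p <- ccid_params("poisson", alpha = 0.5, lam = 5)   # marginal mean 10
x <- rccid(350, p)                                  # latent path
y <- censor(x, limit = 11)                          # observed series
censoring_fraction(y)
#> [1] 0.3714286

coef(censinar(y, method = "cml"))    # censoring-blind: biased
#>     alpha    lambda
#> 0.6146659 3.4492352

fit <- censinar(y, method = "gda", seed = 1)        # censoring-aware
coef(fit)
#>     alpha    lambda
#> 0.4579197 5.1756667
```

With ~37 % of the entries sitting at `L = 11`, the blind conditional-ML
fit drifts to `(0.61, 3.45)` — serial dependence overstated by a fifth,
innovation mean understated by a third — while the data-augmented sampler
returns `(0.46, 5.2)`, within posterior uncertainty of the truth
`(0.5, 5)`. `summary()`, `plot()`, `simulate()`, `predict()`,
`residuals()` and `logLik()` work on the fitted object as usual.

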