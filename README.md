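# benchdose

Benchmark-dose (BMD) estimation for toxicology and ecotoxicology in R.

Risk assessors derive a point of departure from dose–response data as the
dose producing a predefined small change in response — the benchmark
response (BMR) — relative to the background, and report its one-sided
lower confidence limit (BMDL) as the regulatory quantity. `benchdose`
fits parametric dose–response models to binomial, count, and continuous
endpoints by maximum likelihood and derives BMD/BMDL under all the
standard definitions, with several uncertainty methods, model averaging,
a nonparametric isotonic alternative, and a two-step meta-analytic
procedure for hierarchical designs.

## What it computes

**Definitions.** For binomial data, additional risk
(BMR = f(BMD, β) − p₀) and excess risk
(BMR = (f(BMD, β) − p₀)/(1 − p₀)), with the background p₀ taken from
the model limit at dose 0, a control group, or prior knowledge. For
continuous endpoints, the hybrid approach dichotomizes the response at a
cut-off x₀ (given directly, or k standard deviations from the control
mean) under a normal model, p₀ = 1 − Φ((x₀ − f(0, β))/σ), and applies
the same two risk definitions; added (absolute), extra
(range-normalized), and relative (fold-change) definitions and a
directly specified response level are also available. Definitions flip
sign for decreasing adverse directions.

**Models.** Log-logistic, log-normal, Weibull type 1/2, exponential
decay, and multistage families in the drc parameterization (e.g.
f(d) = c + (d\* − c)/(1 + exp(b(log d − log e)))), with normal,
binomial, Poisson, and NB2 negative-binomial likelihoods, optional
exposure offsets for counts, and optional log-transformed responses.

**Uncertainty.** Delta-method Wald BMDLs on the natural (truncated at 0)
or log scale via after-fitting, inverse regression on the one-sided
confidence band, nonparametric / parametric / semiparametric bootstrap
(with (Y+¼)/(N+½) shrinkage for degenerate binomial groups), and
sandwich (robust, optionally cluster-robust) covariance
A⁻¹B(A⁻¹)ᵀ for misspecified variance structures.

**Model averaging.** AIC/BIC/user weights w_k ∝ exp(−Δ_k/2); BMD by
estimate averaging (Σ w_k BMD_k) or curve averaging (solve on
Σ w_k f_k); BMDL by the Buckland variance inequality, weighted
per-model BMDLs, or bootstrap with weights recomputed per replicate.

## Worked example

An earthworm-style acute toxicity test: six concentrations, 40 worms
each, mortality counted, natural (background) mortality estimated as
the lower limit of a three-parameter log-normal curve.

```r
library(benchdose)
worms <- make_fixture_suite(seed = 1)$earthworm
fit <- drfit(worms, "LN.4", fixed = c(d = 1))  # upper limit fixed at 1
fit
#> Dose-response model LN.4 (binomial)
#> Parameters:
#>          b          c          d          e
#>  1.4451462  0.1001848  1.0000000 42.7535803
#> logLik: -12.2095  AIC: 30.419  direction: increasing

spec <- bmr_spec(0.05, "additional")  # 5% additional risk, model-based p0
est <- bmd(fit, spec)
est
#> BMD (additional): 14.19743  SE: 3.681994  target level: 0.1501848

bmdl_delta(fit, est)
#> BMDL (delta, one-sided 95%): 8.141094   BMD: 14.19743

bootstrap_bmd(worms, "LN.4", spec, fixed = c(d = 1), n_boot = 1000, seed = 1)
#> BMDL (boot_nonparametric, one-sided 95%): 7.618586   BMD: 14.19743   [ 9 failed replicates ]
```

The fitted background mortality is c ≈ 0.100, so the BMD is the
concentration where the probability of death reaches
0.100 + 0.05 ≈ 0.150 (the printed target level); the delta and
bootstrap BMDLs are the one-sided 95% lower limits by the two methods.

Model averaging, the isotonic BMD, and hierarchical designs follow the
same pattern; see `?ma_bootstrap_bmdl`, `?bmd_isotonic`, and
`?fit_per_cluster`, the methods vignette in `vignettes/`, and the
configuration pipeline `?run_analysis` (also exposed as a command-line
script in `inst/cli/benchdose.R`).

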