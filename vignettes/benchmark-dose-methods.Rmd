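---
title: "Benchmark-dose methodology in benchdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmark-dose methodology in benchdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benchdose)
```

## The estimation problem

A dose–response experiment observes a response $Y$ (death indicator,
offspring count, body weight, ...) at a handful of dose levels $d_i$.
The benchmark dose (BMD) is the dose at which a fitted curve
$f(d, \beta)$ reaches a predefined small change — the benchmark
response (BMR) — relative to the background level, and the quantity
actually carried into risk assessment is the BMDL, the lower limit of a
one-sided confidence interval for the BMD. Everything in this package
exists to make those two numbers, and the assumptions behind them,
explicit and reproducible.

## Dose–response models

Six families are provided in the conventional dose–response
parameterization built around the kernel argument
$t = \log d - \log e$, where $e$ is the location (the dose of
half-maximal kernel response):

* log-logistic: $f(d) = c + (d^\ast - c) / (1 + \exp(b t))$
* log-normal: kernel $\Phi(b t)$
* Weibull type 1: kernel $\exp(-\exp(b t))$
* Weibull type 2: kernel $1 - \exp(-\exp(b t))$
* exponential decay: $f(d) = c + (d^\ast - c) \exp(-d/e)$
* multistage: $f(d) = c + (1 - c)(1 - \exp(-\sum_m b_m d^m))$,
  $b_m \ge 0$

$c$ and $d^\ast$ are the lower and upper limits; two- and
three-parameter versions fix them at 0 and/or 1, and any parameter can
be fixed by the user (e.g. `fixed = c(d = 1)` to estimate a binomial
lower limit as a natural background rate). The value at dose 0 is
always the analytic limit of the kernel, never an evaluation at
$\log 0$. Note one quirk inherited from the convention: the sign of
$b$ that makes a curve increasing differs between the logistic and the
normal/Weibull kernels.

Fitting is by maximum likelihood per response distribution: grouped
binomial; Poisson or NB2 negative binomial ($\mathrm{var} = \mu +
\mu^2/\theta$) for counts, with the `weight` column usable as an
exposure offset so that $f$ is a rate per exposure unit; and normal
with a single pooled residual standard deviation $\sigma$, profiled out
analytically. A pooled $\sigma$ is an assumption, not a theorem —
residual plots (`standardized_residuals()`) are the check. Positive
parameters ($e$, $\theta$, multistage slopes) are optimized on the log
scale by a Nelder–Mead simplex refined with BFGS (relative
log-likelihood tolerance $10^{-8}$); starting values come from
self-starters that read the limits off extreme group means and
linearize the kernel (logit/probit/log–log transforms regressed on log
dose). Two-parameter kernel families with binomial data are exact
GLMs in log dose, and are fitted by iteratively reweighted least
squares with the matching link for speed; the solution is the same
maximum-likelihood estimate. The covariance of $\hat\beta$ is the
inverse observed information (central-difference Hessian). AIC counts
$\sigma$ and $\theta$ as parameters; this can shift AIC by a constant
relative to software that does not, but the constant cancels in the
AIC differences that drive model weights.

## BMD definitions

With background probability $p_0$ (risk definitions) or background
mean $f(0,\beta)$, `target_response()` translates a BMR into the
response level $y^\ast$ the curve must reach:

| definition | target $y^\ast$ (increasing adverse direction) |
|---|---|
| additional | $p_0 + \mathrm{BMR}$ |
| excess | $p_0 + \mathrm{BMR}(1 - p_0)$ |
| hybrid additional | $x_0 - \sigma\,\Phi^{-1}(1 - \mathrm{BMR} - p_0)$ |
| hybrid excess | $x_0 - \sigma\,\Phi^{-1}(1 - \mathrm{BMR}(1-p_0) - p_0)$ |
| added | $f(0) + \mathrm{BMR}$ |
| extra | $f(0) + \mathrm{BMR}(f(\infty) - f(0))$ |
| relative | $f(0)(1 + \mathrm{BMR})$ |
| point | $\mathrm{BMR}$ |

The hybrid definitions address continuous endpoints that carry no
intrinsic notion of "adverse": a cut-off $x_0$ — given in response
units, or as $k$ standard deviations from the control mean, or implied
by a specified background probability — dichotomizes the response under
a normal model, and $p_0 = 1 - \Phi((x_0 - f(0,\beta))/\sigma)$. Two
$\sigma$'s could be meant here: the control group's own SD or the
pooled residual SD of the fit. The fitted model assumes variance
homogeneity, so the pooled SD is the default (`sigma_source =
"pooled"`); the control-only option is exposed for users who want the
cut-off anchored strictly to control variability.

For a decreasing adverse direction all signs flip; for excess risk the
rescaling denominator becomes the available range $p_0$, giving
$y^\ast = p_0(1 - \mathrm{BMR})$. The adverse direction is inferred
from the fitted curve and can be overridden (`adverse =` in
`bmr_spec()`) for endpoints where the lower tail is the adverse one.
Two identities are useful sanity checks and are enforced in the test
suite: additional and excess coincide when $p_0 = 0$, and extra
coincides with excess when the curve limits are 0 and 1.

The BMD solves $f(\mathrm{BMD}, \beta) = y^\ast$ — in closed form for
the invertible kernels, otherwise by Brent bracketing on the log-dose
interval $[10^{-12} d_{\max}, 100\, d_{\max}]$. Targets outside the
curve's range raise an error naming the range; solutions beyond the
largest tested dose are flagged as extrapolation rather than refused.

## Standard errors and BMDLs

The BMD never enters the model parameterization; it is derived
*after* fitting, and its standard error follows from the delta method
through the implicit-function theorem: for
$h(d, \beta) = f(d, \beta) - y^\ast(\beta)$,
$g = -\frac{\partial h/\partial\beta}{\partial h/\partial d}$ at the
estimate and $\mathrm{se} = \sqrt{g^\top \Sigma g}$. The target is
recomputed under each parameter perturbation, so model-based
backgrounds propagate. Curves nearly flat at the BMD
($|\partial h/\partial d| < 10^{-12}$) are refused — a delta SE there
would be meaningless.

BMDL options:

* **Wald**: $\max(0, \mathrm{BMD} - z_{0.95}\,\mathrm{se})$, or on the
  log scale $\exp(\log \mathrm{BMD} - z\,\mathrm{se}/\mathrm{BMD})$,
  which cannot truncate to zero.
* **Inverse regression**: the smallest dose where the one-sided
  pointwise delta-method band on $f$ reaches $y^\ast$. The band is
  pointwise, not simultaneous.
* **Bootstrap**: nonparametric (resample within dose groups; binomial
  groups drawn from their observed proportions), parametric (normal
  with group means and a common SD, binomial, Poisson/NB2), or
  semiparametric (recentred residuals resampled onto the fitted curve,
  continuous only). The BMDL is the empirical 5% quantile (type 7) of
  the converged replicate BMDs at the default one-sided 0.95 level.
  Degenerate all-0/all-1 binomial groups are resampled from the
  shrunken proportion $(Y + \tfrac14)/(N + \tfrac12)$ so replicates are
  not frozen at the degenerate outcome. Replicates are seeded
  individually from the master seed, so results are bit-reproducible;
  failed replicates are dropped, counted, and reported, and more than
  20% failures aborts with advice to review the model — silently
  dropping them would hide instability. Self-starters are re-run in
  every replicate rather than recycling the original estimates, so a
  replicate cannot inherit a poor original fit. For the parametric
  continuous sampler the common SD defaults to the pooled within-group
  SD (consistent with the fitted model's homogeneity assumption), with
  a control-group-SD option.

When the variance model is in doubt (overdispersed counts being the
classic case — check `overdispersion_ratio()`, the residual deviance
per degree of freedom), the sandwich covariance
$\hat A^{-1} \hat B (\hat A^{-1})^\top$ replaces the model-based
$\Sigma$ in the delta method: $\hat A$ is the observed information and
$\hat B$ the outer-product sum of per-observation scores, summed within
clusters first when cluster-robust errors are requested. Point
estimates are untouched; only the uncertainty widens.

## Model averaging

Candidate models $k = 1 \dots K$ receive weights
$w_k = \exp(-\Delta_k/2) / \sum_i \exp(-\Delta_i/2)$ from their AIC
(or BIC) differences $\Delta_k$. An alternative $\exp(-\Delta_k)$
kernel is available via `delta_scale = 1`; published weight tables are
not always unambiguous about which kernel produced them, so both are
provided and neither is asserted as canonical. The MA BMD is either
the weighted average of per-model BMDs or the BMD of the averaged curve
$f_{MA} = \sum_k w_k f_k$ (backgrounds recomputed from $f_{MA}$
itself). For the BMDL: the Buckland variance inequality
$\mathrm{se}_{MA} = \sum_k w_k \sqrt{\mathrm{var}_k + (\mathrm{BMD}_k -
\mathrm{BMD}_{MA})^2}$ with a Wald limit; a weighted average of
per-model BMDLs; or bootstrap, which is the only available route for
curve averaging. Inside each bootstrap replicate the weights are
recomputed from the replicate AICs — freezing them would discard
exactly the model-selection uncertainty that motivates averaging.
Candidates that fail on the original data are dropped with a warning
before averaging.

## Isotonic alternative

When no parametric shape is defensible, the dose-group means are
projected onto the monotone cone by the weighted pool-adjacent-violators
algorithm (weights = group sizes) and the BMD is read off the linear
interpolant between the two flanking dose levels. Interpolation is on
the natural dose scale by default (a log-dose option exists); the trend
direction comes from the weighted Spearman correlation, with ties
raising an error that asks for an explicit direction. Only the
non-hybrid definitions are supported, with backgrounds taken from the
monotonized control mean; the estimator has no closed-form SE, so its
BMDL comes from the shared bootstrap machinery with the refit replaced
by monotonization. Two structural caveats: the estimate is confined to
the observed dose range by construction, and a piecewise-linear
interpolant is biased wherever the true curve is strongly convex
between dose levels — it is only trustworthy when the design brackets
the target response with reasonably close dose levels.

## Hierarchical designs

Nested designs (sub-experiments, batches) violate the independence
assumption of a pooled fit. The supported procedure is two-step: fit
the dose–response model per cluster, extract BMD and delta SE, and
combine by DerSimonian–Laird random-effects meta-analysis
($Q = \sum w_i (\theta_i - \bar\theta_{FE})^2$,
$\tau^2 = \max(0, (Q - (K-1)) / (\sum w - \sum w^2/\sum w))$,
inverse-variance weights $1/(\mathrm{se}_i^2 + \tau^2)$). Combination
is on the natural BMD scale by default with a log-scale option
(`log_scale = TRUE` combines log-BMDs and exponentiates); the log
scale is the better approximation when per-cluster BMDs are skewed,
which is common, and is what the heterogeneity-recovery tests use.
The BMDL is a one-sided normal limit without a Knapp–Hartung
adjustment — a known limitation, anticonservative at very small $K$.
DL is non-iterative and standard; REML is out of scope. Clusters whose
fit or BMD fails are excluded with a warning, never silently.

## Synthetic data and what the tests show

All test inputs are generated in code (`scenario_spec()` /
`generate_scenario()`): seeded draws from a known true curve under
normal, binomial, Poisson, or NB2 noise, plus a hierarchical generator
that perturbs the log-location per cluster (for the kernel families a
shift of $\log e$ is exactly a shift of the log-BMD, so the
between-cluster SD is interpretable on the log-BMD scale). Every
scenario carries an independent truth record: the true BMD is obtained
by plain bisection on the true curve at tolerance $10^{-12}$,
deliberately a different algorithm from the package's solver, so the
two cannot confirm each other's bugs.

The continuous validation design uses four-parameter log-logistic
truths with lower and upper limits 2 and 10 observed at doses 0.1,
0.5, 1, 5, 10 with 10 (or 3) replicates and SD 0.1 (or 1); the three
location/shape profiles (`validation_scenario()`) are this package's
own choice — shallow $(b,e) = (-0.75, 2)$, medium $(-1.5, 1)$, steep
$(-3, 1)$ — as only the limits, doses, and noise levels of such a
design are conventionally fixed.

Problem sizes in the test suite were chosen to make the statistical
claims sharp but cheap: the binomial coverage study uses 300 data sets
at four doses (0.5, 2, 8, 32; geometric spacing around the true BMD of
10/9 from a log-logistic with $b = -1$, $e = 10$) with 50 animals per
dose and 250 bootstrap replicates; pilot theory says a one-sided 95%
interval estimated over 300 runs has a binomial SE of about 1.3%, so
the accepted band 0.90–0.98 separates real failure from noise. The
homogeneous-$\tau^2$ check uses $K = 30$ clusters because the
positive-part DL estimator's bias is of order
$0.4\sqrt{2/(K-1)}$ of the sampling variance — at small $K$ that bias
alone would swamp the property being tested.

What passing these tests does **not** show: the generators draw i.i.d.
noise from the assumed distributions, so they exercise correctness of
the machinery, not robustness to real-data pathologies — litter
effects, non-monotone (hormetic) responses, dose-measurement error,
missing high-dose animals, or variance heterogeneity beyond what the
sandwich estimator absorbs.

## Numerical choices, in one place

* optimizer: Nelder–Mead then BFGS, relative tolerance $10^{-8}$;
  positive parameters on the log scale; IRLS fast path for binomial
  two-parameter kernels.
* BMD root: closed form where the kernel inverts, else Brent on
  $[10^{-12} d_{\max}, 100\,d_{\max}]$ (log-dose scale), tolerance
  $10^{-12}$; consistency $|f(\mathrm{BMD}) - y^\ast| < 10^{-8}$
  enforced.
* derivatives: central differences, step $10^{-5}\max(|\beta_j|,
  10^{-3})$ for information/score matrices.
* bootstrap quantile: type 7, on converged replicates only; >20%
  failures abort.
* Wald truncation at 0 on the natural scale; confidence levels are
  one-sided everywhere, and a level $\le 0.5$ is rejected with a hint
  rather than silently reinterpreted.
* degenerate inputs: saturated designs warn; all-constant responses fit
  a flat curve whose BMD is then correctly unreachable; zero predicted
  variances yield zero residuals with a warning, not NaN.

## Limitations

Profile-likelihood BMDLs, simultaneous inference over multiple
endpoints or curves, mixed-effects dose–response models (the two-step
meta-analysis is the supported alternative), hormesis and
fractional-polynomial families, transform-both-sides estimation, and
Bayesian model averaging are out of scope. The `extra` definition
requires a finite upper asymptote and errors otherwise rather than
guessing one.
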