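---
title: "Asymmetric Lomax links for imbalanced binary regression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asymmetric Lomax links for imbalanced binary regression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lomaxlink)
```

## The problem

Binary regression links the probability of success to a linear predictor
through a cdf, $p_i = F(\eta_i)$, $\eta_i = x_i'\beta$.  The usual choices
(logit, probit) are symmetric: they approach 0 and 1 at the same rate, which
implicitly assumes the two classes behave symmetrically.  When one class is
rare — diseased trees among healthy ones, occasional blood donors among
regulars — that assumption costs predictive sharpness and biases the
coefficients.  An asymmetric link lets the approach to 0 differ from the
approach to 1, and a single extra parameter can control how much.

## The distributions

The base distribution here is the **double Lomax (DLomax)**: the
distribution of the ratio of two i.i.d. standard Laplace variates, a
symmetric, very heavy-tailed density on the real line,

$$g(x) = \frac{1}{2\sigma(1 + |x-\mu|/\sigma)^2}, \qquad
G(x) = \begin{cases}
  \dfrac{1}{2(1 + (\mu - x)/\sigma)}, & x \le \mu,\\[4pt]
  1 - \dfrac{1}{2(1 + (x - \mu)/\sigma)}, & x > \mu.
\end{cases}$$

Skew is introduced by exponentiation of the standard ($\mu=0$, $\sigma=1$)
cdf.  The **power double Lomax (PDLomax)** has
$F_P(x \mid \lambda) = G(x)^\lambda$ and the **reverse power double Lomax
(RPDLomax)** has $F_{RP}(x \mid \lambda) = 1 - G(-x)^\lambda$, both with
$\lambda > 0$.  At $\lambda = 1$ both collapse to the DLomax; away from 1
they are genuinely asymmetric, and the two families are reflections of each
other: $F_{RP}(x) = 1 - F_P(-x)$.  (Note the sign flip: the reflection acts
on the argument as well as the probability.  The identity
`rpdlomax_cdf(x, lam) + pdlomax_cdf(-x, lam) == 1` is enforced to 1e-12 in
the test suite.)

In regression terms, $\lambda$ tunes how fast the success probability
saturates on each side, so one family handles an excess of 0's more
gracefully and the other an excess of 1's.  Which one fits a given dataset
better is an empirical question answered by the comparison metrics below.
Moments and shape constants of these transformed distributions are not
derived here; the package only needs their cdfs, densities and quantiles,
all of which are closed-form.

Quantiles invert the closed forms directly
($F_P^{-1}(p) = G^{-1}(p^{1/\lambda})$,
$F_{RP}^{-1}(p) = -G^{-1}((1-p)^{1/\lambda})$), and powers are always
computed as $\exp(\lambda \log G)$, keeping the tails accurate for small
and large $\lambda$ alike.

## The regression model and its priors

$$Y_i \mid \beta, \lambda \sim \text{Bernoulli}(p_i), \quad
p_i = F_\lambda(x_i'\beta), \quad
\beta_j \sim N(0, 10^2), \quad
\delta = \log\lambda \sim U(-2, 2).$$

The log-scale reparameterization $\delta = \log\lambda$ improves sampling
geometry, and the uniform bounds confine $\lambda$ to
$(e^{-2}, e^{2}) = (0.14, 7.39)$: beyond that range the extra skew obtained
from increasing $\lambda$ is practically nil, so wider priors only add
ridge-shaped posterior mass without changing the fitted curve.  All results
are reported on the $\lambda$ scale by applying $\exp$ to the $\delta$
draws — so the reported mean of $\lambda$ is $\overline{\exp(\delta)}$, not
$\exp(\bar\delta)$ (Jensen's inequality makes the difference real, and the
tests assert the convention).

Eight links are available: `logit`, `probit`, `cauchit`,
`loglog` ($e^{-e^{-\eta}}$), `cloglog` ($1 - e^{-e^{\eta}}$), `dlomax`,
`pdlomax`, `rpdlomax`.  The DLomax is fit as its own (symmetric,
$\lambda$-free) link rather than as a power link pinned at $\lambda = 1$,
so its comparison metrics are not charged for a parameter it does not use.

## Posterior computation

`fit_binreg()` samples with a **Laplace-initialized adaptive random-walk
Metropolis** algorithm:

1. `delta` is mapped to an unbounded coordinate by a scaled logistic
   transform, with the Jacobian folded into the target, so proposals never
   fight the prior boundary.
2. The posterior mode is found with BFGS (started at the logistic-regression
   MLE), and the proposal covariance is the inverse Hessian at the mode
   scaled by $2.38^2/d$ — the classical optimum for Gaussian targets.
3. Chains start from jittered copies of the mode; during warmup a
   Robbins–Monro recursion nudges the global proposal scale toward a 0.234
   acceptance rate.  Warmup draws are discarded.

For these posteriors — at most six coefficients plus one $\delta$, smooth
and nearly Gaussian at the mode — a well-calibrated random-walk chain is
accurate and fast; a gradient-based sampler would reduce autocorrelation
but the parameter-recovery and prior-recovery tests show the posterior
means, spreads and interval coverage are already where they should be.
Convergence is monitored with the split potential scale reduction factor
$\hat R$ per parameter: a warning above 1.05, a `converged = FALSE` flag
above 1.1.  Non-converged fits are surfaced, never silently used —
`comparison_table()` blanks their rows, which is also the honest way to
report a model whose sampler would not settle (the PDLomax link on strongly
separated data is a known offender: its $\beta$ and $\lambda$ are weakly
identified together, and the posterior develops a long curved ridge).

The point-estimate convention throughout is the posterior mean.  A master
seed fans out per-chain (and, in the studies, per-replicate) seeds through
a single `sample.int` call, so any subset of the work is independently
reproducible and a fixed master seed gives bit-identical reports.

## Model comparison

With $D(\theta) = -2\log p(y \mid \theta)$:

* $\bar D$ = posterior mean deviance; $\hat D = D(\bar\beta, \bar\delta)$
  (the *mean of the $\delta$ draws* is plugged in, matching the definition
  of $\hat D$ as deviance at posterior-mean parameters);
* $\rho_d = \bar D - \hat D$, $\text{DIC} = \bar D + \rho_d$,
  $\text{EAIC} = \bar D + 2k$, $\text{EBIC} = \bar D + k\log n$;
* $\text{WAIC} = -2(\widehat{\text{LPPD}} - \hat p_{\text{WAIC}})$ from the
  pointwise posterior predictive densities;
* LOO via **truncated importance sampling**: raw ratios
  $r_i^{(s)} = 1/p(y_i \mid \theta^{(s)})$ are capped at
  $\sqrt{S}\,\bar r_i$ and
  $\widehat{\text{elpd}}_i = \log\left(\sum_s w_i^{(s)} p(y_i \mid \theta^{(s)}) \big/ \sum_s w_i^{(s)}\right)$.
  The truncation is the simplest stabilization in the PSIS-LOO family;
  full generalized-Pareto smoothing would reduce the (already small)
  upward noise of the raw ratios further but is not needed at the
  problem sizes here — the test suite checks the estimator directly
  against exact leave-one-out refitting.  **LOO is reported as
  $-2\sum_i \widehat{\text{elpd}}_i$**, i.e. on the deviance scale, so its
  magnitude lines up with WAIC in comparison tables.

Smaller is better for every metric; only orderings are meaningful, so the
tests assert orderings and the algebraic identities, never absolute values.

Model adequacy is checked with **randomized quantile residuals**: with
$\hat p_i$ the posterior-mean predictive probability,
$u_i \sim U(0, 1-\hat p_i)$ for $y_i = 0$ and $u_i \sim U(1-\hat p_i, 1)$
for $y_i = 1$, and $r_i = \Phi^{-1}(u_i)$.  Under a correctly specified
model these are i.i.d. standard normal regardless of the response
distribution.  The randomization takes an explicit seed; residuals
integrate the posterior only through $\hat p_i$, which keeps them cheap and
deterministic given the fit.

## The simulation studies and what the generators emulate

**Parameter recovery** (`recovery_study()`): data are generated from the
model itself — one covariate $X \sim U(-3,3)$, $\beta = (0, 1)$ — and
refit, for each link and sample size.  Replicated estimates are summarized
by bias, RMSE and the coverage (CP) of the central 95% posterior interval.
RMSE is $\sqrt{R^{-1}\sum_r (\hat\theta^{(r)} - \theta)^2}$; because the
squared and rooted conventions are easy to confuse across reports, the
summary carries both `rmse` and `mse` columns.  Replicated fits use 4
chains of 1250 iterations (250 warmup): random-walk draws are
autocorrelated, and this length is calibrated so each fit carries roughly
the effective sample size that a few hundred near-independent
gradient-sampler draws would — with materially fewer draws the empirical
2.5/97.5 interval endpoints narrow and coverage is understated.  The test
suite runs 30 replicates per cell at $n \in \{500, 2000\}$, enough to see
bias and RMSE shrink with $n$ and coverage sit in the high 0.8s–0.9s;
single-cell bias estimates at 30 replicates still wobble by about
$\text{RMSE}/\sqrt{30}$, which the tests account for when comparing bias
across sample sizes.

**Misspecification** (`misspec_study()`): data come from a *power Cauchy*
model, $p_i = (\arctan(\eta_i)/\pi + 1/2)^\lambda$, which none of the
candidate links matches, with $\lambda \in \{0.25, 0.5, 2, 4\}$ covering
success rates from roughly 80% down to 20% (the exact expectations under
$X \sim U(-3,3)$ are 0.805, 0.669, 0.338 and 0.205 by quadrature —
`expected_success_rate()` is the oracle the generator is tested against).
Each candidate link is scored by WAIC and LOO per replicate, and each
asymmetric link by the fraction of replicates in which it beats the logit
baseline.

What these generators deliberately emulate: a single uniformly distributed
covariate, a known truth, and imbalance induced through the response
function rather than through rare-event intercepts.  What they do not
emulate: correlated or many covariates, covariate measurement error,
label noise, or separation — so passing these studies shows the estimator
and the comparison machinery work as designed, not that any particular
link will win on a given real dataset.

## Application workflow

`load_binary_csv()` validates and z-scores covariates, storing the (mean,
sd) pairs; `correlation_screen()` drops one member of every covariate pair
with $|r| \ge 0.95$ — the member with the larger mean absolute correlation
to the remaining covariates, ties broken by column order.  The 0.95 default
sits below the correlations at which screening is uncontroversial (0.98,
1.0) but above anything a well-posed design should contain.
Standardization constants always come from the analyzed dataset itself;
there is no train/test split in this workflow.

`predict_at()` makes plug-in predictions at raw covariate values
(unspecified covariates sit at their means, i.e. standardized zero), using
posterior means for $\beta$ and $\lambda$; `effect_curve()` sweeps one
covariate over a grid the same way, and `class_predictive_summary()`
summarizes the per-observation mean posterior predictive probabilities by
observed class — the clearest single display of whether an asymmetric link
actually separates an imbalanced pair of classes.

## Numerical choices and edge cases

* Probabilities are clipped to $[10^{-12}, 1-10^{-12}]$ before entering
  log-likelihoods; extreme linear predictors thus cost likelihood rather
  than producing $-\infty$.
* The DLomax cdf's two branches agree at the location; $x \le \mu$ is
  evaluated with the left branch.  The density has a kink at the location
  (a measure-zero point; finite-difference cdf/pdf consistency is tested
  away from it).
* An empty dataset is legal: the sampler then reproduces the prior, which
  is one of the property tests.
* Sampler failures in replicated studies are recorded per replicate and
  excluded from summaries (`R_effective` counts survivors), not fatal.

## Known limitations

* The PDLomax link can fail to converge on data that favor a strongly
  reversed asymmetry; the package reports this rather than fixing it, as
  the remedy (informative priors on $\lambda$) changes the model.
* Truncated importance sampling, like all importance-sampling LOO, can be
  optimistic for observations with very influential likelihood terms; the
  `max_weight_frac` diagnostic exposes weight concentration.
* Frequentist/MLE fitting, stacking, and confusion-matrix-based evaluation
  are out of scope.
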