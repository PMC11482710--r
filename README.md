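# lomaxlink

Bayesian binary regression with **asymmetric Lomax link functions** for
imbalanced classification problems — rare diseased trees among healthy
ones, occasional blood donors among regulars, defaults among good payers.

Symmetric links (logit, probit) force the success probability to approach
0 and 1 at the same rate. `lomaxlink` provides links built from the double
Lomax (DLomax) distribution — the heavy-tailed ratio of two i.i.d. standard
Laplace variates — skewed by a single exponent λ:

- **PDLomax**: F_P(x | λ) = G(x)^λ
- **RPDLomax**: F_RP(x | λ) = 1 − G(−x)^λ

with G the standard DLomax cdf, G(x) = 1/[2(1 − x)] for x ≤ 0 and
1 − 1/[2(1 + x)] for x > 0. At λ = 1 both collapse to the symmetric
DLomax; away from 1 each family saturates faster on one side, which is
exactly what an imbalanced response calls for. The regression model is

    Y_i ~ Bernoulli(p_i),   p_i = F_λ(x_i'β),
    β_j ~ N(0, 10²),        δ = log λ ~ U(−2, 2),

fit by a Laplace-initialized adaptive Metropolis sampler with split-R̂
convergence diagnostics. Model choice uses DIC/EAIC/EBIC plus WAIC and
truncated-importance-sampling LOO (reported on the deviance scale), and
adequacy is checked with randomized quantile residuals. The package also
ships the two supporting simulation studies (well-specified parameter
recovery; misspecification under a power Cauchy generator,
p = (arctan(η)/π + 1/2)^λ) and an application workflow with CSV
ingestion, standardization, correlation screening, effect curves and
class-conditional predictive summaries.

## Worked example

Fit an imbalanced synthetic dataset (21.5% successes) with the logit and
RPDLomax links and compare:

```r
library(lomaxlink)

d <- simulate_binary(lomax_link("rpdlomax", lambda = 0.4),
                     beta = c(-1, 1.2), n = 1500, seed = 1)
fits <- list(
  logit    = fit_binreg(d, lomax_link("logit"),
                        config = fit_config(seed = 2, iterations = 1250,
                                            warmup = 250)),
  rpdlomax = fit_binreg(d, lomax_link("rpdlomax"),
                        config = fit_config(seed = 3, iterations = 1250,
                                            warmup = 250)))
fits$rpdlomax
#>    parameter    mean      sd  median      p5     p95  rhat
#>  (Intercept) -0.9305 0.22279 -0.9364 -1.2899 -0.5388 1.007
#>           x1  1.1638 0.15121  1.1472  0.9369  1.4170 1.023
#>        delta -0.8786 0.10294 -0.8668 -1.0680 -0.7232 1.024
#>       lambda  0.4176 0.04254  0.4203  0.3437  0.4852 1.024
```

The true parameters (β₀, β₁, λ) = (−1, 1.2, 0.4) are recovered within the
posterior spread, and λ's 90% interval excludes 1: the data genuinely want
an asymmetric link. The comparison table (smaller is better everywhere)
prefers RPDLomax on every criterion:

```r
comparison_table(fits)
#>      model   rho_d   D_bar   D_hat     DIC    EAIC    EBIC     LOO    WAIC
#> 1    logit 1.88393 1286.19 1284.31 1288.08 1290.19 1300.82 1288.21 1288.19
#> 2 rpdlomax 2.84747 1272.11 1269.26 1274.96 1278.11 1294.05 1275.00 1274.97
```

and the class-conditional predictive summary shows why: the RPDLomax fit
pushes the observed failures toward low probabilities (median 0.085)
while keeping the successes high (median 0.429), a wider separation than
the logit fit manages (0.113 vs 0.373):

```r
class_predictive_summary(fits$rpdlomax)
#>     class    min     q1 median  mean    q3   max    n
#> 1 success 0.0405 0.2553 0.4292 0.372 0.515 0.556  323
#> 2 failure 0.0401 0.0541 0.0848 0.172 0.266 0.556 1177
```

Plug-in predictions at raw covariate values use published or fitted
posterior-mean summaries together with the standardization constants, e.g.
for a fitted remote-sensing model of diseased trees:

```r
std <- data.frame(name = c("GLCM_Pan", "Mean_R", "Mean_NIR", "SD_Pan"),
                  mean = c(127.07, 107.74, 453.70, 20.64),
                  sd   = c(10.67, 71.77, 156.20, 6.76))
beta <- c(26.110, 1.142, 137.094, -19.340, 0.206)
predict_at(beta, lam = 0.256, link = "rpdlomax",
           values = c(Mean_R = 90), covariate_names = std$name,
           standardization = std)
#> [1] 0.01490382
predict_at(beta, lam = 0.256, link = "rpdlomax",
           values = c(Mean_R = 100), covariate_names = std$name,
           standardization = std)
#> [1] 0.5597561
```

— the probability of disease jumps from 1.5% to 56% across a 10-unit
window of the red band, the steep effect `effect_curve()` traces in full.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/lomaxlink.R compare --data mydata.csv --response y \
    --links logit,dlomax,rpdlomax --seed 1 --out results/
```

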