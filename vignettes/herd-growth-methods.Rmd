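---
title: "Hierarchical Ricker models for multi-herd count series: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Ricker models for multi-herd count series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(herdgrowth)
```

## The model

`herdgrowth` analyses annual abundance indices of socially bonded ungulate
herds — groups of females, juveniles and subadult males counted repeatedly
each year. The abundance index for a herd-year is the highest single-survey
group count, plus any hunter harvest recorded for that year; adult males are
never counted. The unit of inference is the growth observation
$(N_t, r_t)$ with $r_t = \ln(N_{t+1}/N_t)$.

The growth response is the linearized Ricker model

$$r_t = r_{\max} + \beta N_t + \varepsilon_t,$$

where $r_{\max}$ is the intrinsic per-capita growth rate (the model's
y-intercept, per year), $\beta$ the strength of density dependence (per
animal per year, negative under regulation), and carrying capacity is the
x-intercept $K = -r_{\max}/\beta$. Four per-herd variants add temporal
random effects:

| variant | growth response | temporal variation |
|---|---|---|
| `none` | $r_{\max,j} + \beta_j N_t$ | — |
| `r_var` | $r_{\max,j} + \beta_j N_t + \gamma_{t,j}$ | additive (density-independent) |
| `beta_var` | $r_{\max,j} + \beta_{\delta t,j} N_t$ | multiplicative (density-dependent) |
| `both` | $r_{\max,j} + \beta_{\delta t,j} N_t + \gamma_{t,j}$ | both |

with $\gamma_{t,j} \sim N(0, \sigma_{\gamma j})$ and
$\beta_{\delta t,j} \sim N(\mu_{\beta\delta j}, \sigma_{\beta\delta j})$.
All herds are fitted **jointly**: $r_{\max,j}$ is a herd-level random effect
around a common mean ($\mu_{r\max}$, $\sigma_{r\max}$) because the intrinsic
rate should be similar within a species, while every $\beta$ parameter is
herd-specific, and one residual SD $\sigma_\varepsilon$ is shared by all
herds. The shared residual is not a convenience: within a single herd, the
additive effect $\gamma_{t}$ and the residual are statistically confounded
(one observation per year for each), so the temporal SDs are identified only
as each herd's *excess* spread over the pooled residual level.

Priors follow the vague JAGS-style convention: all means get
$N(0, \text{precision } 0.001)$ (variance 1000) and all SDs get
$\text{Uniform}(0, 100)$.

## Sampler

Because every location parameter has a conjugate normal conditional, the
posterior is sampled by Gibbs sweeps written in C++ (via Rcpp), with the
Uniform-prior SDs updated by univariate slice sampling (stepping-out plus
shrinkage, bounded at 0 and 100). No adaptive tuning is needed, so the
"adaptation" phase of the run configuration is simply extra discarded
warm-up prepended to the counted iterations; retained draws per chain are
`iterations - burn_in`. The default configuration mirrors a full-scale run
(3 chains × 150,000 iterations, burn-in 75,000, adaptation 75,000, no
thinning); `quick_config()` gives a reduced 3 × 10,000 setting for tests and
exploration. Chains start from jittered OLS estimates (chain 1 unjittered)
so the split-$\hat R$ diagnostic — pass requires $\hat R < 1.01$ for every
parameter — is meaningful. Seeds fan out deterministically: chain $c$ of a
run with seed $s$ uses `set.seed(1000 s + c)`, and the sampler draws all
randomness from R's RNG.

The per-draw deviance is the joint conditional deviance
$-2\sum_{t,j}\log N(r_{t,j} \mid \mu_{t,j}, \sigma_\varepsilon)$ over all
herds — which is why a deviance table's "no temporal variation" column is
one constant number for every herd: it is the same baseline joint fit.

## Model selection and its operating characteristics

`selection_procedure()` fits the baseline (all herds `none`) and then, for
each herd in turn, three joint fits upgrading only that herd. Each herd's
variant is chosen by `select_variant()`: the minimum mean deviance wins if
it beats the runner-up by more than 2; otherwise the simplest variant within
2 of the minimum wins (complexity `none` < `r_var` = `beta_var` < `both`;
ties at equal complexity go to the lower deviance).

A caution that our simulations make explicit: the posterior mean
*conditional* deviance is a liberal selection score for one-effect-per-
observation random effects. With ~20 observations per herd, a herd's sample
residual variance fluctuates around the pooled level with a chi-square
spread of roughly ±35%, and any excess is absorbed by $\gamma_t$ or
$\beta_{\delta t}$, dropping the joint mean deviance by well over the
margin of 2. In null simulations (no temporal variation anywhere, seven
herds, T = 20, $\sigma_\varepsilon = 0.1$) only about a third of
herd-selections come out `none`; we verified with 10×-longer chains and
dispersed starts that this is a property of the exact posterior, not a
mixing artifact. Conversely, genuine additive variation
($\sigma_\gamma = 0.15$ against $\sigma_\varepsilon = 0.1$) is preferred in
a clear majority of replicates. A mean-deviance margin rule therefore has
good power but a high false-variation rate at these series lengths —
consistent with such procedures detecting temporal variation in nearly
every herd they are applied to. The corresponding acceptance test asserts
the stated expectation for the null case and is expected to fail; we keep
it failing rather than weaken the assertion.

## Estimates, detection, and exclusion

`summarize_herd()` reports posterior medians and central 95% credible
intervals. $K$ is computed per draw as $-r_{\max,j}/\beta$, where $\beta$
is the herd's fixed slope or, under slope-varying variants, the per-draw
hyper-mean $\mu_{\beta\delta j}$ (an option pools per-draw, per-year
$-r_{\max}/\beta_{\delta t}$ instead; the hyper-mean is the defensible
default since per-year slopes can pass through zero). The $K$ interval comes
from quantiles of the per-draw ratio, not from combining interval endpoints.
Density dependence is *detected* when the slope's 95% CrI lies entirely
below zero; herds failing detection have no usable $K$ (the ratio's interval
spans zero symmetrically into the thousands) and are excluded from the
stochasticity and regression stages, with the exclusion logged.

## Stochasticity decomposition

For each eligible herd the predicted variance of next abundance under the
classical Ricker form $N_{t+1} = \alpha N_t e^{-\beta_\Delta N_t}$
($\alpha = e^{r_{\max}}$, $\beta_\Delta = |\beta|$) is split into

- demographic: $\alpha N e^{-\beta_\Delta N}(1 - e^{-\beta_\Delta N}) +
  \sigma^2_{dem} N e^{-2\beta_\Delta N}$ with $\sigma^2_{dem} = \alpha$ by
  convention;
- density-independent (changes in $r$): $\sigma^2_r\,\alpha^2 N^2
  e^{-2\beta_\Delta N}$;
- density-dependent (changes in $\beta$): $\sigma^2_\beta\,\alpha^2 N^4
  e^{-2\beta_\Delta N}$.

At $N = K$, $e^{-\beta_\Delta K} = 1/\alpha$ collapses these to $K$,
$\sigma_r^2 K^2$ and $\sigma_\beta^2 K^4$ — identities the tests verify to
$10^{-10}$ and which anchor the relative total stochasticity
$\mathrm{Var}(K)/K$.

One genuine ambiguity: the printed source equations reuse the same variance
symbol ($\sigma^2_{\beta_\Delta}$) in both environmental components, almost
certainly a transcription artifact. Our default (`sigma_r_mode =
"fitted_gamma"`) uses the fitted temporal-$r$ variance $\sigma_\gamma^2$ in
the density-independent term — zero when the selected variant has no
$\gamma$ — and `"as_printed"` reproduces the printed form. Relatedly, the
published "relative total variance" axis cannot be reconstructed exactly
from its description, so the second cross-herd regression is a qualitative
target: we assert its negative slope under either mode, not its
coefficients.

## Cross-herd regressions

Both relationships are ordinary least squares of a response on the
reciprocal of a positive predictor (posterior medians only; no
errors-in-variables correction): temporal slope variation
$\sigma_{\beta\delta}$ on $1/K$, and $\beta$ on one over the relative total
stochasticity. Feeding the bundled published estimates
(`elk_growth_estimates()`, six herds after exclusion) through the first
regression returns slope 0.101, intercept −0.00037, $R^2$ = 0.885 —
matching the published 0.099 / −0.00036 / 0.87 to within the rounding of
the printed inputs. $p$-values (two-sided $t$, $n-2$ df) are reported but
never used for gating.

## Synthetic data: what it emulates and what it does not

`simulate_herd()` iterates the fitted model forward on the log scale:
$\ln N_{t+1} = \ln N_t + r_{\max} + \gamma_t + \beta_t N_t + \epsilon_t$,
noise entering exactly where the linearized model's residual sits. Latent
abundance stays continuous, floored at one animal (the fitted model treats
$N$ as an index, not a census); harvest is removed after growth and recorded
in the harvest table. Each survey replicate draws a binomial count of the
rounded latent abundance at a fixed detection probability — a deliberate
stand-in, since the source surveys report only high detection (> 0.8,
CV ≈ 0.05) without an explicit observation model. `simulate_dataset()`
reproduces the field scale: seven herds, series of 18–23 years, carrying
capacities log-spaced from ~22 to ~600 animals, herd $r_{\max}$ drawn from
$N(0.231, 0.045)$ (the published hyper-parameters), one harvested herd and
one herd with missing survey years. Per-herd seeds derive deterministically
from the master seed.

What a green simulation-based test does **not** establish: robustness to
age/sex structure, observer trends, immigration pulses, or non-Ricker
(e.g. θ-logistic) curvature — none of which the generator produces.

## Numerical and interface choices

- Gap years (missing surveys) default to `skip`: transitions spanning a gap
  are dropped rather than annualized, never fabricating dynamics;
  `annualize` divides the log-ratio by the span and is offered as a flag.
- Missing harvest records mean zero harvest; ties in the yearly maximum
  count are harmless.
- The sign convention is centralized: fits report the (negative) slope
  $\beta$; the stochasticity layer takes $\beta_\Delta = |\beta|$ once, at
  `stoch_params()` construction.
- `Normal(0, 0.001)` priors are read as precision 0.001 — the convention of
  the Gibbs-sampling tools this model family is usually fitted with; an SD
  of 0.001 would be absurdly informative.
- Degenerate inputs error early and loudly: empty survey sets, non-positive
  abundances in a log-growth computation, $\beta = 0$ carrying capacities,
  single-chain convergence checks, inverse regressions with non-positive or
  constant predictors.
- The deviance-selection fits run with convergence checking disabled
  (`check = FALSE`) for speed; final fits attach a split-$\hat R$ report and
  warn — never silently — when any parameter exceeds 1.01.

## Known limitations

- Observer error is taken at face value (the source's sensitivity analysis
  found no bias, and we do not re-implement it).
- Mean-deviance selection is liberal at T ≈ 20 (see above); treat detected
  temporal variation in short series with caution.
- The Gibbs sampler can mix slowly in the $\sigma \to 0$ funnel of the
  variance components; the dispersed-start $\hat R$ gate is the guard rail,
  and paper-scale runs leave wide margins.
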