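---
title: "Two-sex demography of adult sex ratio bias: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sex demography of adult sex ratio bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asrdemog)
```

This vignette documents the models behind `asrdemog`, the assumptions they
make, the numerical choices in the implementation, and what the package's
simulation-based validation does and does not demonstrate about real field
data.

## The two-sex projection model

The population is censused just after breeding and classified into four
stages: female and male juveniles (the one-year transition from hatching to
recruitment) and female and male adults (a stasis stage). One annual step
multiplies the stage vector by a 4×4 matrix whose survival entries are the
sex- and stage-specific apparent survival probabilities
$\phi_{\female J}, \phi_{\male J}, \phi_{\female A}, \phi_{\male A}$ and whose
fecundity entries split per-capita reproduction by the hatching sex ratio
$\rho$ (the probability a hatchling is male).

Reproduction couples the sexes through a harmonic-mean mating function,

$$R_\female = \frac{k\, n_{\male A}}{n_{\male A} + n_{\female A}/h}, \qquad
  R_\male  = \frac{k\, n_{\female A}}{n_{\male A} + n_{\female A}/h},$$

so the matrix depends on the current adult composition and the model is
nonlinear: iteration, not an eigendecomposition, is the route to equilibrium.
The parameters, with units and defaults used across the package:

| parameter | meaning | domain | typical plover value |
|---|---|---|---|
| $\phi_{\cdot J}$ | annual apparent juvenile survival | $[0,1]$ | 0.15–0.55 |
| $\phi_{\cdot A}$ | annual apparent adult survival | $[0,1]$ | 0.55–0.80 |
| $\rho$ | hatching sex ratio (proportion male) | $[0,1]$ | ≈ 0.5 |
| $k$ | modal clutch size | integer ≥ 1 | 2 or 3 |
| $h$ | mating index: mean annual mates per male | $>0$ | 0.8–1 (polyandry–monogamy) |

"Apparent" survival deliberately confounds mortality with permanent
emigration; nothing in the package attempts to separate them. The adult sex
ratio is read from the stable stage distribution $\mathbf{w}$:
$\mathrm{ASR} = w_{\male A}/(w_{\male A}+w_{\female A})$.

### Equilibrium: simulation and an independent oracle

`stable_structure()` iterates the dynamics for 1000 steps (the default
horizon), renormalising the structure to unit sum each step — the dynamics are
homogeneous of degree one, so renormalisation changes nothing but prevents
overflow. Convergence is monitored by the max-norm change over the final step
against a $10^{-9}$ tolerance; across the plover-like parameter box above the
residual after 1000 steps is below $10^{-12}$.

`equilibrium_oracle()` solves the same equilibrium by an unrelated route.
Writing $x = n_{\male A}/n_{\female A}$, $\lambda$ for the per-step
multiplier, and $B(x) = kx/(x + 1/h)$ for the female-normalised birth rate
(total hatchlings per adult female is $2B(x)$), the adult recruitment balance
of each sex at equilibrium gives

$$\lambda(\lambda-\phi_{\female A}) = 2(1-\rho)\,\phi_{\female J} B(x),\qquad
  \lambda(\lambda-\phi_{\male A})\,x = 2\rho\,\phi_{\male J} B(x).$$

The factor $\lambda$ multiplying the left-hand sides reflects the one-step
delay between hatching and recruitment: juveniles counted at time $t$ recruit
at $t+1$, by which time the adult pool has grown by $\lambda$. Dropping that
factor (i.e. treating recruitment as same-step) shifts the equilibrium ASR by
up to ~0.02 whenever adult survival differs between the sexes, so the
delay-consistent form is the one implemented; the two routes agree with the
1000-step simulation to better than $10^{-6}$, which is the package's core
correctness test.

When one sex's adult survival exceeds any growth rate the other sex can
sustain, the system has no interior fixed point (ASR drifts to 0 or 1); the
oracle reports this as an error rather than returning a boundary value.

Closed forms used as test anchors: full symmetry gives ASR = 0.5; sex-equal
survival gives ASR = $\rho$; sex-equal *adult* survival gives
ASR $= \rho\phi_{\male J}/(\rho\phi_{\male J}+(1-\rho)\phi_{\female J})$, in
which case ASR is also invariant to $h$. A caution on symmetry: because $h$
divides only the female density, the model family is exactly mirror-symmetric
under swapping the sexes only at $h = 1$; at $h < 1$ the swap reverses the
direction of ASR bias but not to machine precision (≈ $10^{-3}$).

## Survival estimation (Cormack–Jolly–Seber)

Apparent survival and detection are estimated from annual encounter histories
conditioned on first capture. Every candidate model keeps
$\phi \sim \mathrm{sex} * \mathrm{stage}$; the eight candidates differ in the
detection structure, all subsets of $\{\mathrm{sex}, \mathrm{year},
\mathrm{stage}\}$ with full interactions among included terms. Design choices:

- **Cell-means parameterisation on the logit scale.** Full interactions make
  every model a cell-means model, so one logit parameter per observed cell is
  both the identifiable parameterisation and structurally keeps all
  probabilities in $(0,1)$. `K` counts the cells present in the data.
- **Stage as an age class.** A bird marked as a hatchling is a juvenile on its
  first survival interval and on its first possible re-encounter occasion,
  and an adult from then on; birds marked as adults are adults throughout.
- **Likelihood.** Products of per-interval survival/detection terms over the
  observed stretch, closed by the never-seen-again recursion
  $\chi_t = (1-\phi_t) + \phi_t(1-p_{t+1})\chi_{t+1}$. Identical histories are
  aggregated into weighted classes, which makes the likelihood cost
  independent of the number of individuals. An analytic score (direct terms
  plus backward accumulation through $\chi$) accelerates the quasi-Newton
  optimisation; it is verified against finite differences in the tests, and
  the likelihood itself against a brute-force enumeration of latent death
  times for short studies.
- **Optimisation.** BFGS with 5 starts by default (origin plus random); in
  bootstrap resamples one start from the full-data estimates suffices.
  Estimates with $|\mathrm{logit}| > 9$ are flagged as boundary cases (e.g.
  perfect detection). With year-dependent detection the final interval's
  $\phi$ and $p$ are identified only through their product; reported survival
  comes from the time-constant sex-stage cells, which are unaffected.
- **AICc** uses the number of released individual-occasions (occasions after
  first capture, summed over individuals) as the effective sample size. Ties
  are broken toward fewer parameters, then lexicographic model label.
- **Dispersion.** In place of an external goodness-of-fit bootstrap, the
  package simulates datasets from the fitted model (same releases), refits,
  and reports the ratio of observed to mean simulated deviance; values near 1
  indicate adequate dispersion and values above ~3 serious lack of fit.

## Hatching sex ratio and mating system

The hatching sex ratio is estimated by an intercept-only binomial GLMM (logit
link) with a brood random intercept, fitted by Laplace approximation via
`lme4`; when the brood variance estimate collapses (≤ $10^{-8}$) the model is
refitted as a plain GLM and flagged. The interval is Wald on the logit scale —
matching the intercept z-test used to judge deviation from parity — and
single-sex degenerate data fall back to an exact binomial interval on the
admissible side. Only complete broods should enter (the reader's
`complete_only` filter); partial broods would bias $\rho$ through post-hatch
brood mixing.

The mating index is $h = 1/\bar\mu$ where each female's annual mate rate is
$\mu_i = \max(1, m_i/b_i)$ over females seen breeding in at least two years.
The floor at 1 means $h \le 1$ by construction; the estimator rejects
configurations implying $h > 1$.

## LTRE decomposition of ASR bias

The deviation of ASR from parity is decomposed against a null parameter set
with no sex differences: survival of one sex copied onto the other (both the
female-referenced and male-referenced nulls are supported), $\rho = 0.5$,
$h = 1$. Each contribution is

$$C(\theta) = \Delta\theta \cdot
  \left.\frac{\partial\,\mathrm{ASR}}{\partial\theta}\right|_{M'},$$

with sensitivities evaluated at parameters midway between observed and null.
Because the mating function feeds perturbations back through the population
structure, sensitivities are computed numerically: the parameter is perturbed
over an 11-point grid spanning ±5% of its value (±0.025 absolute at zero),
clipped to its domain, the model is simulated to equilibrium at each point,
and the derivative is taken from an interpolating cubic spline. The grid is
narrow enough that the spline derivative matches central finite differences
to $10^{-3}$, and wide enough to be insensitive to the $10^{-12}$-level noise
of the equilibrium itself.

The decomposition is first order. Midpoint evaluation cancels the
second-order error exactly, so the residual
$\mathrm{ASR}(M)-\mathrm{ASR}(M_0)-\sum C(\theta)$ is third-order in the
parameter differences — typically below 3% of the deviation, but it can reach
~25% of a small deviation when juvenile survival differs between the sexes by
0.3 or more. The residual is therefore always computed and reported, never
absorbed; single-cause scenarios (only one parameter biased) attribute ≥95%
of the deviation to that parameter.

## Bootstrap propagation of survival uncertainty

ASR uncertainty comes from a six-step nonparametric bootstrap: (i) resample
encounter histories with replacement, stratified by stage at marking so the
release structure is preserved; (ii) refit all candidate CJS models; (iii)
take survival from the lowest-AICc fit — model-selection uncertainty thus
stays inside the interval, and the winning model per iteration is recorded;
(iv) rebuild the two-sex matrix with $\rho$, $k$, $h$ held at their point
estimates (only the mark-recapture data are resampled); (v) simulate 1000
steps; (vi) record ASR. The interval is the 2.5–97.5% percentile range of the
replicates. Because each replicate's four survival estimates come from a
single joint fit, their sampling correlations propagate into ASR. Failed
iterations (e.g. a resample missing a survival cell) are redrawn and counted;
more than 10% failures aborts. The interval covers mark-recapture sampling
variation only — uncertainty in $\rho$ and $h$ is deliberately outside it.

## Parental care

Families are classified as biparental, male-only or female-only. Simultaneous
95% intervals for the three proportions default to Bonferroni-adjusted exact
(Clopper–Pearson) intervals, whose joint coverage is guaranteed at every
sample size; the narrower equal-half-width construction (smallest integer
half-width whose exact conditional coverage under the multinomial at the
observed proportions reaches 95%, computed by truncated-Poisson convolution)
is available as `method = "sison_glaz"` but undercovers by a few percent at
very small $n$, which is why it is not the default.

The cross-population regressions acknowledge uncertainty on both axes: each
bootstrap iteration draws one ASR per population (from its stored bootstrap
replicates when available, else uniformly within its 95% CI) and one care
proportion per population (uniformly within its truncated simultaneous CI),
then fits the model. Cooperation uses the a priori concave quadratic
$P_{\male\female} = \beta_0+\beta_1 A+\beta_2 A^2$ (OLS). Uniparental care
uses $P = \beta_0 + e^{\beta_1 A}$, fitted by profiling $\beta_1$ (the
intercept is linear given the rate, so a 1-D grid-plus-refine search is
robust); a power-law base parameterisation $\beta_0 + {\beta_1'}^A$ with
$\beta_1' = e^{\beta_1}$ is available via `form = "power"`, but the
exponential-rate form is the default because it admits declining care
(negative rate) without leaving the reals. Mirrored datasets give
opposite-signed rate coefficients, though not exact negatives: the
additive-intercept exponential family is not closed under $A \mapsto 1-A$.

## The synthetic-data generator

`simulate_population()` emulates a multi-year colour-ringing study: a founding
adult cohort enters at occasion 1; each year `round(n0/2k)` complete broods of
exactly `k` chicks hatch, chick sex drawn at $\rho$ with a Normal(0,
`brood_sd`) brood intercept on the logit scale (the same structure the GLMM
estimator assumes; `brood_sd = 0` gives i.i.d. chick sexes). Survival is a
single per-interval Bernoulli per individual — juvenile rate on the first
interval for chicks, adult rate otherwise — and detection is an independent
Bernoulli per live individual per occasion. Histories with no detections are
discarded (and counted), matching the conditioning of the CJS likelihood;
chicks first detected after their hatch year enter as adult-marked, as they
would in the field. Mating records use a two-point annual-mate-rate
distribution calibrated so the population index converges to the target `h`
(only the mean is identified by the estimator, so the within-population
distribution is a free choice); care categories are i.i.d. draws from the
stated probabilities.

What passing recovery tests shows — and what it does not: the generator
matches the estimators' assumptions by construction (no trap response, no
transients, no heterogeneity beyond the brood effect, no emigration pulses,
no inter-annual variation in vital rates). Recovery therefore validates the
estimation machinery, not the robustness of the method to real-data
violations of those assumptions.

## Numerical choices and degenerate inputs

- Projection starts from the uniform structure (¼,¼,¼,¼); the asymptotic
  structure is independent of any interior start (tested).
- Equilibrium tolerance $10^{-9}$ max-norm over the final step; warnings carry
  the residual. Population collapse mid-projection returns the partial
  trajectory with an extinction flag.
- Root finding brackets $x \in (10^{-9}, 10^9)$ on the log scale, tolerance
  $10^{-13}$.
- Likelihood clipping at $10^{-12}$ exists only inside the optimiser's
  objective; the user-facing likelihood reports non-finite values with a
  warning instead of clipping.
- All random draws run under `with_seed()`, which restores the caller's RNG
  state; the pipeline derives per-population, per-stage child seeds from one
  master seed by a fixed integer hash, so any stage can be reproduced in
  isolation.
- Problem sizes in the test suite are chosen to keep the full run to a few
  minutes: recovery studies use hundreds to a few thousand histories,
  bootstrap checks use 100–200 iterations, and the heavyweight null-study
  check uses a ~42 000-history simulation with a 100-iteration bootstrap.

## Known limitations

- No density dependence, stochastic environments, multi-state movement,
  individual covariates or age structure beyond the juvenile/adult
  dichotomy.
- The LTRE does not isolate the contribution of the mating-structure feedback
  itself; it appears in the residual.
- The ASR interval excludes uncertainty in $\rho$, $k$ and $h$ by design.
- Inter-annual variation in asymptotic ASR is out of reach: the method
  assumes each population sits at its equilibrium structure.
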