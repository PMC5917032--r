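# asrdemog

Demographic analysis of adult sex ratio (ASR) variation in stage-structured
wild populations, built for mark-recapture studies of birds with flexible
parental care — the motivating system is *Charadrius* plovers, where closely
related populations range from strongly male-biased to female-biased ASRs and
from biparental care to routine desertion by either parent.

The package answers two questions a field demographer asks of such data:

1. **Where does ASR bias come from?** Sex biases can arise at hatching, during
   the juvenile year, or in adulthood. The package estimates each rate from
   individual data and decomposes the equilibrium ASR bias into the
   contribution of each one.
2. **What does ASR bias do to parental cooperation?** Across populations, the
   package regresses the proportion of biparentally tended families on ASR,
   propagating the uncertainty of both axes.

## The model

Population dynamics follow a two-sex post-breeding projection over the stage
vector **n** = (♀J, ♀A, ♂J, ♂A):

```
n_t = M(n_{t-1}) n_{t-1}

        ⎡   0        R♀(1−ρ)    0      R♂(1−ρ) ⎤
M(n) =  ⎢  φ♀J        φ♀A       0        0     ⎥
        ⎢   0        R♀ ρ       0      R♂ ρ    ⎥
        ⎣   0          0       φ♂J      φ♂A    ⎦
```

with annual apparent survival φ by sex and stage, hatching sex ratio ρ, and a
harmonic-mean mating function that makes the model nonlinear in the adult sex
composition:

```
R♀ = k n♂A / (n♂A + n♀A / h),   R♂ = k n♀A / (n♂A + n♀A / h)
```

where `k` is the modal clutch size and `h` the mating index (mean annual mates
per male; `h = 1` monogamy, `h < 1` polyandry, estimated as the inverse mean
annual mate rate of females, each floored at 1). ASR is read from the stable
stage distribution **w** reached after 1000 time steps:
`ASR = w♂A / (w♂A + w♀A)`.

Around this core the package provides:

- **`fit_cjs()` / `cjs_model_set()` / `select_best_model()`** —
  Cormack–Jolly–Seber maximum likelihood for sex- and stage-specific apparent
  survival (`φ ~ sex ∗ stage` throughout), AICc selection across all eight
  detection structures `p ~ {1, sex, year, stage, and their full
  interactions}`, plus a parametric-bootstrap dispersion diagnostic
  (`dispersion_check()`).
- **`estimate_hatching_sex_ratio()`** — binomial GLMM of chick sex with a
  brood random intercept; **`mating_system_index()`** — the mating index `h`.
- **`stable_structure()` / `equilibrium_oracle()`** — equilibrium ASR by
  simulation and, independently, by root finding on the two-sex fixed-point
  system (the pair agree to 1e-6 and cross-validate each other).
- **`bootstrap_asr()`** — the six-step bootstrap: resample histories, refit
  the CJS model set, select by AICc, rebuild the matrix, project, record ASR;
  survival correlations stay inside each replicate.
- **`ltre_contributions()`** — life table response experiment against a
  no-sex-difference null (both the female-referenced and male-referenced
  variants), with numerical spline sensitivities evaluated at midway
  parameters, `C(θ) = Δθ · ∂ASR/∂θ |_M′`.
- **`care_proportions()` / `bootstrap_care_regression()`** — family care
  categories with simultaneous multinomial CIs and the cross-population
  quadratic (cooperation) and exponential (uniparental care) bootstrap
  regressions.
- **`simulate_population()` / `truth_parameters()`** — a synthetic-data
  generator producing all four input tables under known vital rates, so every
  stage is testable by parameter recovery.
- **`run_pipeline()`** — the whole analysis from a config of per-population
  CSV paths, with deterministic per-stage child seeds and JSON stage reports.

## Worked example

Simulate a 7-year study of a male-biased population (juvenile survival 0.30 ♀
vs 0.50 ♂, adult survival 0.65/0.70, unbiased hatching, polyandrous `h =
0.85`), then run the full chain:

```r
library(asrdemog)
truth <- truth_parameters(
  phi_fj = 0.3, phi_mj = 0.5, phi_fa = 0.65, phi_ma = 0.7,
  p_detect = 0.6, rho = 0.5, brood_sd = 0.3, k = 3, h = 0.85,
  n_years = 7, n0 = 300, seed = 42)
study <- simulate_population(truth)
study
#> Synthetic study: 882 encounter histories, 900 chicks in 300 broods,
#>   150 mating records, 300 care records
#>   zero-detection histories censored: 318

fit <- select_best_model(lapply(cjs_model_set(), function(sp)
  fit_cjs(study$encounter_histories, sp, seed = 1)))
fit
#> CJS fit: phi~sex*stage, p~stage
#>   logL = -1256.336  K = 6  n_eff = 3468  AICc = 2524.696
#>   apparent survival:
#>         sex stage estimate     se
#> phi:F:J   F     J    0.261 0.0313
#> phi:M:J   M     J    0.470 0.0403
#> phi:F:A   F     A    0.661 0.0250
#> phi:M:A   M     A    0.708 0.0221
```

The fitted survival rates recover the generating values within their standard
errors. Assemble the two-sex model from the estimated inputs and derive ASR
with uncertainty:

```r
sv <- survival_parameters(fit)
params <- two_sex_params(sv$phi_fj, sv$phi_mj, sv$phi_fa, sv$phi_ma,
  rho = estimate_hatching_sex_ratio(study$hatch_records)$rho_hat,
  k = 3, h = mating_system_index(study$mating_records)$h)
stable_structure(params)
#> Stable stage structure (fJ, fA, mJ, mA):
#>   0.2720  0.1592  0.2613  0.3075
#>   growth rate: 1.1072   ASR: 0.6589

boot <- bootstrap_asr(study$encounter_histories,
  params_fixed = list(rho = params$rho, k = 3, h = params$h),
  B = 100, seed = 1)
sprintf("ASR = %.3f [%.3f, %.3f]", boot$mean, boot$ci_low, boot$ci_high)
#> "ASR = 0.647 [0.571, 0.742]"
```

The population is estimated ~65% male among adults. The LTRE attributes the
bias almost entirely to the juvenile-survival sex difference:

```r
ltre_contributions(params, "M0_female")
#> LTRE decomposition (M0_female null)
#>   ASR observed 0.6589, null 0.5000, deviation 0.1589
#>   C(phi_J) = +0.13537  (diff +0.2085 x sens +0.6492)
#>   C(phi_A) = +0.02812  (diff +0.0469 x sens +0.6000)
#>   C(h) = +0.00076  (diff -0.1620 x sens -0.0047)
#>   C(rho) = -0.00969  (diff -0.0100 x sens +0.9687)
#>   residual (higher-order terms): +0.00429
```

`C(phi_J)` is ~85% of the total deviation: the ASR bias was created during the
juvenile year, not at hatching (`C(rho)` ≈ −0.01) nor by the mating system.

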