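---
title: "Universal mammalian epigenetic clocks: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Universal mammalian epigenetic clocks: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uniclock)
```

## The modeling problem

A pan-mammalian epigenetic clock is a single linear model, fitted on CpG
methylation fractions (beta values), that estimates age in any mammalian
species. The obstacle is the outcome scale: a year means something very
different to a mouse (maximum lifespan ~4 years) and a bowhead whale
(~211 years). `uniclock` implements three outcome transformations that make
ages comparable across species, the penalized regression machinery around
them, and the cross-species meta-analysis used to map *all* age-related
CpGs rather than only the sparse set a clock selects.

## The three age transformations

All three transforms are strictly increasing in age and have closed-form
inverses (verified to 1e-9 years over age grids in the test suite); natural
logarithms are used throughout.

**Clock 1 (basic):** `y = log(Age + offset)` with `offset = 2` years, so
prenatal ages (negative, bounded below by gestation) stay in the log
domain. This clock ignores species traits entirely, which is exactly why it
is informative: trained species-blind, it underestimates the age of
long-lived species held out of training, and the package's `delta_age()`
statistic (the bias of leave-one-species-out estimates evaluated at half
the species' maximum lifespan) quantifies that lifespan-dependent bias.

**Clock 2 (relative age):**
`RelativeAge = (Age + GestationT) / (MaxLifespan + GestationT)` lies in
[0, 1]; the model outcome is the double-log transform
`-log(-log(RelativeAge))`, which maps the unit interval to the whole real
line and gives extra leverage to very young and very old samples. Gestation
time enters only to keep the numerator positive from conception onward.

**Clock 3 (log-linear adult age):**
`RelativeAdultAge = (Age + GestationT) / (ASM + GestationT)` is age in
units of the age at sexual maturity. The outcome is a change-point
transform, logarithmic below `m_hat` and linear above, with matching value
and derivative at the change point — encoding the faster tick rate of
methylation clocks during development. The change point would ideally be
proportional to each species' maximum relative adult age, but that requires
the (often poorly known) maximum lifespan; instead it is predicted from two
far better established traits through the allometric power law
`m_hat = c2 * (GestationT/ASM)^0.38` with `c2 = 5.0`. The exponent comes
from the cross-species ordinary-least-squares regression

```
log((MaxLifespan + GestationT)/(ASM + GestationT))
    ~ 2.92 + 0.38 * log(GestationT/ASM)
```

which `fit_allometric_surrogate()` reproduces; `c2` absorbs the intercept
(`c2 = c1 * exp(2.92)`, with the implied proportionality constant
`c1 ~ 0.2694` recorded but never used separately).

### Lifespan adjustment

Reported maximum lifespans are uncertain for almost every species except
humans and laboratory mice, whose records rest on billions and millions of
observed individuals. `adjust_max_lifespan()` therefore multiplies every
other species' reported maximum by 1.3 before relative age is computed; the
exempt set defaults to human and house mouse and is configurable. The
adjustment is applied exactly once (a second call is an error) and clock-2
transforms refuse unadjusted tables, so the convention is enforced at the
type level. Log-lifespan *ratios* (`log_lifespan_ratio()`), used to order
species by lifespan on a [0, 1] scale, intentionally use the reported,
unadjusted values: with the bowhead whale (211 y) as reference the human
value is `ln(122.5)/ln(211) = 0.90`, which is only reproduced without the
1.3 inflation. The ratio is invariant to the logarithm's base.

### Numerical choices

- Observed relative ages are clamped into `[eps, 1 - eps]` with
  `eps = 1e-6` before the double log, so animals recorded at or beyond
  their species maximum encode to finite outcomes. Model *predictions* are
  not clamped: the y-space is unconstrained, and the clock-2 inverse maps
  any finite prediction into `(-GestationT, MaxLifespan)`.
- For |y| large enough that `exp(-exp(-y))` underflows (|y| beyond roughly
  30), the inverse saturates at its mathematical bounds in double
  precision; tests assert strict monotonicity only where the double
  exponential is representable.
- All transforms are vectorized and bit-identical to elementwise
  evaluation.

## Clock training and prediction

`train_clock()` regresses the transformed age on beta values with the
elastic net (`glmnet::cv.glmnet`). Tunable parameters, with defaults and
rationale:

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.5 | elastic-net mixing; the pan-tissue-clock convention, half-way between ridge and lasso |
| `nfolds` | 10 | internal CV folds for the penalty path |
| penalty | `lambda.min` | minimum mean cross-validated error |
| `missing_max` | 0.2 | CpGs with more missingness are dropped; the rest are mean-imputed |
| `seed` | — | controls the internal fold split; training is deterministic given data and seed |

The original analyses name only the software, not these hyperparameters;
they are exposed as arguments and recorded in the model metadata.
Predictors enter on the raw beta scale (glmnet standardizes internally but
returns coefficients on the original scale; no standardization parameters
are stored). Training means of the selected CpGs are stored in the model so
prediction can impute CpGs that are missing — or absent outright — from a
new matrix. A constant outcome yields an intercept-only model rather than
an error. Models serialize to a directory of two CSVs plus a YAML sidecar
(`save_clock()`/`load_clock()`), with the `(Intercept)` row convention used
for published clocks and a format version that is checked on load.

`age_acceleration()` is the raw residual of DNAmAge on age — zero mean,
uncorrelated with age by construction — and `group_ageaccel_test()`
compares it between a control and an experimental group with a
pooled-variance t-test, reporting a positive sign when controls are
epigenetically older (the convention for anti-aging intervention studies).

## Cross-validation and evaluation

Two splits mirror how such clocks are validated:

- **LOFO** (`lofo_folds()`): ten fractions with similar proportions of
  species and tissues. Within each species-tissue stratum samples are
  shuffled under the global seed and dealt round-robin from a random
  starting fold, so per-stratum fold counts differ by at most one.
- **LOSO** (`loso_folds()`): one fold per species; measures transfer to
  species absent from training.

`run_crossval()` trains on each complement and predicts the held-out fold
(fold-specific seeds derived from the global one), and `evaluate()` reports
Pearson correlation and MAE overall, per species and per species-tissue
stratum, restricting per-stratum statistics and their medians to strata
with at least 15 samples. "MAE" is the *median* absolute error in years by
default (`mae_type = "mean"` is available). `delta_age()` evaluates each
species' fitted LOSO regression at half the maximum lifespan by default;
the per-sample mean discrepancy is available via `method = "mean"` because
the two readings of "mean discrepancy at half maximum lifespan" are both
defensible — the fitted-value form is the default as the more explicit
formula.

## Meta-EWAS of age

`stratum_correlations()` computes, per species-tissue stratum with at least
`min_n = 15` samples, the Pearson correlation of every CpG with age, and
converts it to a signed Z via the t statistic
`t = r * sqrt((n-2)/(1-r^2))`, its two-sided p, and the signed normal
quantile (`correlation_to_z()`). This is the conventional route for feeding
correlation tests into Stouffer combination; Fisher's
`atanh(r) * sqrt(n-3)` is available as an alternative. |Z| is capped at 37,
the practical double-precision limit of the normal quantile, so perfect
correlations stay finite. Zero-variance CpGs get Z = 0 with a flag rather
than NaN.

`two_step_meta()` combines Z statistics with the unweighted Stouffer method
(`sum(z)/sqrt(k)`) twice: tissues within each species first, then across
species. The two steps matter: with species A contributing tissue Zs (2, 2)
and species B contributing (0), the two-step result is 2.0 while naive
pooling gives `4/sqrt(3) ~ 2.31` — the correction prevents species sampled
in many tissues from dominating. When every species has one stratum the
two reduce to the same answer, which is how `single_tissue_meta()` handles
single-tissue analyses. Raw p (two-sided normal) and Benjamini-Hochberg q
are reported; no multiplicity correction is baked into the Z statistics,
and any descriptive significance cutoff is left to the caller.

Small strata can be pooled *before* thresholding through an explicit
pooling map (species to pooled label, optionally merging tissues), the
mechanism used in practice for taxa sampled a few animals per species (many
lemur species pooled into one strepsirrhine stratum per tissue; monotremes
pooled across species and tissues). The threshold applies after pooling.
The conventional relaxed threshold `min_n = 10` is used for sparsely
sampled groups and for age-group analyses.

`age_group_split()` partitions samples at 1.5 and 3.5 times the species
ASM (young / middle / old; both boundaries belong to the older group),
enabling the check that age-related methylation is not purely a
developmental phenomenon. `top_k_cpgs()` selects the k strongest CpGs of a
given sign, ordered by |Z| with lexicographic tie-breaks for deterministic
output, and `hypergeometric_enrichment()` tests such lists against
annotation sets (PRC2-binding regions, chromatin states, interval sets
resolved against an array manifest via `resolve_intervals()`) with the
one-sided exact hypergeometric test in both tails. The odds ratio uses the
Haldane 0.5 correction only when a cell of the 2x2 table is zero; p values
always come from the uncorrected exact table.

## The synthetic-data generator

`sim_design()` / `simulate_traits()` / `simulate_methylomes()` generate the
package's validation surface: a many-species, multi-tissue beta matrix with
a known planted age signal. What it emulates, and how the defaults were
chosen:

- **Traits.** ASM is log-uniform on [0.1, 10] years; gestation is a
  uniform 2-30% of ASM; maximum lifespan follows the allometric relation
  above with log-normal noise (`trait_noise_sd = 0.5`, chosen so the two
  log variables of the allometric regression correlate moderately, near
  0.5, as real mammalian traits do). With zero trait noise the allometric
  fit recovers (2.92, 0.38) exactly, which ties the generator and the
  estimator to the same relation.
- **Ages** are uniform from 0 to 90% of the reported species maximum,
  spanning development to near end of life.
- **Signal.** Planted CpGs follow
  `logit(beta) = b0 + s * loglogAge + t_ct + e`, with the signal on the
  clock-2 (double-log relative age) scale. This makes clock 2 well
  specified while clocks 1 and 3 are informatively misspecified — which is
  what lets the simulation reproduce the lifespan-dependent bias of the
  species-blind basic clock in the Delta.Age direction check. Slopes are
  drawn from 0.5-1.5 logit units per unit of transformed age (mirrored
  negative for the loss set), baselines from N(0, 1.5), per-CpG-per-tissue
  offsets from N(0, 0.25), and observation noise from N(0, 0.5) — values in
  the range seen on methylation arrays, chosen once.
- **Boundedness.** The inverse logit keeps betas strictly inside (0, 1).
- **Determinism.** One seed governs everything; purpose-specific sub-seeds
  (traits / ages / betas) mean enlarging the CpG panel never perturbs the
  trait draws. Identical design + seed gives identical bytes, which the
  fixture tests check.

The default design (20 species x 3 tissues x 20 samples, 2,000 CpGs,
100 + 100 planted) is the study-scale condition used by the heavier tests
and the acceptance script; problem sizes were chosen so the whole
validation suite runs in minutes on a single CPU. `make_fixture()` writes
three canonical bundles: `tiny` (3 x 2 x 16, 200 CpGs) for fast tests,
`default`, and `null` (no planted signal) for type-I calibration.

What the generator does **not** emulate: probe-level array chemistry and
measurement error structure, batch and study effects, taxon-specific probe
dropout (e.g. the sparser marsupial mappings), non-uniform age sampling,
within-species trait variation, and correlation between CpGs beyond the
shared age signal. Passing tests therefore demonstrate that the estimators
recover the signal they target under a clean generative model — not that
real consortium-scale accuracies will be attained on any particular
dataset.

## Design decisions that were genuinely open

- **r-to-Z rule.** The conversion behind the meta-analysis is not uniquely
  determined by convention; the t-statistic route is the default and
  Fisher's z is provided, since the two differ negligibly at the stratum
  sizes involved.
- **Pooling versus thresholding order.** The stratum-size threshold is
  applied *after* pooling small strata, which is the only order under which
  pooling a few-samples-per-species taxon can rescue it for analysis.
- **Delta.Age operationalization** (fitted value at half maximum lifespan
  versus mean discrepancy): both implemented, fitted-value default.
- **MAE as median.** The evaluation reports median absolute error as MAE,
  the convention for clock accuracy summaries; the mean is a flag away.
- **Exact p values for enrichment.** The hypergeometric tails are exact and
  therefore discrete and super-uniform under the null; calibration checks
  in the tests use the mid-p correction, the standard device for discrete
  tests, rather than pretending the raw p values are continuous-uniform.

## Limitations

- Normalization of raw array data (IDATs) is out of scope; the package
  consumes normalized beta matrices.
- Trait tables are strict: species missing a trait are excluded from
  operations needing it (with a warning), never imputed.
- The clamp parameter, lifespan multiplier, exempt set, thresholds and all
  trainer hyperparameters are exposed, but their defaults are the
  conventions described above; changing them changes the clocks.
- Leave-one-species-out transfer in simulation is optimistic relative to
  real data because the planted signal is perfectly shared across species.
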