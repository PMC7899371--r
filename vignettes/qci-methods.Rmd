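---
title: "Constructing a Quality of Care Index from burden panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing a Quality of Care Index from burden panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcindex)
```

## The model

`qcindex` builds a disease-specific, 0–100 composite index of care quality
from six primary epidemiologic measures (incidence, prevalence, deaths,
DALY, YLL, YLD), reported per country, year, sex and age group as counts
and rates per 100,000 with 95% uncertainty intervals. The construction has
four steps.

**1. Secondary ratios.** Per stratum, four dimensionless ratios:
mortality-to-incidence (MIR = deaths/incidence), DALY-to-prevalence,
prevalence-to-incidence, and YLL-to-YLD. Each is an indirect probe of the
same thing — how well a health system converts disease burden into
survival and function. MIR is the classic population-level survival proxy;
prevalence-to-incidence approximates mean disease duration and therefore
rises with good care; the two burden ratios fall as care prevents fatal
and disabling outcomes. The intended inputs are both-sex,
age-standardized rates, so that demographic structure does not leak into
the index; the ratios being dimensionless, pooled counts are also valid
inputs (used for coarse age groups, below).

**2. Standardization.** Each ratio is z-scored against the reference set:
ζ_j = (x_j − μ_j)/σ_j with μ, σ the sample mean and SD over reference
strata. z-scores are unbounded; no ±1 clamp is applied or assumed.

**3. First principal component.** The loading vector is the unit-norm
first eigenvector of the 4×4 correlation matrix of the ratios
(equivalently, PCA on ζ). Because the four ratios are strongly mutually
correlated, the first component captures most of the variance and its
loadings come out near ±0.5 each. An explicit **orientation** step then
fixes the sign indeterminacy of eigenvectors: the oriented score must
anticorrelate with MIR on the reference set, so that a higher score always
means better care. A fixed-coefficient mode
(`published_loadings()`, `fixed_coefficient_score()`) evaluates the
published loading vector (0.5003587, 0.5007964, 0.5002090, −0.4986332)
verbatim instead of fitting; its squared norm is 1 to within 5e-6, which
is why we treat it as a unit-norm eigenvector and apply the same
orientation machinery downstream (the published weights give MIR a
positive coefficient, so the orientation there is −1). All four ratios
enter standardized in this mode as well — we read the one unstandardized
term in the published formula as notational shorthand, since mixing a raw
ratio on the order of 0.5 with z-scores would make its weight meaningless.

**4. Min–max rescaling.** QCI = 100·(s − s_min)/(s_max − s_min), with the
bounds taken over the reference set, so the best reference stratum scores
exactly 100 and the worst exactly 0. Strata scored *outside* the reference
set (sexes, age groups, out-of-sample years) reuse the reference μ, σ,
loadings and bounds unchanged and are clipped to [0, 100]. This keeps every
subgroup on one shared scale — a requirement for the gender ratio and age
comparisons to be meaningful — at the price that extreme subgroups can
saturate at 0 or 100.

**Reference set.** By default the model is fitted on both-sex,
age-standardized country-year strata across the full requested year span.
Fitting across years (rather than per year) is a deliberate choice: a
single shared min–max scale is the only way a country can be compared
against its own past, and it is consistent with reporting one country at
100 in the final year alongside sub-100 global values in the first. The
reference description is stored in the fitted `qci_model` and the choice
is configurable.

## Disparity analytics

**Gender Disparity Ratio.** GDR = QCI_female / QCI_male per (location,
year, age group), both sexes scored under the both-sex reference model.
GDR = 1 is parity; values below 1 indicate male-favoring care. A male QCI
of exactly 0 makes the ratio undefined: such strata raise an explicit
condition (scalar API) or are dropped with a report (table API), never
silently imputed. A female QCI of 0 yields GDR = 0, which is reported
as-is. Outliers are flagged by a leave-one-out rule — a value is flagged
when it lies more than k = 3 SDs from the mean of the *other* values —
two-sided, and flags only annotate: flagged strata stay in every
downstream aggregate.

**Age groups.** Fine 5-year bands pool into childhood (< 20 years),
adulthood (20–65) and elderly (> 65). A band is assigned by its lower
bound, so 65–69 counts as elderly; with the conventional 5-year grid no
band straddles a boundary under this rule. The cuts are parameterizable
(`age_group_scheme()`), accommodating the alternative 18-year childhood
boundary some reports use. Pooling is ratio-of-sums on counts — summing
numerators and denominators before dividing — because ratios of pooled
counts are the epidemiologically coherent aggregate, whereas averaging
band-level ratios would weight tiny and huge bands equally.

**SDI quintiles.** Equal-count rank-based quintiles (low … high), ties
broken by location identifier for determinism. Group summaries of QCI are
weighted means, with prevalence counts as the default weight (configurable),
since no canonical aggregation of national indices to regions exists.

## Significance and standardization conventions

Two estimates are called significantly different when their 95%
uncertainty intervals do not overlap. Closed intervals touching at a
single endpoint are treated as overlapping — i.e. *not* significant — the
conservative reading; on the bundled published global table
(`cns_global_burden()`) the resulting pattern is insensitive to this
convention. Direct age-standardization uses Σ_a w_a · (count_a/pop_a) ·
1e5 against a bundled GBD-style world standard population
(`world_standard_population()`); any weight vector summing to 1 (within
1e-9) is accepted, so analyses can substitute their own standard.

## The synthetic generator

Real GBD extractions cannot be redistributed, so the package ships a
seeded generator whose defaults define the study conditions used
throughout the tests: 100 countries, years 1990–2017, twenty 5-year age
bands (0–4 … 95+).

Per country: SDI ~ Uniform(0.2, 0.95); latent care quality
q = 1.0·SDI + N(0, 0.05²), floored at 0.01 (with slope 1 and small noise
the SDI–quality rank correlation is high by construction, and the floor
keeps the multiplicative sex offset order-preserving). The gender gap is a
log-scale offset δ = −0.30 + 0.33·SDI, with female quality q·exp(δ/2) and
male q·exp(−δ/2): care is male-favoring at low SDI (δ ≈ −0.23) and near
parity at the top (δ ≈ +0.01), the qualitative pattern reported for this
disease family. Burden follows the causal chain: incidence from a
5-per-100k baseline times an age profile (a shallow childhood peak, a dip
in adolescence, a rise into old age — the canonical CNS-cancer shape);
MIR(q) = plogis(1.73 − 3.47·q), spanning roughly 0.75 down to 0.17 across
the SDI range — bracketing realistic global values; survival years
1.0 + 6.0·q (so prevalence ≥ incidence always); YLL = deaths × residual
life expectancy per band (a GBD-style reference life table); YLD =
prevalence × disability weight 0.12.

Mean-one multiplicative lognormal noise (CV 0.08, roughly the relative
uncertainty scale of such estimates) is applied per measure, country,
year, sex and band — but **DALY is always the exact post-noise sum
YLL + YLD** at every aggregation level, so the accounting identity is a
hard (bit-exact) test, not a tolerance test. Uncertainty intervals are
symmetric ±15% multiplicative bands — a simplification; real UIs come from
posterior draws and are asymmetric. Population pyramids are a fixed
exponential template; country totals are lognormal.

What the generator does *not* emulate: year trends in quality or
incidence, age- or sex-specific latent quality beyond the single gender
offset, correlated (rather than independent) measure noise, asymmetric
uncertainty, missing data, or any calibration to real GBD marginals.
Passing the recovery tests therefore shows the pipeline inverts the
generative structure it targets — monotone links, a dominant shared
component, an SDI-dependent gender gap — not that it would be unbiased on
real registry data.

Companion outputs for validity analysis: a HAQ-like reference index
(affine in latent quality plus N(0, 0.05) noise, min–max rescaled 0–100)
and inpatient/outpatient utilization covariates (log-linear in SDI,
lognormal noise). All generator outputs are exact functions of the
configuration seed; sub-stages use fixed small offsets of it.

## The validity model

The validity harness fits QCI ~ inpatient utilization + outpatient
utilization + deaths rate + prevalence rate with a country random
intercept, by REML via `lme4::lmer()` — the established estimator; the
package's contribution is the harness and its recovery tests, not a
solver. The headline validity number is kept separate, as the simple
Pearson correlation between QCI and the reference index on the
complete-case join. Constant or collinear covariates are rejected up front
(rank check on the fixed-effects design) rather than surfacing as cryptic
fit failures.

## Numerical choices and degenerate inputs

- Eigendecomposition via `eigen(symmetric = TRUE)` on the 4×4 correlation
  matrix; the test suite cross-checks the loadings against an independent
  SVD-based PCA (`prcomp`) to 1e-8, up to sign.
- Unit loading norm is asserted to 1e-9; standard-population weights must
  sum to 1 within 1e-9.
- Zero-denominator strata (incidence, prevalence or YLD equal to 0) are
  excluded from ratio computation with a warning and an `excluded`
  attribute listing them — never a silent NaN, never imputed.
- A constant ratio column, fewer than 5 reference strata, or a degenerate
  (zero-width) score range each raise a typed error.
- Quintile ties break by location id; CSV output preserves full double
  precision (shortest round-trip representation), making pipeline runs
  byte-reproducible for a fixed configuration.

## Problem sizes in the test suite

Unit tests run on a 20-country × 6-year world; the end-to-end recovery
tests use the full default conditions (100 countries × 28 years, one
seed); the mixed-model recovery study uses 20 replicates of 50 countries ×
10 years with known slope 0.5 and unit variances. These sizes are the
package's chosen validation conditions and are large enough that the
stochastic assertions (rank correlation ≥ 0.9, CI coverage ≥ 18/20) are
stable across seeds.

## Known limitations

QCI is relative: it is anchored to its reference set, so values are not
comparable across diseases or across differently chosen reference sets.
Subgroup clipping can censor genuinely extreme strata at 0 or 100, which
in turn makes the GDR saturate there. The index inherits every bias of the
underlying burden estimation (lead-time bias where screening differs,
modeled data where registries are absent), and the synthetic recovery
results quantify internal consistency, not real-world validity — the
external-data correlation analysis requires datasets this package does not
ship.
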