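---
title: "Methods: classifying pro-longevity, antilongevity and role-switching biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying pro-longevity, antilongevity and role-switching biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agemarkers)
```

## The problem

A *biomarker of aging* is a measurable feature that predicts later
functional capacity — here, life expectancy — better than chronological age
does. Longitudinal studies of inbred strains make this testable without
sacrificing the prediction target: features are measured per strain at fixed
age groups (6, 12, 18, optionally 20, and 24 months), while life expectancy
is estimated independently per strain and sex. Because all animals of an
inbred strain are genetically near-identical, the strain-level life
expectancy can be merged onto every phenotype record of that strain.

Two lines of evidence then exist for every feature, and they concern
*different spans of life*:

* **Prognostic evidence** (early effects): at each measurement age, the
  Pearson correlation between the feature value and strain life expectancy.
  A positive correlation means high values predict a long lifespan.
* **Longitudinal evidence** (late effects): the feature's within-study trend
  over age. A trend alone only marks a *biomarker of age*; it becomes
  evidence about *aging* when the literature records a matching effect —
  a beneficial effect for a declining feature, a deleterious effect for a
  rising one.

When the two channels agree, the feature is a clear-cut **pro-longevity** or
**antilongevity** biomarker. When they conflict — e.g. high values predict a
*short* lifespan early, while the validated longitudinal pattern is
protective late — the conflict is resolved by positing a **role switch**:
the feature's early effect direction is opposite to its late one. A role
switch can also appear within the prognostic channel alone, as a sign
change of the relevant correlations across age groups.

## The procedure, stage by stage

### Longitudinal trends

Per feature and sex (sexes are a hard stratum; nothing is ever pooled across
them), values are standardized to mean 0 and sample SD 1 over all age
groups jointly, then regressed on age in raw months by ordinary least
squares. The slope's two-sided t-test decides the call: `down`/`up` when
p < α (default 0.05), else `none`. Because the response has unit SD, the
slope m converts exactly to the Pearson correlation with age via
r = m · s_age, with s_age the sample SD of the ages; the package verifies
this identity against a direct correlation oracle to 1e-10. Standardizing
per feature × sex over all ages jointly is what makes the identity hold;
the trend fit is invariant to affine rescaling of the raw feature.

### Prognostic screening

Per feature, sex and age group, the Pearson correlation between feature
value and merged strain life expectancy is computed over individual records
(each record carries its strain-level lifespan), with pairwise-complete
deletion and the effective n reported. A cell is **relevant** iff
|r| ≥ r_min and p < α (defaults 0.2 and 0.05). Old-age evidence (18, 20,
24 M) is the most volatile — only a fraction of strains survives to
contribute — so a relevant cell at a volatile age is kept only if (a) a
non-volatile age is relevant with the same sign, or (b) at least two
volatile ages are relevant with the same sign. Clause (b) is this package's
choice (configurable off): consistent late-life evidence should not be
discarded wholesale.

### Cox cross-check

As an alternative prognostic statistic, a Cox proportional-hazards model is
fit per feature × sex × age group with life expectancy as the time,
all lifespans treated as observed events (a strain life expectancy is a
summary, not censored follow-up; the censoring flag exists for generality),
and the standardized feature as covariate. Standardizing the covariate is an
assumption adopted for cross-feature comparability and flagged as such.
All animals of a strain share one lifespan, so ties are
heavy: Efron's correction is the default, Breslow available by flag.
Displayed coefficients are negated (`display_sign = -coefficient`) so a
hazard-decreasing ("good") feature points the same way as a positive
lifespan correlation; the sign-concordance of the two channels is itself an
acceptance test. Monotone likelihoods (a feature that perfectly ranks
lifespan) are flagged and capped rather than reported as divergent.
No strain-level frailty or clustered variance is attempted — plain Cox, as
an extension point.

### Classification rules

For each feature (sexes are classified jointly into one call, with sex
qualifiers — matching the one-row-per-feature result layout):

1. Relevant prognostic cells of **both signs** (after the volatile filter,
   pooled over sexes) → `role_switching`, basis `prognostic_switch`. The
   early class comes from the sign at the earliest relevant age, the late
   class from the latest. If both signs occur at the same age (a pure sex
   conflict, not seen in practice), earliest/latest still anchor the call.
2. Otherwise the prognostic class (all-positive → pro-longevity,
   all-negative → antilongevity) is compared with the validated
   longitudinal class (down + beneficial late effect → pro-longevity,
   up + deleterious → antilongevity). Agreement → that class, basis
   `corroborative`. Disagreement → `role_switching`, basis
   `conflicting_resolved`: the early class from the prognosis (its earliest
   relevant age is the natural early anchor), the late class from the
   validated trend.
3. Only one channel defined → that class, basis `prognostic_only` /
   `longitudinal_only`, flagged provisional.
4. A significant trend with no validating effect and no prognosis →
   `age_only` (the feature tracks time, not aging); nothing at all →
   `unclassified`.

Qualifiers: "pronounced in *sex*" when relevant evidence sits in exactly
one sex, or in both with a maximal-|r| margin ≥ 0.15 (the margin is a
package-level choice with no field-standard value, and is configurable);
"pronounced at *a* M" when exactly one age group carries the deciding
direction's relevant evidence (skipped for prognostic switches, which have
no single deciding direction). If the significant sexes disagree on trend
direction, the longitudinal channel is treated as undefined for that
feature rather than picking a side.

The protocol leaves edge cases that the rules above must decide: how
evidence is aggregated across sexes, which age anchors an early class, and
what happens when exactly one channel is defined. The choices here
(earliest-relevant-age anchoring, joint per-feature sex call, clause (b)
of the volatile filter, the qualifier margin) are deliberate, explicit and
configurable.

### Stratified re-analysis

Short-lived strains die of specific genetic disease predispositions, which
could bias biomarker detection. `exclude_strains()` re-runs the pipeline
without them (the designation is an input list; `flag_short_lived()` offers
a lifespan-quantile stand-in). `compare_trends()` asks whether short-lived
strains age "twice as fast": the feature is standardized once per sex, a
reference slope is fit on the pooled longer-lived strains, and each
short-lived strain's own slope is categorized as `concordant`, `faster`
(same sign, ≥ 2× the reference, and ≥ 1.96 pooled SEs apart), `opposite`
(signs differ, both individually significant) or `indeterminate`. The
comparison statistic is this package's operationalization of "twice as
fast" / "opposite trend" and is fully threshold-configurable;
pooled-reference (rather than pairwise strain-vs-strain) comparison is
likewise a design choice.

## The synthetic cohort generator

`generate_cohort()` states a world with the structure the analysis assumes:
30 strains (6 of them short-lived, capped at 18 months, optionally with
dropout of records past the strain's life expectancy), 8 animals per strain
and sex, age groups 6/12/18/24 M, strain lifespans ~ N(26, 5²) months
truncated above the short-lived cap. A feature value is

value(age) = trend_slope · age + b(age) · z_lifespan + ε,   ε ~ N(0, σ²)

where z_lifespan is the strain's standardized life expectancy (the
prognostic signal can only be strain-mediated, mirroring the record-wise
merge) and b(age) = r(age)·σ/√(1 − r(age)²) is the closed form that gives
the target correlation r(age). Role switches are parameterized by
age-varying r, not separate features. Because only ~30 independent lifespans
exist, the *realized* correlation would fluctuate around the target with an
SD near 0.1; the generator therefore orthogonalizes the noise against
z_lifespan within each age group (and rescales it to the nominal σ), making
the planted correlation exact to ~1% while leaving trend variability — and
hence the null calibration of the trend t-test — intact. A planted-truth
table applies the very same rule semantics to the noiseless parameters.

What the generator does **not** emulate: real phenotype marginals (units,
skew, floor effects), within-animal serial correlation, measurement batch
structure, or informative missingness. A green recovery test therefore
establishes that the pipeline's statistics and rules recover the planted
correlation/trend structure — not that they would be robust to those
real-data complications.

## Numerical choices and degenerate inputs

* Missing values are first-class: no imputation anywhere; every stage does
  pairwise-complete (Cox multivariate: listwise) deletion and reports n.
* Constant features raise a degenerate-feature error in `standardize()`;
  screening wrappers exclude and log them instead of failing the run.
  Degenerate prognostic cells (constant lifespan or feature) are returned
  flagged, never silently zero.
* Lifespans are months throughout; readers convert days by /30.44. Whether
  a strain's life expectancy is a mean or median is left agnostic.
* Feature ordering ties are broken lexicographically; chart delimiters
  count significant down-trends and non-up-trends from the left.
* The slope→r conversion clamps to [−1, 1] only to absorb floating-point
  overshoot in the perfectly collinear limit.
* Seeds: one integer seed determines the whole cohort byte-for-byte.

## Worked example

The packaged encoding of the canonical 12-feature panel (blood counts,
serum chemistry, body phenotypes) reproduces the reference classification:

```{r}
cl <- classify_features(example_panel_bundles())
cl[, c("feature", "overall", "basis", "qualifiers")]
sum(cl$basis == "corroborative")          # 7 clear-cut features
sum(cl$overall == "role_switching")       # 5 role-switching features
```

The magnitudes in that encoding are illustrative stand-ins (the underlying
measurements are external); directions, relative strengths and qualifier
patterns are faithful, and the engine consumes only those.

## Known limitations

* Effects are supplied as an annotation table; no literature mining.
* Plain linear regression and plain Cox: no mixed effects, no frailty.
* The acceptance targets are counts on the packaged worked example; the
  underlying raw measurements are external and not reproduced here.
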