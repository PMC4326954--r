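# agemarkers

Classification of longitudinal phenotype features into **pro-longevity**,
**antilongevity** and **role-switching** biomarkers of aging.

## The problem

Longitudinal studies of inbred mouse strains measure phenotypes (blood
counts, leucocyte subsets, serum chemistry, body composition, …) at fixed
age groups (6, 12, 18, 20, 24 months), while strain life expectancy is
estimated in a separate study. Because inbred animals are genetically
near-identical, the strain × sex life expectancy can be merged onto every
phenotype record, giving two independent lines of evidence per feature:

* **prognostic** (early effects): per age group, the Pearson correlation
  r between feature value and life expectancy, *relevant* iff |r| ≥ 0.2
  and p < 0.05;
* **longitudinal** (late effects): the OLS slope m of the standardized
  feature on age (equivalently the correlation with age, r = m·s_age),
  significant by a two-sided t-test at α = 0.05, and *validated* as
  aging-relevant only when the literature records a matching effect
  (beneficial for a downtrend, deleterious for an uptrend).

Corroborating evidence gives a clear-cut class; conflicting evidence is
resolved as a **role switch** (e.g. antilongevity early, pro-longevity
late), as is a sign switch of the relevant correlations across age groups.
Univariate/multivariate Cox proportional-hazards fits (Efron ties, inverted
display sign) cross-check the correlation channel, and a stratified re-run
excluding short-lived, disease-truncated strains probes robustness. A
synthetic cohort generator with planted trends, planted per-age prognostic
correlations and a planted-truth table makes every stage testable offline.

## Worked example

```r
library(agemarkers)
cl <- classify_features(example_panel_bundles())
cl[, c("feature", "overall", "basis", "qualifiers")]
```

```
   feature        overall                basis           qualifiers
1   Bcells  pro_longevity        corroborative pronounced in female
2      BMI role_switching conflicting_resolved    pronounced at 6 M
3      CHr role_switching conflicting_resolved   pronounced at 12 M
4       Fe role_switching conflicting_resolved   pronounced at 12 M
5      HCT  pro_longevity        corroborative   pronounced in male
6      HGB  pro_longevity        corroborative   pronounced in male
7       HR role_switching conflicting_resolved    pronounced at 6 M
8    LYMPH  pro_longevity        corroborative pronounced in female
9       Mg  pro_longevity        corroborative   pronounced at 12 M
10    NEUT  antilongevity        corroborative                     
11     RBC  pro_longevity        corroborative   pronounced in male
12      T4 role_switching    prognostic_switch                     
```

Seven features are clear-cut (six pro-longevity — B cells, lymphocytes, red
cells, haemoglobin, hematocrit, magnesium — and one antilongevity,
neutrophils); five are role-switching (iron and CHr, thyroxine — the one
feature whose prognosis itself switches sign from 6 M to 12/18 M — BMI and
heart rate, all antilongevity early / pro-longevity late).

End-to-end on a synthetic cohort:

```r
res <- run_pipeline(system.file("extdata", "example_config.yaml",
                                package = "agemarkers"),
                    out_dir = "agemarkers_out")
res$classification          # one overall class per feature
res$truth                   # the planted classes it should recover
res$comparison              # short-lived vs longer-lived trend categories
```

which writes `trends.csv`, `prognostic.csv`, `cox.csv`,
`classification.csv`, `classification_longerlived.csv`, `comparison.csv`,
`planted_truth.csv`, `chartspec.json` and `manifest.json`. The same run is
available from the shell:

```sh
Rscript inst/cli/agemarkers run --config inst/extdata/example_config.yaml --out out/
```

## Package map

| Module | Contents |
| --- | --- |
| `R/data_model.R` | CSV readers/writers, lifespan merge, derived absolute counts |
| `R/synthetic_data.R` | `cohort_config()`, `generate_cohort()`, `planted_truth()` |
| `R/trends.R` | `standardize()`, `fit_trend()`, `slope_to_correlation()`, `order_features()` |
| `R/prognostic.R` | `correlate_lifespan()`, `cox_univariate()`, `cox_multivariate()` |
| `R/classify.R` | volatile-age filter, validation, `classify_features()`, qualifiers |
| `R/stratify.R` | `exclude_strains()`, `compare_trends()` |
| `R/pipeline.R` | `run_pipeline()`, `build_chart_spec()` |

See `vignettes/biomarker-classification-methods.Rmd` for the model,
assumptions, tunables and limitations.
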