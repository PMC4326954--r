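Package: agemarkers
Title: Classification of Longitudinal Phenotype Features into Pro-Longevity,
    Antilongevity and Role-Switching Biomarkers of Aging
Version: 0.1.0
Authors@R: person("agemarkers", "maintainers", email = "agemarkers@example.org",
    role = c("aut", "cre"))
Description: A pipeline for classifying longitudinal phenotype features of
    inbred mouse strains (or any strain/breed-structured cohort with
    strain-level life expectancy) into pro-longevity, antilongevity and
    role-switching biomarkers of aging. Combines per-sex longitudinal trend
    detection by simple linear regression on standardized values, per-age-group
    prognostic screening by Pearson correlation against strain life expectancy
    with a relevance gate, univariate and multivariate Cox proportional-hazards
    cross-checks, literature-effect validation, and a rule-based evidence
    integration engine that resolves conflicting early/late evidence as a role
    switch. Ships a synthetic cohort generator with planted trends and
    prognostic correlations so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
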