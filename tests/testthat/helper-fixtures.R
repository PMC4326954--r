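# shared fixture builders and independent oracles (built in code, no files)

# minimal wide phenotype table: one feature column per entry of `values`
make_table <- function(strain, sex, age, values) {
  df <- data.frame(animal_id = sprintf("a%d", seq_along(strain)),
                   strain = strain, sex = sex, age_months = age,
                   stringsAsFactors = FALSE)
  for (nm in names(values)) df[[nm]] <- values[[nm]]
  phenotype_table(df, features = names(values))
}

tiny_lifespans <- function(strains, sexes = "female",
                           life = seq(20, by = 4, length.out = length(strains))) {
  expand <- expand.grid(strain = strains, sex = sexes,
                        stringsAsFactors = FALSE)
  expand$life_expectancy <- rep(life, times = length(sexes))
  expand$event_observed <- TRUE
  expand
}

small_config <- function(seed = 1, features = default_feature_panel(),
                         n_strains = 12, n_animals = 4, dropout = FALSE) {
  cohort_config(n_strains = n_strains,
                n_animals_per_strain_sex = n_animals,
                short_lived = list(n_strains = 3, lifespan_cap = 18,
                                   dropout = dropout),
                features = features, seed = seed)
}

# independent Cox oracle: hand-coded partial likelihood (tie-free data),
# maximized by grid/golden-section search, never by survival::coxph
oracle_partial_loglik <- function(beta, z, time) {
  ord <- order(time)
  z <- z[ord]; time <- time[ord]
  sum(vapply(seq_along(time), function(i) {
    beta * z[i] - log(sum(exp(beta * z[time >= time[i]])))
  }, numeric(1)))
}

oracle_cox_coef <- function(z, time, interval = c(-10, 10)) {
  optimize(function(b) -oracle_partial_loglik(b, z, time),
           interval = interval, tol = 1e-9)$minimum
}

# one-sign-only cell frame for classifier tests
make_cells <- function(feature, sex, ages, r, p = 1e-3) {
  data.frame(feature = feature, sex = sex, age_group = ages,
             pearson_r = r, p_value = p, n = 50,
             relevant = abs(r) >= 0.2 & p < 0.05, degenerate = FALSE,
             stringsAsFactors = FALSE)
}

make_trend <- function(feature, sex, slope, p = 1e-4) {
  data.frame(feature = feature, sex = sex, slope_m = slope, p_value = p,
             r_longitudinal = sign(slope), n = 100,
             trend_call = ifelse(p >= 0.05, "none",
                                 ifelse(slope < 0, "down", "up")),
             stringsAsFactors = FALSE)
}

make_annotation <- function(feature, early, late, label = "") {
  annotation_table(data.frame(feature_name = feature, early_effect = early,
                              late_effect = late, label = label,
                              source = "test", stringsAsFactors = FALSE))
}
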