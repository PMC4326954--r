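# Synthetic cohort generator -------------------------------------------------
#
# Emulates the statistical structure the pipeline assumes: ~30 inbred
# strains with strain-level mean lifespans (including a short-lived,
# disease-truncated subset), sexes generated separately, discrete
# measurement age groups, features with planted linear age trends and
# planted per-age-group correlations with strain lifespan (sign switches
# across ages allowed), and i.i.d. Gaussian animal-level noise.  The
# prognostic signal enters through the strain's standardized lifespan: the
# generated value at age a is
#     value = trend_slope * a + b(a) * z_lifespan + noise,
# with b(a) = r(a) * noise_sd / sqrt(1 - r(a)^2), the closed form that makes
# the population correlation of value with lifespan at age a equal r(a).

#' Specify a synthetic feature
#'
#' @param name feature name
#' @param trend_slope planted longitudinal slope (standardized units per
#'   month)
#' @param prognostic_r named numeric vector, target correlation of the
#'   feature with strain lifespan per age group (names are ages in months);
#'   unnamed scalars are recycled to all configured age groups. `|r|` must
#'   be < 1.
#' @param noise_sd animal-level Gaussian noise SD (> 0)
#' @param early_effect,late_effect literature effect valence
#'   (`beneficial`/`deleterious`/`unknown`)
#' @param label,source free-text annotation fields
#' @param sex_modifier optional named list of per-sex multipliers applied to
#'   both the slope and the prognostic correlations, e.g.
#'   `list(female = 1, male = 0.5)`
#' @return a `feature_spec` list
#' @export
feature_spec <- function(name, trend_slope = 0, prognostic_r = 0,
                         noise_sd = 1, early_effect = "unknown",
                         late_effect = "unknown", label = "", source = "",
                         sex_modifier = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  if (noise_sd <= 0) {
    am_stop(sprintf("feature '%s': noise_sd must be > 0", name),
            class = "agemarkers_config_error")
  }
  if (any(abs(prognostic_r) >= 1)) {
    am_stop(sprintf("feature '%s': |prognostic_r| must be < 1", name),
            class = "agemarkers_config_error")
  }
  stopifnot(early_effect %in% EFFECTS, late_effect %in% EFFECTS)
  structure(list(name = name, trend_slope = trend_slope,
                 prognostic_r = prognostic_r, noise_sd = noise_sd,
                 early_effect = early_effect, late_effect = late_effect,
                 label = label, source = source,
                 sex_modifier = sex_modifier),
            class = "feature_spec")
}

#' Configure a synthetic cohort
#'
#' Defaults state the world the pipeline targets: 30 strains, 8 animals per
#' strain and sex, age groups 6/12/18/24 months, strain mean lifespans
#' around 26 +/- 5 months with a 6-strain short-lived subset capped at 18
#' months.
#'
#' @param n_strains number of strains
#' @param n_animals_per_strain_sex animals per strain per sex
#' @param age_groups strictly increasing measurement ages (months)
#' @param lifespan_mean,lifespan_sd strain lifespan distribution (months)
#' @param short_lived list(n_strains, lifespan_cap, dropout): the first
#'   `n_strains` strains are short-lived with lifespans below `lifespan_cap`
#'   months; with `dropout = TRUE` animals contribute no records at age
#'   groups exceeding their strain's life expectancy
#' @param features list of [feature_spec()]s
#' @param seed integer seed: the same seed yields a byte-identical cohort
#' @return a `cohort_config` list
#' @export
cohort_config <- function(n_strains = 30, n_animals_per_strain_sex = 8,
                          age_groups = c(6, 12, 18, 24),
                          lifespan_mean = 26, lifespan_sd = 5,
                          short_lived = list(n_strains = 6,
                                             lifespan_cap = 18,
                                             dropout = FALSE),
                          features = default_feature_panel(),
                          seed = 1L) {
  if (is.unsorted(age_groups, strictly = TRUE)) {
    am_stop("age_groups must be strictly increasing",
            class = "agemarkers_config_error")
  }
  if (short_lived$n_strains >= n_strains) {
    am_stop("short_lived$n_strains must be < n_strains",
            class = "agemarkers_config_error")
  }
  stopifnot(n_strains > 0, n_animals_per_strain_sex > 0,
            lifespan_mean > 0, lifespan_sd > 0)
  if (inherits(features, "feature_spec")) features <- list(features)
  structure(list(n_strains = n_strains,
                 n_animals_per_strain_sex = n_animals_per_strain_sex,
                 age_groups = age_groups, lifespan_mean = lifespan_mean,
                 lifespan_sd = lifespan_sd, short_lived = short_lived,
                 features = features, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default synthetic feature panel
#'
#' A panel covering every class the engine can emit: corroborative
#' pro-longevity and antilongevity features, a role switch by conflicting
#' evidence, a role switch by prognostic sign switch, a pure biomarker of
#' age, and an inert feature.
#'
#' @param age_groups age groups the per-age correlations are keyed to
#' @return list of [feature_spec()]s
#' @export
default_feature_panel <- function(age_groups = c(6, 12, 18, 24)) {
  r_const <- function(r) stats::setNames(rep(r, length(age_groups)),
                                         age_groups)
  r_switch <- stats::setNames(c(-0.5, 0.5, 0.5, 0.5)[seq_along(age_groups)],
                              age_groups)
  list(
    feature_spec("proA", trend_slope = -0.04, prognostic_r = r_const(0.5),
                 early_effect = "beneficial", late_effect = "beneficial",
                 label = "anti-inflammatory"),
    feature_spec("proB", trend_slope = -0.03, prognostic_r = r_const(0.45),
                 early_effect = "beneficial", late_effect = "beneficial",
                 label = "anti-anaemic"),
    feature_spec("antiA", trend_slope = 0.04, prognostic_r = r_const(-0.5),
                 early_effect = "deleterious", late_effect = "deleterious",
                 label = "pro-inflammatory"),
    feature_spec("switchConf", trend_slope = -0.04,
                 prognostic_r = r_const(-0.5),
                 early_effect = "deleterious", late_effect = "beneficial",
                 label = "damaging early, protective late"),
    feature_spec("switchProg", trend_slope = -0.03, prognostic_r = r_switch,
                 early_effect = "deleterious", late_effect = "beneficial",
                 label = "sign switch in prognosis"),
    feature_spec("ageOnly", trend_slope = 0.04, prognostic_r = r_const(0),
                 label = "accumulates with age, no known effect"),
    feature_spec("inert", trend_slope = 0, prognostic_r = r_const(0))
  )
}

# per-age target r for a spec, resolved against the configured age groups
resolve_prognostic_r <- function(spec, age_groups) {
  r <- spec$prognostic_r
  if (is.null(names(r)) || all(names(r) == "")) {
    r <- stats::setNames(rep(r, length.out = length(age_groups)), age_groups)
  }
  out <- stats::setNames(numeric(length(age_groups)),
                         as.character(age_groups))
  hit <- intersect(names(out), names(r))
  out[hit] <- r[hit]
  out
}

sex_mult <- function(spec, sex) {
  if (is.null(spec$sex_modifier)) return(1)
  m <- spec$sex_modifier[[sex]]
  if (is.null(m)) 1 else m
}

#' Generate a synthetic cohort
#'
#' Deterministic for a fixed seed. Strain lifespans are drawn per strain x
#' sex from a truncated normal; short-lived strains are drawn uniformly
#' below the cap. Feature values are linear in age and in the strain's
#' standardized lifespan plus Gaussian noise (see module header for the
#' calibration). With `short_lived$dropout = TRUE`, records at age groups
#' exceeding a strain's life expectancy are removed.
#'
#' @param config a [cohort_config()]
#' @return list with `records` ([phenotype_table()]), `lifespans`
#'   (lifespan table), `annotations` (effect-annotation table), `truth`
#'   (planted classification per feature, from [planted_truth()])
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  strains <- sprintf("S%02d", seq_len(config$n_strains))
  k_short <- config$short_lived$n_strains
  cap <- config$short_lived$lifespan_cap

  lifespans <- do.call(rbind, lapply(SEXES, function(sx) {
    ls <- pmax(rnorm(config$n_strains, config$lifespan_mean,
                     config$lifespan_sd), cap + 2)
    if (k_short > 0) {
      ls[seq_len(k_short)] <- runif(k_short, max(6, cap - 8), cap)
    }
    data.frame(strain = strains, sex = sx, life_expectancy = ls,
               event_observed = TRUE, stringsAsFactors = FALSE)
  }))

  feat_names <- vapply(config$features, `[[`, character(1), "name")
  # feasibility: b = r * sd / sqrt(1 - r^2) must be finite
  for (spec in config$features) {
    for (sx in SEXES) {
      r <- resolve_prognostic_r(spec, config$age_groups) * sex_mult(spec, sx)
      if (any(abs(r) >= 1)) {
        am_stop(sprintf(
          "feature '%s': |prognostic_r| >= 1 after sex modifier, infeasible",
          spec$name), class = "agemarkers_config_error")
      }
    }
  }

  rec_list <- list()
  for (sx in SEXES) {
    ls_sx <- lifespans[lifespans$sex == sx, ]
    z_life <- as.numeric(scale(ls_sx$life_expectancy))
    n_anim <- config$n_animals_per_strain_sex
    grid <- expand.grid(animal = seq_len(n_anim),
                        strain_i = seq_len(config$n_strains),
                        age = config$age_groups)
    df <- data.frame(
      animal_id = sprintf("%s_%s_a%d", strains[grid$strain_i], sx,
                          grid$animal),
      strain = strains[grid$strain_i], sex = sx, age_months = grid$age,
      stringsAsFactors = FALSE)
    for (spec in config$features) {
      mult <- sex_mult(spec, sx)
      r_by_age <- resolve_prognostic_r(spec, config$age_groups) * mult
      b_by_age <- r_by_age * spec$noise_sd / sqrt(1 - r_by_age^2)
      noise <- rnorm(nrow(grid), 0, spec$noise_sd)
      # empirical calibration: orthogonalize the noise against the
      # standardized lifespan within each age group (and rescale to the
      # nominal SD) so the realized correlation matches the planted one
      # instead of fluctuating with the ~n_strains independent lifespans
      for (a in config$age_groups) {
        idx <- which(grid$age == a)
        z <- z_life[grid$strain_i[idx]]
        e <- noise[idx]
        if (length(idx) > 3 && sd(z) > 0) {
          # remove only the lifespan projection (not the group mean, which
          # carries the null trend variability the t-test calibration needs)
          e <- e - (cov(e, z) / var(z)) * (z - mean(z))
          if (sd(e) > 0) e <- e * spec$noise_sd / sd(e)
        }
        noise[idx] <- e
      }
      df[[spec$name]] <- spec$trend_slope * mult * grid$age +
        b_by_age[as.character(grid$age)] * z_life[grid$strain_i] + noise
    }
    rec_list[[sx]] <- df
  }
  records <- do.call(rbind, rec_list)
  rownames(records) <- NULL

  if (isTRUE(config$short_lived$dropout)) {
    key <- paste(records$strain, records$sex)
    le <- lifespans$life_expectancy[match(key,
                                          paste(lifespans$strain,
                                                lifespans$sex))]
    records <- records[records$age_months <= le, , drop = FALSE]
    rownames(records) <- NULL
  }

  annotations <- annotation_table(data.frame(
    feature_name = feat_names,
    early_effect = vapply(config$features, `[[`, character(1), "early_effect"),
    late_effect = vapply(config$features, `[[`, character(1), "late_effect"),
    label = vapply(config$features, `[[`, character(1), "label"),
    source = "synthetic", stringsAsFactors = FALSE))

  list(records = phenotype_table(records, features = feat_names),
       lifespans = lifespans, annotations = annotations,
       truth = planted_truth(config))
}

#' Planted-truth classification of a cohort configuration
#'
#' Applies the same rule semantics as the classification engine to the
#' noiseless feature parameters: any nonzero planted slope is a significant
#' trend, a planted `|r| >= r_min` is a relevant prognostic cell, and the
#' usual volatile-age filter, validation and conflict-resolution rules
#' follow. Pure function of the configuration; no data are generated.
#'
#' @param config a [cohort_config()]
#' @param r_min relevance threshold matching the analysis (default 0.2)
#' @param volatile_ages matching the analysis (default 18, 20, 24)
#' @return data.frame: feature, expected overall class (plus early/late and
#'   basis columns)
#' @export
planted_truth <- function(config, r_min = 0.2,
                          volatile_ages = VOLATILE_AGES_DEFAULT) {
  rows <- lapply(config$features, function(spec) {
    trend <- do.call(rbind, lapply(SEXES, function(sx) {
      m <- spec$trend_slope * sex_mult(spec, sx)
      data.frame(feature = spec$name, sex = sx, slope_m = m,
                 p_value = if (abs(m) > 1e-12) 0 else 1,
                 r_longitudinal = sign(m), n = Inf,
                 trend_call = if (abs(m) <= 1e-12) "none"
                              else if (m < 0) "down" else "up",
                 stringsAsFactors = FALSE)
    }))
    cells <- do.call(rbind, lapply(SEXES, function(sx) {
      r <- resolve_prognostic_r(spec, config$age_groups) * sex_mult(spec, sx)
      data.frame(feature = spec$name, sex = sx,
                 age_group = config$age_groups, pearson_r = r,
                 p_value = ifelse(abs(r) > 1e-12, 0, 1),
                 n = Inf, relevant = abs(r) >= r_min, degenerate = FALSE,
                 stringsAsFactors = FALSE)
    }))
    ann <- annotation_table(data.frame(
      feature_name = spec$name, early_effect = spec$early_effect,
      late_effect = spec$late_effect, label = spec$label, source = "",
      stringsAsFactors = FALSE))
    bundle <- list(feature = spec$name, trend = trend, cells = cells,
                   annotation = ann)
    cl <- classify_feature(bundle, volatile_ages = volatile_ages)
    data.frame(feature = spec$name, expected_class = cl$overall,
               class_early = cl$class_early, class_late = cl$class_late,
               basis = cl$basis, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
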