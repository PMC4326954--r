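test_that("same seed yields a byte-identical cohort, different seed does not", {
  a <- generate_cohort(small_config(seed = 11))
  b <- generate_cohort(small_config(seed = 11))
  c <- generate_cohort(small_config(seed = 12))
  expect_identical(a$records, b$records)
  expect_identical(a$lifespans, b$lifespans)
  expect_false(identical(a$records, c$records))
})

test_that("dropout removes records beyond the strain's life expectancy", {
  co <- generate_cohort(small_config(seed = 3, dropout = TRUE))
  key <- paste(co$records$strain, co$records$sex)
  le <- co$lifespans$life_expectancy[
    match(key, paste(co$lifespans$strain, co$lifespans$sex))]
  expect_true(all(co$records$age_months <= le))
  # the short-lived subset (cap 18 M) must actually lose its 24 M records
  full <- generate_cohort(small_config(seed = 3, dropout = FALSE))
  expect_lt(nrow(co$records), nrow(full$records))
})

test_that("empirical lifespan correlation tracks prognostic_r within 0.1", {
  spec <- feature_spec("f", trend_slope = 0,
                       prognostic_r = c(`6` = 0.5, `12` = -0.4, `18` = 0.3,
                                        `24` = 0.6))
  for (seed in 1:3) {
    cc <- cohort_config(n_strains = 30, n_animals_per_strain_sex = 8,
                        features = list(spec), seed = seed)
    co <- generate_cohort(cc)
    merged <- merge_lifespan(co$records, co$lifespans)
    for (a in cc$age_groups) {
      cell <- correlate_lifespan(merged, "f", "female", a)
      target <- spec$prognostic_r[[as.character(a)]]
      expect_lt(abs(cell$pearson_r - target), 0.1)
    }
  }
})

test_that("within-strain feature means rank with lifespan when |r| >= 0.5", {
  cc <- cohort_config(n_strains = 20, n_animals_per_strain_sex = 8,
                      features = list(feature_spec("f", prognostic_r = 0.6)),
                      seed = 5)
  co <- generate_cohort(cc)
  rec <- co$records[co$records$sex == "male" & co$records$age_months == 6, ]
  means <- tapply(rec$f, rec$strain, mean)
  ls <- co$lifespans[co$lifespans$sex == "male", ]
  rho <- cor(means[ls$strain], ls$life_expectancy, method = "spearman")
  expect_gt(rho, 0)
})

test_that("planted_truth applies the engine's rule semantics to the noiseless spec", {
  mk <- function(...) small_config(features = list(feature_spec(...)))
  truth1 <- planted_truth(mk("z", trend_slope = 0, prognostic_r = 0))
  expect_equal(truth1$expected_class, "unclassified")

  truth2 <- planted_truth(mk("a", trend_slope = 0.05, prognostic_r = -0.5,
                             early_effect = "deleterious",
                             late_effect = "deleterious"))
  expect_equal(truth2$expected_class, "antilongevity")

  # pro-longevity by construction: downtrend, beneficial, positive r
  truth3 <- planted_truth(mk("p", trend_slope = -0.05, prognostic_r = 0.5,
                             early_effect = "beneficial",
                             late_effect = "beneficial"))
  expect_equal(truth3$expected_class, "pro_longevity")

  # sign switch across age groups in the prognosis alone
  truth4 <- planted_truth(mk("s", trend_slope = -0.03,
                             prognostic_r = c(`6` = -0.5, `12` = 0.5,
                                              `18` = 0.5, `24` = 0),
                             early_effect = "deleterious",
                             late_effect = "beneficial"))
  expect_equal(truth4$expected_class, "role_switching")
  expect_equal(truth4$basis, "prognostic_switch")

  # downtrend with beneficial late effect but short-lifespan prognosis at the
  # earliest age only: conflict resolved as a role switch
  truth5 <- planted_truth(mk("fe", trend_slope = -0.03,
                             prognostic_r = c(`6` = -0.5, `12` = 0, `18` = 0,
                                              `24` = 0),
                             early_effect = "deleterious",
                             late_effect = "beneficial"))
  expect_equal(truth5$expected_class, "role_switching")
  expect_equal(truth5$class_early, "antilongevity")
  expect_equal(truth5$class_late, "pro_longevity")
})

test_that("infeasible prognostic_r is a configuration error", {
  expect_error(feature_spec("f", prognostic_r = 1),
               class = "agemarkers_config_error")
  cc <- small_config(features = list(
    feature_spec("f", prognostic_r = 0.9,
                 sex_modifier = list(male = 1.2))))
  expect_error(generate_cohort(cc), class = "agemarkers_config_error")
})

test_that("sex modifiers scale the planted signal per sex", {
  cc <- cohort_config(n_strains = 30, n_animals_per_strain_sex = 8,
                      features = list(feature_spec(
                        "f", prognostic_r = 0.6,
                        sex_modifier = list(female = 1, male = 0))),
                      seed = 9)
  co <- generate_cohort(cc)
  merged <- merge_lifespan(co$records, co$lifespans)
  rf <- correlate_lifespan(merged, "f", "female", 6)$pearson_r
  rm_ <- correlate_lifespan(merged, "f", "male", 6)$pearson_r
  expect_gt(rf, 0.4)
  expect_lt(abs(rm_), 0.25)
})
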