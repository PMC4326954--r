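test_that("filter_volatile_evidence masks isolated old-age evidence", {
  only24 <- make_cells("f", "female", c(6, 12, 24), c(0.05, 0.1, 0.5))
  out <- filter_volatile_evidence(only24)
  expect_false(out$relevant[out$age_group == 24])
  expect_match(out$mask_reason[out$age_group == 24], "volatile")
  expect_equal(direction_summary(out), "none")

  with12 <- make_cells("f", "female", c(12, 18), c(0.4, 0.45))
  out2 <- filter_volatile_evidence(with12)
  expect_true(all(out2$relevant))

  # clause (b): two concordant volatile ages survive without earlier support
  late2 <- make_cells("f", "female", c(18, 24), c(-0.4, -0.45))
  out3 <- filter_volatile_evidence(late2)
  expect_true(all(out3$relevant))
  expect_equal(direction_summary(out3), "short")

  # opposite-signed volatile cells do not support each other
  late_mixed <- make_cells("f", "female", c(18, 24), c(-0.4, 0.45))
  out4 <- filter_volatile_evidence(late_mixed)
  expect_false(any(out4$relevant))
})

test_that("validate_longitudinal matches trend direction to late effect", {
  expect_equal(validate_longitudinal("down",
                                     make_annotation("RBC", "beneficial",
                                                     "beneficial")),
               "pro_longevity")
  expect_equal(validate_longitudinal("up",
                                     make_annotation("NEUT", "deleterious",
                                                     "deleterious")),
               "antilongevity")
  expect_equal(validate_longitudinal("up",
                                     make_annotation("x", "unknown",
                                                     "unknown")),
               "age_only")
  expect_equal(validate_longitudinal("down", NULL), "age_only")
  # mismatched valence (uptrend, beneficial effect) is not a validation
  expect_equal(validate_longitudinal("up",
                                     make_annotation("x", "beneficial",
                                                     "beneficial")),
               "age_only")
})

test_that("select_candidates routes features by evidence pattern", {
  bundles <- list(
    trendOnly = list(feature = "trendOnly",
                     trend = make_trend("trendOnly", "female", 0.03),
                     cells = make_cells("trendOnly", "female", c(6, 12),
                                        c(0.05, 0.02), p = 0.6),
                     annotation = NULL),
    progOnly = list(feature = "progOnly",
                    trend = make_trend("progOnly", "female", 0.0, p = 0.9),
                    cells = make_cells("progOnly", "female", 12, 0.45),
                    annotation = NULL),
    both = list(feature = "both",
                trend = make_trend("both", "female", -0.03),
                cells = make_cells("both", "female", c(6, 12), c(0.4, 0.45)),
                annotation = make_annotation("both", "beneficial",
                                             "beneficial")),
    nothing = list(feature = "nothing",
                   trend = make_trend("nothing", "female", 0.0, p = 0.9),
                   cells = make_cells("nothing", "female", 6, 0.01, p = 0.9),
                   annotation = NULL))
  sel <- select_candidates(bundles)
  expect_setequal(names(sel$candidates), c("progOnly", "both"))
  expect_equal(sel$fate$fate[sel$fate$feature == "trendOnly"], "age_only")
  expect_equal(sel$fate$fate[sel$fate$feature == "nothing"], "unclassified")
  expect_equal(sel$fate$fate[sel$fate$feature == "progOnly"],
               "candidate_prognostic_only")
})

test_that("classify_feature reproduces the canonical decision patterns", {
  # corroborative pro-longevity (magnesium pattern: long at 12 M, downtrend,
  # beneficial effect)
  mg <- list(feature = "Mg",
             trend = rbind(make_trend("Mg", "female", -0.03),
                           make_trend("Mg", "male", -0.012, p = 0.04)),
             cells = rbind(make_cells("Mg", "female", c(6, 12), c(0.1, 0.42),
                                      p = c(0.5, 0.002)),
                           make_cells("Mg", "male", 12, 0.40, p = 0.002)),
             annotation = make_annotation("Mg", "beneficial", "beneficial"))
  res <- classify_feature(mg)
  expect_equal(res$overall, "pro_longevity")
  expect_equal(res$basis, "corroborative")
  expect_equal(res$qualifiers, "pronounced at 12 M")

  # conflicting evidence resolved as role switch (iron pattern: short at
  # 12 M, downtrend with beneficial late effect)
  fe <- list(feature = "Fe",
             trend = rbind(make_trend("Fe", "female", -0.02),
                           make_trend("Fe", "male", -0.019)),
             cells = rbind(make_cells("Fe", "female", 12, -0.40),
                           make_cells("Fe", "male", 12, -0.38)),
             annotation = make_annotation("Fe", "deleterious", "beneficial"))
  res2 <- classify_feature(fe)
  expect_equal(res2$overall, "role_switching")
  expect_equal(res2$basis, "conflicting_resolved")
  expect_equal(res2$class_early, "antilongevity")
  expect_equal(res2$class_late, "pro_longevity")

  # sign switch in the prognosis alone (thyroxine pattern)
  t4 <- list(feature = "T4",
             trend = rbind(make_trend("T4", "female", -0.015),
                           make_trend("T4", "male", -0.016)),
             cells = rbind(make_cells("T4", "male", 6, -0.40),
                           make_cells("T4", "female", c(12, 18),
                                      c(0.40, 0.38))),
             annotation = make_annotation("T4", "deleterious", "beneficial"))
  res3 <- classify_feature(t4)
  expect_equal(res3$overall, "role_switching")
  expect_equal(res3$basis, "prognostic_switch")
  expect_equal(res3$class_early, "antilongevity")
  expect_equal(res3$class_late, "pro_longevity")
})

test_that("qualifiers follow the sex margin and single-age rules", {
  base <- function(cf, cm) list(
    feature = "f",
    trend = rbind(make_trend("f", "female", -0.02),
                  make_trend("f", "male", -0.02)),
    cells = rbind(cf, cm),
    annotation = make_annotation("f", "beneficial", "beneficial"))

  one_sex <- classify_feature(base(make_cells("f", "female", c(6, 12),
                                              c(0.4, 0.45)),
                                   make_cells("f", "male", c(6, 12),
                                              c(0.05, 0.1), p = 0.5)))
  expect_match(one_sex$qualifiers, "pronounced in female")

  margin <- classify_feature(base(make_cells("f", "female", 6, 0.45),
                                  make_cells("f", "male", 6, 0.42)))
  expect_false(grepl("pronounced in", margin$qualifiers))
  expect_match(margin$qualifiers, "pronounced at 6 M")

  wide_margin <- classify_feature(base(make_cells("f", "female", 6, 0.25),
                                       make_cells("f", "male", 6, 0.45)))
  expect_match(wide_margin$qualifiers, "pronounced in male")
})

test_that("classification is deterministic and complete over a bundle set", {
  bundles <- example_panel_bundles()
  a <- classify_features(bundles)
  b <- classify_features(bundles)
  expect_identical(a, b)
  expect_equal(sort(a$feature), sort(names(bundles)))
  expect_true(all(a$overall %in% c("pro_longevity", "antilongevity",
                                   "role_switching", "age_only",
                                   "unclassified")))
  # class invariants
  rs <- a[a$overall == "role_switching", ]
  expect_true(all(rs$class_early != rs$class_late))
  expect_true(all(rs$class_early != "none" & rs$class_late != "none"))
  cc <- a[a$overall %in% c("pro_longevity", "antilongevity"), ]
  expect_true(all(cc$class_early == cc$overall & cc$class_late == cc$overall))
})
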