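# Strain stratification ------------------------------------------------------
#
# Sensitivity re-analysis excluding the short-lived, disease-truncated
# strains, and a per-strain comparison of longitudinal trend speeds against
# the pooled longer-lived reference ("do short-lived mice age twice as
# fast?").

#' Remove strains from records and lifespan table
#'
#' @param records a [phenotype_table()]
#' @param lifespans lifespan table
#' @param excluded character vector of strain names; unknown strains warn
#'   and are ignored
#' @return list(records, lifespans) with attributes `n_records_removed`,
#'   `n_strains_removed`; a warning is raised if the exclusion empties a
#'   sex x age stratum that was previously populated
#' @export
exclude_strains <- function(records, lifespans, excluded) {
  unknown <- setdiff(excluded, unique(records$strain))
  if (length(unknown) > 0) {
    am_warn(sprintf("strain(s) not present in records: %s",
                    paste(unknown, collapse = ", ")),
            class = "agemarkers_unknown_strain")
  }
  keep_r <- !records$strain %in% excluded
  keep_l <- !lifespans$strain %in% excluded
  out_records <- structure(records[keep_r, , drop = FALSE],
                           features = features_of(records),
                           class = class(records))
  before <- unique(records[, c("sex", "age_months")])
  after <- unique(out_records[, c("sex", "age_months")])
  lost <- !paste(before$sex, before$age_months) %in%
    paste(after$sex, after$age_months)
  if (any(lost)) {
    am_warn(sprintf("exclusion emptied stratum(s): %s",
                    paste(paste0(before$sex[lost], " x ",
                                 before$age_months[lost], " M"),
                          collapse = ", ")),
            class = "agemarkers_empty_stratum")
  }
  structure(list(records = out_records,
                 lifespans = lifespans[keep_l, , drop = FALSE]),
            n_records_removed = sum(!keep_r),
            n_strains_removed = length(intersect(excluded,
                                                 unique(records$strain))))
}

#' Flag short-lived strains by lifespan quantile
#'
#' Convenience helper: strains whose life expectancy (averaged over sexes)
#' falls at or below the given quantile of the strain lifespan distribution.
#' The canonical route is an explicit strain list from prior knowledge of
#' disease predisposition; this is a data-driven stand-in.
#'
#' @param lifespans lifespan table
#' @param prob quantile cutoff (default 0.25)
#' @return character vector of strain names
#' @export
flag_short_lived <- function(lifespans, prob = 0.25) {
  by_strain <- tapply(lifespans$life_expectancy, lifespans$strain, mean)
  names(by_strain)[by_strain <= quantile(by_strain, prob)]
}

# per-subset OLS slope of pre-standardized values on age; NULL if degenerate
slope_fit <- function(z, ages) {
  ok <- !is.na(z)
  z <- z[ok]; ages <- ages[ok]
  if (length(z) < 3 || length(unique(ages)) < 2 || sd(z) == 0) return(NULL)
  fit <- lm(z ~ ages)
  sm <- summary(fit)$coefficients
  list(slope = unname(sm["ages", "Estimate"]),
       se = unname(sm["ages", "Std. Error"]), n = length(z))
}

#' Compare per-strain longitudinal trends with the longer-lived reference
#'
#' The feature is standardized once over the whole sex stratum so that all
#' slopes live on one scale. The reference slope is fit on the pooled
#' longer-lived strains; each short-lived strain's slope is fit on its own
#' records. Categories: `opposite` when the signs differ and both slopes are
#' individually significant (|slope/se| >= `z_threshold`); `faster` when the
#' signs agree, `|strain slope| >= ratio_threshold * |reference slope|` and
#' the difference exceeds `z_threshold` pooled standard errors; `concordant`
#' otherwise; `indeterminate` when either fit is degenerate.
#'
#' @param records a [phenotype_table()]
#' @param feature feature name
#' @param sex sex stratum
#' @param short_lived character vector of short-lived strain names
#' @param z_threshold z-score threshold (default 1.96)
#' @param ratio_threshold slope-ratio threshold for `faster` (default 2)
#' @return data.frame, one row per short-lived strain: strain, feature, sex,
#'   category, strain_slope, reference_slope, reason
#' @export
compare_trends <- function(records, feature, sex, short_lived,
                           z_threshold = 1.96, ratio_threshold = 2.0) {
  sub <- records[records$sex == sex, , drop = FALSE]
  z <- standardize(sub[[feature]])
  ref_idx <- !sub$strain %in% short_lived
  ref <- slope_fit(z[ref_idx], sub$age_months[ref_idx])
  rows <- lapply(short_lived, function(s) {
    out <- data.frame(strain = s, feature = feature, sex = sex,
                      category = "indeterminate", strain_slope = NA_real_,
                      reference_slope = if (is.null(ref)) NA_real_
                                        else ref$slope,
                      reason = "", stringsAsFactors = FALSE)
    own_idx <- sub$strain == s
    own <- slope_fit(z[own_idx], sub$age_months[own_idx])
    if (is.null(ref)) { out$reason <- "degenerate reference fit"; return(out) }
    if (is.null(own)) { out$reason <- "degenerate strain fit"; return(out) }
    out$strain_slope <- own$slope
    both_sig <- abs(own$slope / own$se) >= z_threshold &&
      abs(ref$slope / ref$se) >= z_threshold
    if (sign(own$slope) != sign(ref$slope) && both_sig) {
      out$category <- "opposite"
    } else if (sign(own$slope) == sign(ref$slope) &&
               abs(own$slope) >= ratio_threshold * abs(ref$slope) &&
               (abs(own$slope - ref$slope) /
                sqrt(own$se^2 + ref$se^2)) >= z_threshold) {
      out$category <- "faster"
    } else {
      out$category <- "concordant"
    }
    out
  })
  do.call(rbind, rows)
}

#' Trend comparison matrix over features and sexes
#'
#' @inheritParams compare_trends
#' @param features feature names (default all)
#' @param sexes sexes (default both)
#' @return data.frame stacking [compare_trends()] over features and sexes
#' @export
compare_trends_matrix <- function(records, short_lived,
                                  features = features_of(records),
                                  sexes = intersect(SEXES,
                                                    unique(records$sex)),
                                  z_threshold = 1.96,
                                  ratio_threshold = 2.0) {
  rows <- list()
  for (sx in sexes) for (f in features) {
    res <- tryCatch(
      compare_trends(records, f, sx, short_lived,
                     z_threshold = z_threshold,
                     ratio_threshold = ratio_threshold),
      agemarkers_error = function(e) NULL)
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  do.call(rbind, rows)
}
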