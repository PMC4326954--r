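# Rule-based biomarker classification ----------------------------------------
#
# Evidence per feature comes in three channels:
#   * longitudinal: a per-sex trend call (down / none / up),
#   * prognostic: per-sex, per-age-group lifespan correlations gated by the
#     relevance rule, filtered for volatile old-age evidence,
#   * annotation: literature effect valences (early / late).
# The engine resolves them into one of five classes: pro_longevity,
# antilongevity, role_switching, age_only, unclassified.  Conflicts between
# prognostic (early-life) and validated longitudinal (late-life) evidence
# are resolved as a role switch; a sign switch across age groups in the
# prognosis alone is a role switch as well.

VOLATILE_AGES_DEFAULT <- c(18, 20, 24)

#' Assemble evidence bundles from pipeline stage outputs
#'
#' Joins per-sex trend rows, per-sex/per-age prognostic cells and (optional)
#' effect annotations into one bundle per feature, the unit the classifier
#' consumes.
#'
#' @param trends data.frame from [fit_trends()] (both sexes)
#' @param cells data.frame from [prognostic_cells()] (both sexes)
#' @param annotations data.frame from [read_annotations()] or `NULL`
#' @return named list of bundles; each bundle is a list with elements
#'   `feature`, `trend` (data.frame), `cells` (data.frame), `annotation`
#'   (one-row data.frame or `NULL`)
#' @export
build_evidence <- function(trends, cells, annotations = NULL) {
  feats <- sort(union(unique(trends$feature), unique(cells$feature)))
  bundles <- lapply(feats, function(f) {
    ann <- NULL
    if (!is.null(annotations)) {
      hit <- annotations[annotations$feature_name == f, , drop = FALSE]
      if (nrow(hit) == 1) ann <- hit
    }
    list(feature = f,
         trend = trends[trends$feature == f, , drop = FALSE],
         cells = cells[cells$feature == f, , drop = FALSE],
         annotation = ann)
  })
  names(bundles) <- feats
  bundles
}

#' Mask isolated or inconsistent old-age prognostic evidence
#'
#' Evidence from the oldest age groups is the most volatile (only a fraction
#' of strains survives to contribute), so a relevant cell at a volatile age
#' is kept only if (a) some non-volatile age group is relevant with the same
#' sign, or (b) at least two volatile age groups are relevant with the same
#' sign. Otherwise the cell is masked (`relevant = FALSE`) and the reason
#' recorded in a `mask_reason` column. Applied per sex.
#'
#' @param cells data.frame of prognostic cells for one feature x sex
#' @param volatile_ages age groups treated as volatile (default 18, 20, 24)
#' @return `cells` with volatile-only evidence masked
#' @export
filter_volatile_evidence <- function(cells,
                                     volatile_ages = VOLATILE_AGES_DEFAULT) {
  cells$mask_reason <- NA_character_
  if (nrow(cells) == 0) return(cells)
  for (sx in unique(cells$sex)) {
    idx <- which(cells$sex == sx)
    sub <- cells[idx, , drop = FALSE]
    for (i in seq_along(idx)) {
      row <- sub[i, ]
      if (!isTRUE(row$relevant)) next
      if (!row$age_group %in% volatile_ages) next
      sgn <- sign(row$pearson_r)
      support_nonvolatile <- any(sub$relevant & !is.na(sub$pearson_r) &
                                 !sub$age_group %in% volatile_ages &
                                 sign(sub$pearson_r) == sgn)
      n_volatile_same <- sum(sub$relevant & !is.na(sub$pearson_r) &
                             sub$age_group %in% volatile_ages &
                             sign(sub$pearson_r) == sgn)
      if (!support_nonvolatile && n_volatile_same < 2) {
        cells$relevant[idx[i]] <- FALSE
        cells$mask_reason[idx[i]] <-
          "isolated volatile-age evidence (no concordant earlier or second volatile age)"
      }
    }
  }
  cells
}

#' Validate a longitudinal trend against a literature effect
#'
#' Longitudinal evidence indicates a biomarker of aging (not just of age)
#' only when a matching effect is on record: a beneficial late effect for a
#' downtrend (loss of something good: pro-longevity when high) or a
#' deleterious late effect for an uptrend (accumulation of something bad).
#' An unmatched or unknown effect leaves a biomarker of age only.
#'
#' @param trend_call `"down"`, `"up"` (from [fit_trend()]); `"none"` is not a
#'   valid input
#' @param annotation one-row annotation data.frame or `NULL`
#' @return `"pro_longevity"`, `"antilongevity"` or `"age_only"`
#' @export
validate_longitudinal <- function(trend_call, annotation) {
  stopifnot(trend_call %in% c("down", "up"))
  if (is.null(annotation)) return("age_only")
  late <- annotation$late_effect
  if (trend_call == "down" && identical(late, "beneficial")) "pro_longevity"
  else if (trend_call == "up" && identical(late, "deleterious")) "antilongevity"
  else "age_only"
}

# feature-level trend call pooled over sexes: the significant call if the
# significant sexes agree in sign; "none" if no sex is significant or the
# sexes significantly disagree (flagged)
pooled_trend_call <- function(trend) {
  sig <- trend[trend$trend_call != "none", , drop = FALSE]
  if (nrow(sig) == 0) return(list(call = "none", conflict = FALSE))
  calls <- unique(sig$trend_call)
  if (length(calls) > 1) return(list(call = "none", conflict = TRUE))
  list(call = calls, conflict = FALSE)
}

prog_class_of_sign <- function(s) if (s > 0) "pro_longevity" else "antilongevity"

#' Classify one evidence bundle
#'
#' Decision order:
#' 1. relevant prognostic cells of both signs (in either sex or across
#'    sexes, after the volatile-age filter) constitute a sign switch across
#'    age groups: `role_switching` with basis `prognostic_switch`; the early
#'    class comes from the sign at the earliest relevant age, the late class
#'    from the sign at the latest relevant age.
#' 2. otherwise the prognostic class (long lifespan: pro, short: anti) is
#'    compared with the validated longitudinal class: equal gives that class
#'    with basis `corroborative`; unequal (both defined) gives
#'    `role_switching` with basis `conflicting_resolved`, the early class
#'    from the prognosis and the late class from the validated trend.
#' 3. a single defined evidence channel gives that class with basis
#'    `longitudinal_only` / `prognostic_only` (provisional).
#' 4. a significant trend without validation or prognosis is `age_only`;
#'    nothing at all is `unclassified`.
#'
#' @param bundle one element of [build_evidence()]
#' @param volatile_ages passed to [filter_volatile_evidence()]
#' @param qualifier_margin see [assign_qualifiers()]
#' @return one-row data.frame: feature, class_early, class_late, overall,
#'   basis, qualifiers (`"; "`-separated)
#' @export
classify_feature <- function(bundle, volatile_ages = VOLATILE_AGES_DEFAULT,
                             qualifier_margin = 0.15) {
  ann <- bundle$annotation
  if (!is.null(ann) &&
      ann$early_effect == ann$late_effect &&
      ann$early_effect != "unknown" &&
      isTRUE(ann$role_switch_annotated)) {
    am_stop(sprintf("annotation for '%s' marks a switch but early and late effects agree",
                    bundle$feature),
            class = "agemarkers_annotation_error")
  }
  cells <- filter_volatile_evidence(bundle$cells, volatile_ages = volatile_ages)
  rel <- cells[cells$relevant & !is.na(cells$pearson_r), , drop = FALSE]
  direction <- direction_summary(cells)
  tr <- pooled_trend_call(bundle$trend)
  long_class <- if (tr$call == "none") NA_character_
                else validate_longitudinal(tr$call, ann)

  res <- data.frame(feature = bundle$feature, class_early = "none",
                    class_late = "none", overall = "unclassified",
                    basis = "none", qualifiers = "",
                    stringsAsFactors = FALSE)

  if (direction == "switch") {
    # (1) prognostic sign switch across age groups
    early_sign <- rel$pearson_r[which.min(rel$age_group)]
    late_sign <- rel$pearson_r[which.max(rel$age_group)]
    res$overall <- "role_switching"
    res$basis <- "prognostic_switch"
    res$class_early <- prog_class_of_sign(early_sign)
    res$class_late <- prog_class_of_sign(late_sign)
  } else if (direction %in% c("long", "short")) {
    prog_class <- if (direction == "long") "pro_longevity" else "antilongevity"
    if (!is.na(long_class) && long_class != "age_only") {
      if (long_class == prog_class) {
        res$overall <- prog_class
        res$basis <- "corroborative"
        res$class_early <- res$class_late <- prog_class
      } else {
        # (2) early prognostic effect opposite to validated late effect
        res$overall <- "role_switching"
        res$basis <- "conflicting_resolved"
        res$class_early <- prog_class_of_sign(
          rel$pearson_r[which.min(rel$age_group)])
        res$class_late <- long_class
      }
    } else {
      # (3) prognostic evidence only (trend absent or unvalidated)
      res$overall <- prog_class
      res$basis <- "prognostic_only"
      res$class_early <- res$class_late <- prog_class
    }
  } else {
    if (!is.na(long_class) && long_class != "age_only") {
      res$overall <- long_class
      res$basis <- "longitudinal_only"
      res$class_early <- res$class_late <- long_class
    } else if (tr$call != "none") {
      res$overall <- "age_only"
      res$basis <- "none"
    } # else unclassified
  }
  assign_qualifiers(bundle, res, cells = cells,
                    qualifier_margin = qualifier_margin)
}

#' Attach sex and age-group qualifiers to a classification
#'
#' `"pronounced in <sex>"` is added when relevant prognostic evidence exists
#' in exactly one sex, or when both sexes carry relevant evidence and the
#' stronger sex's maximal `|r|` exceeds the other's by at least
#' `qualifier_margin`. `"pronounced at <age> M"` is added when exactly one
#' age group carries relevant evidence for the deciding prognostic
#' direction (skipped for a prognostic sign switch, where no single
#' direction decides).
#'
#' @param bundle evidence bundle
#' @param classification one-row classification data.frame
#' @param cells volatile-filtered prognostic cells (internal; recomputed if
#'   omitted)
#' @param qualifier_margin minimal `|r|` margin for a sex qualifier when
#'   both sexes are relevant (default 0.15)
#' @return `classification` with its `qualifiers` field filled
#' @export
assign_qualifiers <- function(bundle, classification, cells = NULL,
                              qualifier_margin = 0.15) {
  if (is.null(cells)) cells <- filter_volatile_evidence(bundle$cells)
  rel <- cells[cells$relevant & !is.na(cells$pearson_r), , drop = FALSE]
  quals <- character()
  if (nrow(rel) > 0) {
    sexes <- unique(rel$sex)
    if (length(sexes) == 1 && length(unique(bundle$cells$sex)) > 1) {
      quals <- c(quals, sprintf("pronounced in %s", sexes))
    } else if (length(sexes) == 2) {
      peak <- vapply(SEXES, function(sx) {
        rs <- abs(rel$pearson_r[rel$sex == sx])
        if (length(rs) == 0) 0 else max(rs)
      }, numeric(1))
      if (abs(peak["female"] - peak["male"]) >= qualifier_margin) {
        quals <- c(quals, sprintf("pronounced in %s",
                                  names(peak)[which.max(peak)]))
      }
    }
    if (classification$basis != "prognostic_switch") {
      deciding_sign <- if (classification$basis == "conflicting_resolved" ||
                           classification$overall %in%
                             c("pro_longevity", "antilongevity")) {
        if (classification$class_early == "pro_longevity" ||
            classification$overall == "pro_longevity") 1 else -1
      } else NA_real_
      dec <- if (is.na(deciding_sign)) rel
             else rel[sign(rel$pearson_r) == deciding_sign, , drop = FALSE]
      ages <- unique(dec$age_group)
      if (length(ages) == 1) {
        quals <- c(quals, sprintf("pronounced at %g M", ages))
      }
    }
  }
  classification$qualifiers <- paste(quals, collapse = "; ")
  classification
}

#' Select biomarker candidates from evidence bundles
#'
#' Keeps features carrying either a significant longitudinal trend in at
#' least one sex together with at least one relevant prognostic cell (after
#' the volatile-age filter), or relevant prognostic evidence alone
#' (classified provisionally). Features with a trend but no prognosis and no
#' validating effect are tagged `age_only`; features with neither channel
#' are `unclassified`.
#'
#' @param bundles named list from [build_evidence()]
#' @param volatile_ages passed to [filter_volatile_evidence()]
#' @return list with `candidates` (bundle list) and `rejected` (data.frame
#'   of feature, fate)
#' @export
select_candidates <- function(bundles,
                              volatile_ages = VOLATILE_AGES_DEFAULT) {
  keep <- logical(length(bundles))
  fate <- character(length(bundles))
  for (i in seq_along(bundles)) {
    b <- bundles[[i]]
    cells <- filter_volatile_evidence(b$cells, volatile_ages = volatile_ages)
    has_prog <- any(cells$relevant, na.rm = TRUE)
    tr <- pooled_trend_call(b$trend)
    has_trend <- tr$call != "none"
    validated <- has_trend && !is.null(b$annotation) &&
      validate_longitudinal(tr$call, b$annotation) != "age_only"
    if (has_prog) {
      keep[i] <- TRUE
      fate[i] <- if (has_trend) "candidate" else "candidate_prognostic_only"
    } else if (validated) {
      keep[i] <- TRUE
      fate[i] <- "candidate_longitudinal_only"
    } else if (has_trend) {
      fate[i] <- "age_only"
    } else {
      fate[i] <- "unclassified"
    }
  }
  list(candidates = bundles[keep],
       rejected = data.frame(feature = names(bundles)[!keep],
                             fate = fate[!keep], stringsAsFactors = FALSE),
       fate = data.frame(feature = names(bundles), fate = fate,
                         stringsAsFactors = FALSE))
}

#' Classify every feature of an evidence-bundle set
#'
#' Runs [select_candidates()] and [classify_feature()] over all bundles;
#' every input feature receives exactly one overall class (non-candidates
#' are reported as `age_only` or `unclassified`).
#'
#' @inheritParams select_candidates
#' @inheritParams classify_feature
#' @return data.frame with one row per feature: feature, class_early,
#'   class_late, overall, basis, qualifiers
#' @export
classify_features <- function(bundles,
                              volatile_ages = VOLATILE_AGES_DEFAULT,
                              qualifier_margin = 0.15) {
  rows <- lapply(bundles, function(b)
    classify_feature(b, volatile_ages = volatile_ages,
                     qualifier_margin = qualifier_margin))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
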