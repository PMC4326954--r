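# Tabular domain model -------------------------------------------------------
#
# A phenotype table is a plain data.frame in wide format: one row per
# animal x age group, mandatory columns animal_id, strain, sex, age_months,
# and one numeric column per feature.  The feature column set is carried in
# attr(, "features") so that downstream stages never have to guess which
# columns are measurements.  A merged table additionally carries
# life_expectancy and event_observed columns.

MANDATORY_COLS <- c("animal_id", "strain", "sex", "age_months")

#' Construct a phenotype table
#'
#' @param df data.frame with columns `animal_id`, `strain`, `sex`,
#'   `age_months` and one numeric column per feature. `sex` must be
#'   `"female"` or `"male"`; sexes are a hard stratum and are never pooled by
#'   any analysis stage.
#' @param features character vector naming the feature columns. Defaults to
#'   every non-mandatory column.
#' @return `df` with class `phenotype_table` and a `features` attribute.
#' @export
phenotype_table <- function(df, features = NULL) {
  missing_cols <- setdiff(MANDATORY_COLS, names(df))
  if (length(missing_cols) > 0) {
    am_stop(sprintf("phenotype table lacks mandatory column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            class = "agemarkers_schema_error", missing = missing_cols)
  }
  features <- features %||% setdiff(names(df), c(MANDATORY_COLS,
                                                 "life_expectancy",
                                                 "event_observed"))
  absent <- setdiff(features, names(df))
  if (length(absent) > 0) {
    am_stop(sprintf("feature column(s) absent from table: %s",
                    paste(absent, collapse = ", ")),
            class = "agemarkers_schema_error", missing = absent)
  }
  if (anyDuplicated(features)) {
    am_stop("feature names must be unique", class = "agemarkers_schema_error")
  }
  bad_sex <- which(!df$sex %in% SEXES)
  if (length(bad_sex) > 0) {
    am_stop(sprintf("unknown sex token '%s' at row %d (expected female/male)",
                    df$sex[bad_sex[1]], bad_sex[1]),
            class = "agemarkers_parse_error", rows = bad_sex)
  }
  df$age_months <- as.numeric(df$age_months)
  if (any(!is.finite(df$age_months) | df$age_months <= 0)) {
    am_stop("age_months must be positive and numeric",
            class = "agemarkers_parse_error")
  }
  for (f in features) df[[f]] <- suppressWarnings(as.numeric(df[[f]]))
  structure(as.data.frame(df), features = features,
            class = c("phenotype_table", "data.frame"))
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("<phenotype_table> %d records, %d strains, %d features\n",
              nrow(x), length(unique(x$strain)), length(features_of(x))))
  NextMethod()
}

#' Feature columns of a phenotype table
#' @param x a `phenotype_table`
#' @return character vector of feature column names
#' @export
features_of <- function(x) attr(x, "features")

#' Read a phenotype table from CSV
#'
#' Expects a UTF-8 CSV with a header row and columns `animal_id`, `strain`,
#' `sex`, `age_months`, then one column per feature (one animal x age group
#' per row). Blank or non-numeric feature cells become `NA` (missing), never
#' zeros.
#'
#' @param path CSV file path.
#' @param features optional character vector restricting/declaring the
#'   feature columns; defaults to all non-mandatory columns.
#' @return a [phenotype_table()]
#' @export
read_phenotype_table <- function(path, features = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 colClasses = "character")
  phenotype_table(df, features = features)
}

#' Write a phenotype table (or any pipeline data.frame) to CSV
#' @param x data.frame
#' @param path output path
#' @export
write_table_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a strain life-expectancy table from CSV
#'
#' Columns: `strain`, `sex`, `life_expectancy`, and optionally
#' `event_observed` (defaults to `TRUE`: strain life expectancy is a summary
#' statistic, not a censored follow-up time). Life expectancy is handled in
#' months throughout; declare `unit = "days"` to convert by /30.44.
#'
#' @param path CSV file path.
#' @param unit `"months"` (default) or `"days"`.
#' @return data.frame with one row per strain x sex.
#' @export
read_lifespan_table <- function(path, unit = c("months", "days")) {
  unit <- match.arg(unit)
  df <- read.csv(path, stringsAsFactors = FALSE)
  lifespan_table(df, unit = unit)
}

#' Construct/validate a strain life-expectancy table
#' @param df data.frame with strain, sex, life_expectancy, optional
#'   event_observed
#' @param unit `"months"` or `"days"` (days are converted by /30.44)
#' @return validated data.frame
#' @export
lifespan_table <- function(df, unit = "months") {
  missing_cols <- setdiff(c("strain", "sex", "life_expectancy"), names(df))
  if (length(missing_cols) > 0) {
    am_stop(sprintf("lifespan table lacks column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            class = "agemarkers_schema_error", missing = missing_cols)
  }
  if (is.null(df$event_observed)) df$event_observed <- TRUE
  df$event_observed <- as.logical(df$event_observed)
  df$life_expectancy <- as.numeric(df$life_expectancy)
  if (identical(unit, "days")) {
    df$life_expectancy <- df$life_expectancy / 30.44
  }
  if (any(!is.finite(df$life_expectancy) | df$life_expectancy <= 0)) {
    am_stop("life_expectancy must be positive",
            class = "agemarkers_parse_error")
  }
  key <- paste(df$strain, df$sex)
  if (anyDuplicated(key)) {
    am_stop(sprintf("duplicate strain x sex entries: %s",
                    paste(unique(key[duplicated(key)]), collapse = ", ")),
            class = "agemarkers_schema_error")
  }
  df
}

#' Read an effect-annotation table from CSV
#'
#' Literature-derived effect valences per feature: columns `feature_name`,
#' `early_effect`, `late_effect` (each `beneficial`/`deleterious`/`unknown`),
#' `label`, `source`. Annotations are inputs: the literature search that
#' produces them is outside this package's scope.
#'
#' @param path CSV file path.
#' @return data.frame, one row per annotated feature.
#' @export
read_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  annotation_table(df)
}

#' Construct/validate an effect-annotation table
#' @param df data.frame with feature_name, early_effect, late_effect and
#'   optional label, source columns
#' @return validated data.frame
#' @export
annotation_table <- function(df) {
  missing_cols <- setdiff(c("feature_name", "early_effect", "late_effect"),
                          names(df))
  if (length(missing_cols) > 0) {
    am_stop(sprintf("annotation table lacks column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            class = "agemarkers_schema_error", missing = missing_cols)
  }
  if (anyDuplicated(df$feature_name)) {
    am_stop("annotated features must be unique",
            class = "agemarkers_schema_error")
  }
  for (col in c("early_effect", "late_effect")) {
    bad <- !df[[col]] %in% EFFECTS
    if (any(bad)) {
      am_stop(sprintf("invalid %s value(s): %s", col,
                      paste(unique(df[[col]][bad]), collapse = ", ")),
              class = "agemarkers_parse_error")
    }
  }
  if (is.null(df$label)) df$label <- ""
  if (is.null(df$source)) df$source <- ""
  df
}

#' Merge strain life expectancy onto phenotype records
#'
#' Longitudinal phenotype records carry no individual lifespan, so each
#' record receives the life expectancy of its strain x sex from a separate
#' lifespan study. The merge never alters phenotype values and preserves the
#' record count unless `drop_unmatched` removes rows.
#'
#' @param records a [phenotype_table()]
#' @param lifespans a [lifespan_table()]
#' @param drop_unmatched drop records whose strain x sex is absent from
#'   `lifespans` (dropped count reported in attribute `n_dropped`); if
#'   `FALSE` (default) such records raise an error naming the strains.
#' @return merged `phenotype_table` with `life_expectancy` and
#'   `event_observed` columns.
#' @export
merge_lifespan <- function(records, lifespans, drop_unmatched = FALSE) {
  key_r <- paste(records$strain, records$sex)
  key_l <- paste(lifespans$strain, lifespans$sex)
  idx <- match(key_r, key_l)
  unmatched <- is.na(idx)
  if (any(unmatched)) {
    strains <- sort(unique(records$strain[unmatched]))
    if (!drop_unmatched) {
      am_stop(sprintf("no life expectancy for strain(s): %s",
                      paste(strains, collapse = ", ")),
              class = "agemarkers_merge_error", strains = strains)
    }
    records <- records[!unmatched, , drop = FALSE]
    idx <- idx[!unmatched]
  }
  out <- records
  out$life_expectancy <- lifespans$life_expectancy[idx]
  out$event_observed <- lifespans$event_observed[idx]
  out <- structure(out, features = features_of(records),
                   class = c("phenotype_table", "data.frame"),
                   n_dropped = sum(unmatched))
  out
}

#' Derive absolute cell counts from percentages
#'
#' Blood-count panels often report one absolute total (e.g. the white blood
#' cell count) and per-cell-type percentages. For each percentage feature
#' `pctX` this adds an absolute feature `nX = total * pctX / 100` so that
#' counts and percentages can be analysed on the same footing. Missing inputs
#' propagate to missing outputs.
#'
#' @param records a [phenotype_table()]
#' @param total_feature name of the absolute total feature.
#' @param pct_features character vector of percentage feature names; a name
#'   `pctX` yields `nX`, any other name `Y` yields `nY`.
#' @return `records` with the derived columns appended to the feature set.
#' @export
derive_absolute_counts <- function(records, total_feature, pct_features) {
  feats <- features_of(records)
  absent <- setdiff(c(total_feature, pct_features), feats)
  if (length(absent) > 0) {
    am_stop(sprintf("feature(s) not in table: %s",
                    paste(absent, collapse = ", ")),
            class = "agemarkers_schema_error", missing = absent)
  }
  total <- records[[total_feature]]
  bad_total <- which(!is.na(total) & total < 0)
  if (length(bad_total) > 0) {
    am_stop(sprintf("negative %s for animal '%s'", total_feature,
                    records$animal_id[bad_total[1]]),
            class = "agemarkers_validation_error")
  }
  for (f in pct_features) {
    pct <- records[[f]]
    bad <- which(!is.na(pct) & (pct < 0 | pct > 100))
    if (length(bad) > 0) {
      am_stop(sprintf("percentage %s = %g outside [0,100] for animal '%s'",
                      f, pct[bad[1]], records$animal_id[bad[1]]),
              class = "agemarkers_validation_error")
    }
    derived <- if (startsWith(f, "pct")) sub("^pct", "n", f) else paste0("n", f)
    records[[derived]] <- total * pct / 100
    feats <- union(feats, derived)
  }
  structure(records, features = feats,
            class = c("phenotype_table", "data.frame"))
}
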