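# Pipeline orchestration and chart specs -------------------------------------
#
# run_pipeline() wires the stages together: read/generate -> merge ->
# derive counts -> trends -> prognostic cells -> Cox screen -> volatile
# filter -> classification -> stratified re-run -> trend comparison, and
# writes CSV/JSON outputs plus a manifest.  Charts are emitted as structured
# specs (ordering, bar values, relevance mask, delimiters), not pixels.

#' Build a chart specification
#'
#' A chart spec pairs the regression-based feature ordering of one sex with
#' per-feature bar values: lifespan correlations (panel
#' `lifespan_correlation`) or negated Cox coefficients (panel `cox_display`,
#' the inverted axis that makes hazard-decreasing features point the same
#' way as positive correlations). Bars whose underlying cell is not relevant
#' are open (`filled = FALSE`).
#'
#' @param ordering a [order_features()] result
#' @param cells data.frame with columns `feature`, `relevant` and either
#'   `value`, `pearson_r` or `coefficient` (a `coefficient` is negated for
#'   `cox_display` panels)
#' @param panel_kind `"lifespan_correlation"` or `"cox_display"`
#' @param sex,dataset_label chart metadata
#' @return list: sex, dataset_label, panel_kind, bars (data.frame feature /
#'   value / filled), delimiter_down, delimiter_up
#' @export
build_chart_spec <- function(ordering, cells,
                             panel_kind = c("lifespan_correlation",
                                            "cox_display"),
                             sex = NA_character_, dataset_label = "") {
  panel_kind <- match.arg(panel_kind)
  extra <- setdiff(cells$feature, ordering$ordered_features)
  missing <- setdiff(ordering$ordered_features, cells$feature)
  if (length(extra) > 0 || length(missing) > 0) {
    am_stop(sprintf(
      "ordering/cell feature sets differ; only in cells: [%s], only in ordering: [%s]",
      paste(extra, collapse = ", "), paste(missing, collapse = ", ")),
      class = "agemarkers_chart_error")
  }
  idx <- match(ordering$ordered_features, cells$feature)
  value <- if (!is.null(cells$value)) cells$value[idx]
           else if (panel_kind == "cox_display" &&
                    !is.null(cells$coefficient)) -cells$coefficient[idx]
           else if (!is.null(cells$pearson_r)) cells$pearson_r[idx]
           else am_stop("cells need a value, pearson_r or coefficient column",
                        class = "agemarkers_chart_error")
  list(sex = sex, dataset_label = dataset_label, panel_kind = panel_kind,
       bars = data.frame(feature = ordering$ordered_features, value = value,
                         filled = as.logical(cells$relevant[idx]),
                         stringsAsFactors = FALSE),
       delimiter_down = ordering$delimiter_down,
       delimiter_up = ordering$delimiter_up)
}

#' Default analysis thresholds
#' @return named list of the pipeline's tunable thresholds
#' @export
default_thresholds <- function() {
  list(alpha = 0.05, r_min = 0.2, qualifier_margin = 0.15,
       volatile_ages = VOLATILE_AGES_DEFAULT, ties = "efron")
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config$thresholds <- utils::modifyList(default_thresholds(),
                                         config$thresholds %||% list())
  config
}

config_to_cohort <- function(syn) {
  sl <- utils::modifyList(list(n_strains = 6, lifespan_cap = 18,
                               dropout = FALSE), syn$short_lived %||% list())
  feats <- if (is.null(syn$features)) {
    default_feature_panel(age_groups = syn$age_groups %||% c(6, 12, 18, 24))
  } else {
    lapply(syn$features, function(fs) {
      fs$prognostic_r <- unlist(fs$prognostic_r)
      do.call(feature_spec, fs)
    })
  }
  cohort_config(
    n_strains = syn$n_strains %||% 30,
    n_animals_per_strain_sex = syn$n_animals_per_strain_sex %||% 8,
    age_groups = unlist(syn$age_groups %||% c(6, 12, 18, 24)),
    lifespan_mean = syn$lifespan_mean %||% 26,
    lifespan_sd = syn$lifespan_sd %||% 5,
    short_lived = sl, features = feats, seed = syn$seed %||% 1L)
}

classify_from_tables <- function(records, lifespans, annotations, th) {
  merged <- merge_lifespan(records, lifespans, drop_unmatched = TRUE)
  trends <- fit_trends(records, alpha = th$alpha)
  cells <- prognostic_cells(merged, r_min = th$r_min, alpha = th$alpha)
  bundles <- build_evidence(trends, cells, annotations)
  list(merged = merged, trends = trends, cells = cells,
       classification = classify_features(
         bundles, volatile_ages = th$volatile_ages,
         qualifier_margin = th$qualifier_margin))
}

#' Run the full biomarker classification pipeline
#'
#' Executes read/synthesize, lifespan merge, optional derived counts, trend
#' fits, prognostic screening, Cox screening, classification with
#' qualifiers, the stratified re-run without the short-lived strains, and
#' the per-strain trend comparison. All stage outputs are written to
#' `out_dir` as CSV/JSON together with a `manifest.json` recording seed,
#' thresholds, package version and per-stage row counts.
#'
#' @param config path to a YAML config file, or an equivalent list. Keys:
#'   `synthesis` (a [cohort_config()]-shaped block) *or* `inputs`
#'   (`phenotypes`, `lifespans`, optional `annotations` CSV paths),
#'   `thresholds` (any of alpha, r_min, qualifier_margin, volatile_ages,
#'   ties), `excluded_strains` (list, or `"auto"` for the synthetic
#'   short-lived subset / lifespan-quantile flag), `derive_counts`
#'   (`total`, `pct`), `seed` (override), `out` (directory).
#' @param out_dir output directory (overrides `config$out`); `NULL` writes
#'   nothing
#' @return (invisibly) list with records, lifespans, merged, trends, cells,
#'   cox, classification, stratified, comparison, chart_specs, manifest
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_pipeline_config(config)
  th <- cfg$thresholds
  out_dir <- out_dir %||% cfg$out
  manifest <- list(package_version = as.character(packageVersion("agemarkers")),
                   thresholds = th, stages = list())
  note <- function(stage, n) manifest$stages[[stage]] <<- n

  if (!is.null(cfg$synthesis)) {
    syn <- cfg$synthesis
    if (!is.null(cfg$seed)) syn$seed <- cfg$seed
    cc <- config_to_cohort(syn)
    manifest$seed <- cc$seed
    cohort <- generate_cohort(cc)
    records <- cohort$records
    lifespans <- cohort$lifespans
    annotations <- cohort$annotations
    truth <- cohort$truth
    short_lived_strains <- unique(records$strain)[
      seq_len(cc$short_lived$n_strains)]
  } else if (!is.null(cfg$inputs)) {
    records <- read_phenotype_table(cfg$inputs$phenotypes)
    lifespans <- read_lifespan_table(cfg$inputs$lifespans)
    annotations <- if (!is.null(cfg$inputs$annotations))
      read_annotations(cfg$inputs$annotations) else NULL
    truth <- NULL
    short_lived_strains <- flag_short_lived(lifespans)
  } else {
    am_stop("config needs a 'synthesis' or an 'inputs' block",
            class = "agemarkers_config_error")
  }
  note("records", nrow(records))

  if (!is.null(cfg$derive_counts)) {
    records <- derive_absolute_counts(records, cfg$derive_counts$total,
                                      unlist(cfg$derive_counts$pct))
  }

  excluded <- cfg$excluded_strains %||% "auto"
  if (identical(excluded, "auto")) excluded <- short_lived_strains
  excluded <- unlist(excluded)

  main <- classify_from_tables(records, lifespans, annotations, th)
  note("merged", nrow(main$merged))
  note("trends", nrow(main$trends))
  note("prognostic_cells", nrow(main$cells))
  note("classified", nrow(main$classification))

  cox <- cox_screen(main$merged, ties = th$ties)
  note("cox", if (is.null(cox)) 0L else nrow(cox))

  strat <- NULL
  comparison <- NULL
  if (length(excluded) > 0) {
    kept <- exclude_strains(records, lifespans, excluded)
    strat <- classify_from_tables(kept$records, kept$lifespans,
                                  annotations, th)
    note("stratified_records", nrow(kept$records))
    note("stratified_classified", nrow(strat$classification))
    comparison <- compare_trends_matrix(records, short_lived = excluded)
    note("comparison", if (is.null(comparison)) 0L else nrow(comparison))
  }

  chart_specs <- list()
  for (sx in intersect(SEXES, unique(records$sex))) {
    tr_sx <- main$trends[main$trends$sex == sx, , drop = FALSE]
    if (nrow(tr_sx) == 0) next
    ordering <- order_features(tr_sx)
    for (a in sort(unique(main$cells$age_group))) {
      cells_a <- main$cells[main$cells$sex == sx &
                            main$cells$age_group == a, , drop = FALSE]
      cells_a <- cells_a[match(ordering$ordered_features, cells_a$feature), ]
      chart_specs[[sprintf("%s_%gM_correlation", sx, a)]] <-
        build_chart_spec(ordering, cells_a, "lifespan_correlation",
                         sex = sx, dataset_label = sprintf("%g M", a))
    }
    if (!is.null(cox)) {
      cox_sx <- cox[cox$sex == sx, , drop = FALSE]
      for (a in sort(unique(cox_sx$age_group))) {
        cc_a <- cox_sx[cox_sx$age_group == a, , drop = FALSE]
        if (!setequal(cc_a$feature, ordering$ordered_features)) next
        cc_a$relevant <- cc_a$p_value < th$alpha
        chart_specs[[sprintf("%s_%gM_cox", sx, a)]] <-
          build_chart_spec(ordering, cc_a, "cox_display", sex = sx,
                           dataset_label = sprintf("%g M", a))
      }
    }
  }

  result <- list(records = records, lifespans = lifespans,
                 annotations = annotations, truth = truth,
                 merged = main$merged, trends = main$trends,
                 cells = main$cells, cox = cox,
                 classification = main$classification,
                 stratified = strat$classification,
                 comparison = comparison, chart_specs = chart_specs,
                 excluded_strains = excluded, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_csv(main$trends, file.path(out_dir, "trends.csv"))
    write_table_csv(main$cells, file.path(out_dir, "prognostic.csv"))
    if (!is.null(cox)) write_table_csv(cox, file.path(out_dir, "cox.csv"))
    write_table_csv(main$classification,
                    file.path(out_dir, "classification.csv"))
    if (!is.null(strat))
      write_table_csv(strat$classification,
                      file.path(out_dir, "classification_longerlived.csv"))
    if (!is.null(comparison))
      write_table_csv(comparison, file.path(out_dir, "comparison.csv"))
    if (!is.null(truth))
      write_table_csv(truth, file.path(out_dir, "planted_truth.csv"))
    jsonlite::write_json(chart_specs, file.path(out_dir, "chartspec.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
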