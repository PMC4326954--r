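# Prognostic evidence --------------------------------------------------------
#
# Per feature x sex x age group: Pearson correlation between the feature
# value and the strain life expectancy carried by each merged record, with
# the relevance gate |r| >= r_min and p < alpha; and univariate /
# multivariate Cox proportional-hazards fits as a cross-check.  A positive
# correlation means high feature values are prognostic for a long lifespan.
# Cox coefficients are displayed negated (display_sign) so that "good for
# lifespan" points the same way in both panels.

#' Prognostic correlation of a feature with life expectancy at one age group
#'
#' Pearson correlation (with its two-sided p-value) between feature value and
#' strain life expectancy, over the records of one sex at one age group.
#' A cell is *relevant* iff `|r| >= r_min` and `p < alpha`. Degenerate cells
#' (constant feature or constant lifespan) are returned with `r = NA`,
#' `relevant = FALSE` and a `degenerate` flag instead of erroring, so screens
#' over many features keep running.
#'
#' @param merged merged records from [merge_lifespan()]
#' @param feature feature column name
#' @param sex `"female"` or `"male"`
#' @param age_group age group in months
#' @param r_min relevance threshold on `|r|` (default 0.2)
#' @param alpha relevance threshold on the p-value (default 0.05)
#' @return one-row data.frame: feature, sex, age_group, pearson_r, p_value,
#'   n, relevant, degenerate
#' @export
correlate_lifespan <- function(merged, feature, sex, age_group,
                               r_min = 0.2, alpha = 0.05) {
  sub <- merged[merged$sex == sex & merged$age_months == age_group, ,
                drop = FALSE]
  x <- sub[[feature]]
  y <- sub$life_expectancy
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  cell <- data.frame(feature = feature, sex = sex, age_group = age_group,
                     pearson_r = NA_real_, p_value = NA_real_, n = n,
                     relevant = FALSE, degenerate = TRUE,
                     stringsAsFactors = FALSE)
  if (n < 3) return(cell)
  if (sd(x) == 0 || sd(y) == 0) return(cell)
  ct <- cor.test(x, y, method = "pearson")
  cell$pearson_r <- unname(ct$estimate)
  cell$p_value <- ct$p.value
  cell$degenerate <- FALSE
  cell$relevant <- abs(cell$pearson_r) >= r_min & cell$p_value < alpha
  cell
}

#' Prognostic correlation screen over features, sexes and age groups
#'
#' @inheritParams correlate_lifespan
#' @param features feature names (default all)
#' @param sexes sexes to screen (default both, separately)
#' @param age_groups age groups (default all present)
#' @return data.frame of cells, one row per feature x sex x age group
#' @export
prognostic_cells <- function(merged, features = features_of(merged),
                             sexes = intersect(SEXES, unique(merged$sex)),
                             age_groups = sort(unique(merged$age_months)),
                             r_min = 0.2, alpha = 0.05) {
  grid <- expand.grid(feature = features, sex = sexes, age_group = age_groups,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    correlate_lifespan(merged, grid$feature[i], grid$sex[i],
                       grid$age_group[i], r_min = r_min, alpha = alpha)
  })
  do.call(rbind, rows)
}

#' Summarize the prognostic direction of a set of relevant cells
#'
#' `long` iff every relevant cell has r > 0, `short` iff every relevant cell
#' has r < 0, `switch` iff relevant cells of both signs exist, `none` iff no
#' cell is relevant.
#'
#' @param cells data.frame of prognostic cells (one feature, one or both
#'   sexes)
#' @return one of `"long"`, `"short"`, `"switch"`, `"none"`
#' @export
direction_summary <- function(cells) {
  rel <- cells[cells$relevant & !is.na(cells$pearson_r), , drop = FALSE]
  if (nrow(rel) == 0) return("none")
  pos <- any(rel$pearson_r > 0)
  neg <- any(rel$pearson_r < 0)
  if (pos && neg) "switch" else if (pos) "long" else "short"
}

# standardized covariate + survival frame shared by the Cox fits
cox_frame <- function(merged, features, sex, age_group, complete_only = FALSE) {
  sub <- merged[merged$sex == sex & merged$age_months == age_group, ,
                drop = FALSE]
  if (complete_only) {
    sub <- sub[complete.cases(sub[, features, drop = FALSE]), , drop = FALSE]
  }
  sub
}

#' Univariate Cox proportional-hazards fit at one age group
#'
#' Fits the partial likelihood of a Cox model with strain life expectancy as
#' the time and the standardized feature value as the single covariate, for
#' one sex at one age group. All animals of a strain share one lifespan, so
#' ties are heavy; the Efron correction is the default. The reported
#' `display_sign = -coefficient` inverts the axis so that a feature that is
#' good for lifespan (hazard-decreasing, coefficient < 0) displays positive,
#' directly comparable with its lifespan correlation.
#'
#' Monotone partial likelihoods (the feature perfectly ranks lifespan) are
#' flagged `separation = TRUE` and the coefficient capped at +/-`cap`.
#'
#' @inheritParams correlate_lifespan
#' @param ties tie correction, `"efron"` (default) or `"breslow"`
#' @param cap absolute cap on the log-hazard coefficient under separation
#' @return one-row data.frame: feature, sex, age_group, coefficient, se,
#'   p_value, n, display_sign, separation
#' @export
cox_univariate <- function(merged, feature, sex, age_group,
                           ties = c("efron", "breslow"), cap = 15) {
  ties <- match.arg(ties)
  sub <- cox_frame(merged, feature, sex, age_group)
  ok <- !is.na(sub[[feature]]) & !is.na(sub$life_expectancy)
  sub <- sub[ok, , drop = FALSE]
  n <- nrow(sub)
  if (n < 3 || length(unique(sub$life_expectancy)) < 2) {
    am_stop(sprintf("feature '%s' (%s, %g M): insufficient data for Cox fit",
                    feature, sex, age_group),
            class = "agemarkers_insufficient_data")
  }
  if (sum(sub$event_observed) < 2) {
    am_stop("fewer than 2 observed events", class = "agemarkers_insufficient_data")
  }
  z <- standardize(sub[[feature]])
  separation <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(sub$life_expectancy, sub$event_observed) ~ z,
                    ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- unname(coef(fit)[1])
  se <- sqrt(unname(fit$var[1, 1]))
  if (!is.finite(beta)) {
    am_stop(sprintf("Cox fit failed for '%s' (%s, %g M) after %d iterations",
                    feature, sex, age_group, fit$iter),
            class = "agemarkers_fit_error")
  }
  if (abs(beta) > cap) {
    separation <- TRUE
    beta <- sign(beta) * cap
  }
  p <- 2 * pnorm(-abs(beta / se))
  data.frame(feature = feature, sex = sex, age_group = age_group,
             coefficient = beta, se = se, p_value = p, n = n,
             display_sign = -beta, separation = separation,
             stringsAsFactors = FALSE)
}

#' Univariate Cox screen over features, sexes and age groups
#' @inheritParams cox_univariate
#' @inheritParams prognostic_cells
#' @return data.frame of Cox rows; combinations with insufficient data are
#'   skipped and listed in the `excluded` attribute
#' @export
cox_screen <- function(merged, features = features_of(merged),
                       sexes = intersect(SEXES, unique(merged$sex)),
                       age_groups = sort(unique(merged$age_months)),
                       ties = "efron") {
  rows <- list(); excluded <- list()
  for (sx in sexes) for (a in age_groups) for (f in features) {
    res <- tryCatch(cox_univariate(merged, f, sx, a, ties = ties),
                    agemarkers_error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(feature = f, sex = sx, age_group = a,
                   reason = conditionMessage(res), stringsAsFactors = FALSE)
    } else rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else NULL
  attr(out, "excluded") <- if (length(excluded) > 0) do.call(rbind, excluded)
                           else NULL
  out
}

#' Multivariate Cox proportional-hazards fit at one age group
#'
#' Joint partial-likelihood fit of several standardized features on
#' complete-case rows (listwise deletion). The effective number of records
#' and of contributing strains is reported in attributes `n` and `n_strains`.
#'
#' @inheritParams cox_univariate
#' @param features character vector of feature names to fit jointly
#' @return data.frame with one Cox row per feature, attributes `n` and
#'   `n_strains`
#' @export
cox_multivariate <- function(merged, features, sex, age_group,
                             ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  sub <- cox_frame(merged, features, sex, age_group, complete_only = TRUE)
  n <- nrow(sub)
  if (n < length(features) + 2) {
    am_stop(sprintf("only %d complete cases for %d features (%s, %g M)",
                    n, length(features), sex, age_group),
            class = "agemarkers_insufficient_data")
  }
  Z <- vapply(features, function(f) standardize(sub[[f]]), numeric(n))
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) {
    dep <- features[qrz$pivot[(qrz$rank + 1):ncol(Z)]]
    am_stop(sprintf("collinear feature set, dependent column(s): %s",
                    paste(dep, collapse = ", ")),
            class = "agemarkers_collinearity_error", dependent = dep)
  }
  fit <- survival::coxph(
    survival::Surv(sub$life_expectancy, sub$event_observed) ~ Z, ties = ties)
  beta <- unname(coef(fit))
  se <- sqrt(diag(fit$var))
  out <- data.frame(feature = features, sex = sex, age_group = age_group,
                    coefficient = beta, se = se,
                    p_value = 2 * pnorm(-abs(beta / se)), n = n,
                    display_sign = -beta, stringsAsFactors = FALSE)
  attr(out, "n") <- n
  attr(out, "n_strains") <- length(unique(sub$strain))
  out
}
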