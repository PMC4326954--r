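# Longitudinal trend detection ----------------------------------------------
#
# Per feature x sex: standardize values over all age groups jointly, regress
# on age in raw months by ordinary least squares, test the slope with a
# two-sided t-test, and convert the slope to the equivalent Pearson
# correlation with age.  Standardizing the response makes slopes comparable
# across features and makes the conversion r = m * sd(age) exact in-sample.

#' Standardize a vector to mean 0, sample SD 1
#'
#' Missing entries are preserved as missing; mean and SD are computed over
#' the non-missing values. A constant (or near-constant) vector is a
#' degenerate feature and raises an error rather than being silently zeroed.
#'
#' @param values numeric vector (NAs allowed)
#' @return standardized vector of the same length
#' @export
standardize <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) {
    am_stop("need at least 2 non-missing values to standardize",
            class = "agemarkers_insufficient_data")
  }
  s <- sd(values[ok])
  if (!is.finite(s) || s <= .Machine$double.eps * max(1, abs(mean(values[ok])))) {
    am_stop("constant vector: degenerate feature cannot be standardized",
            class = "agemarkers_degenerate_feature")
  }
  (values - mean(values[ok])) / s
}

#' Fit the longitudinal trend of one feature for one sex
#'
#' Ordinary least squares of standardized feature values on age in months,
#' pooling all strains and age groups within the sex stratum. Significance is
#' the two-sided t-test on the slope; the call is `down`/`up` only when the
#' slope is significant at `alpha`, else `none`. Rows with a missing feature
#' value are dropped (pairwise-complete); the effective n is reported.
#'
#' @param records a [phenotype_table()]
#' @param feature feature column name
#' @param sex `"female"` or `"male"`
#' @param alpha significance threshold for the trend call (default 0.05)
#' @return one-row data.frame: feature, sex, slope_m, p_value,
#'   r_longitudinal, n, trend_call
#' @export
fit_trend <- function(records, feature, sex, alpha = 0.05) {
  sub <- records[records$sex == sex & !is.na(records[[feature]]), , drop = FALSE]
  n <- nrow(sub)
  if (n < 3) {
    am_stop(sprintf("feature '%s' (%s): %d records, need >= 3", feature, sex, n),
            class = "agemarkers_insufficient_data")
  }
  ages <- sub$age_months
  if (length(unique(ages)) < 2) {
    am_stop(sprintf("feature '%s' (%s): all records at one age group",
                    feature, sex),
            class = "agemarkers_rank_deficiency")
  }
  z <- standardize(sub[[feature]])
  fit <- lm(z ~ ages)
  sm <- summary(fit)$coefficients
  slope <- unname(sm["ages", "Estimate"])
  p <- unname(sm["ages", "Pr(>|t|)"])
  r <- slope_to_correlation(slope, ages)
  call <- if (p < alpha && slope < 0) "down"
          else if (p < alpha && slope > 0) "up"
          else "none"
  data.frame(feature = feature, sex = sex, slope_m = slope, p_value = p,
             r_longitudinal = r, n = n, trend_call = call,
             stringsAsFactors = FALSE)
}

#' Fit trends for many features and sexes
#'
#' Convenience wrapper over [fit_trend()]. Features that are degenerate
#' (constant) or lack data are excluded from the result and recorded in the
#' `excluded` attribute with their reason, rather than failing the run.
#'
#' @inheritParams fit_trend
#' @param features feature names (default: all features of `records`)
#' @param sexes sexes to fit (default: both, separately)
#' @return data.frame of trend rows, `excluded` attribute listing skipped
#'   feature x sex combinations
#' @export
fit_trends <- function(records, features = features_of(records),
                       sexes = intersect(SEXES, unique(records$sex)),
                       alpha = 0.05) {
  rows <- list(); excluded <- list()
  for (sx in sexes) {
    for (f in features) {
      res <- tryCatch(fit_trend(records, f, sx, alpha = alpha),
                      agemarkers_error = function(e) e)
      if (inherits(res, "error")) {
        excluded[[length(excluded) + 1L]] <-
          data.frame(feature = f, sex = sx, reason = conditionMessage(res),
                     stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(feature = character(), sex = character(), slope_m = numeric(),
               p_value = numeric(), r_longitudinal = numeric(), n = integer(),
               trend_call = character(), stringsAsFactors = FALSE)
  attr(out, "excluded") <- if (length(excluded) > 0) do.call(rbind, excluded)
                           else NULL
  out
}

#' Convert a regression slope on standardized values to a Pearson correlation
#'
#' With the response standardized to sample SD 1, the OLS slope m on age
#' satisfies r = m * s_age, where s_age is the sample SD of the ages over all
#' measurements. The regression is therefore equivalent to a correlation
#' analysis between the feature and the age of measurement.
#'
#' @param slope_m OLS slope of standardized values on age (per month)
#' @param ages vector of ages (months) the regression was fit on
#' @return the equivalent Pearson correlation coefficient
#' @export
slope_to_correlation <- function(slope_m, ages) {
  s_age <- sd(ages)
  if (!is.finite(s_age) || s_age == 0) {
    am_stop("zero age spread: correlation undefined",
            class = "agemarkers_degenerate_feature")
  }
  r <- slope_m * s_age
  # guard against rounding just past +/-1 in the perfectly collinear limit
  max(-1, min(1, r))
}

#' Order features by longitudinal slope, with trend delimiters
#'
#' Ascending sort by slope (ties broken lexicographically by feature name),
#' the ordering used by the correlation charts. Two delimiters split the
#' ordering, left to right, into significant downtrends, no-trend features,
#' and significant uptrends: `delimiter_down` counts the downtrend features
#' (it is the 0-based index of the first feature with `trend_call` other
#' than `down`), `delimiter_up` the downtrend plus no-trend features.
#'
#' @param trends data.frame of trend rows for a single sex (from
#'   [fit_trends()])
#' @return list with `ordered` (the sorted trend data.frame),
#'   `ordered_features`, `delimiter_down`, `delimiter_up`
#' @export
order_features <- function(trends) {
  if (anyDuplicated(trends$feature)) {
    am_stop("duplicate feature names in trend table (one sex at a time)",
            class = "agemarkers_schema_error")
  }
  ord <- trends[order(trends$slope_m, trends$feature), , drop = FALSE]
  rownames(ord) <- NULL
  list(ordered = ord,
       ordered_features = ord$feature,
       delimiter_down = sum(ord$trend_call == "down"),
       delimiter_up = sum(ord$trend_call != "up"))
}
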