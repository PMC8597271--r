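# Composite risk-score reproducibility: replicate probabilities are scaled to
# a 5-100 score grid (step 5), assigned a risk category by fixed cutoffs, and
# replicate categories are compared with each sample's consensus category.
# The scoring algorithm itself is pluggable: any deterministic mapping from
# the biomarker triplet to a probability plus a monotone probability-to-score
# table can be supplied.

SCORE_GRID <- seq(5, 100, by = 5)

#' Monotone probability-to-score lookup table
#'
#' Builds the step table mapping a predicted probability to the scaled score
#' grid 5, 10, ..., 100. Scores up to 45 cover probabilities below
#' `p_low`, scores 50--85 cover `[p_low, p_high)`, and 90--100 cover
#' probabilities from `p_high` upward, each band subdivided evenly (the top
#' band up to `p_top`). The band edges are configurable because the scaling
#' of any particular validated algorithm is proprietary; the defaults give a
#' realistic spread for simulation work.
#'
#' @param p_low probability at which scores enter the intermediate band.
#' @param p_high probability at which scores enter the high band.
#' @param p_top probability mapped to the top score.
#' @return data frame with `p_min` (lower probability bound, inclusive) and
#'   `score`, monotone non-decreasing.
#' @export
make_score_table <- function(p_low = 0.15, p_high = 0.25, p_top = 0.45) {
  if (!(0 < p_low && p_low < p_high && p_high < p_top && p_top <= 1)) {
    abort_iv("score table needs 0 < p_low < p_high < p_top <= 1",
             "immunoval_invalid_criteria")
  }
  p_min <- c(
    seq(0, p_low, length.out = 10)[1:9],          # scores 5..45
    seq(p_low, p_high, length.out = 9)[1:8],      # scores 50..85
    seq(p_high, p_top, length.out = 3)            # scores 90..100
  )
  data.frame(p_min = p_min, score = SCORE_GRID)
}

#' Scale probabilities onto the 5-100 score grid
#'
#' @param probability predicted probabilities in \[0, 1\].
#' @param table a monotone lookup table from [make_score_table()] (or any
#'   data frame with non-decreasing `p_min` and `score`).
#' @return Scaled scores (multiples of 5 in 5--100).
#' @export
scale_score <- function(probability, table = make_score_table()) {
  if (any(probability < 0 | probability > 1)) {
    abort_iv("probabilities must lie in [0, 1]", "immunoval_invalid_measurement")
  }
  if (is.unsorted(table$p_min) || is.unsorted(table$score)) {
    abort_iv("score table must be monotone", "immunoval_invalid_criteria")
  }
  idx <- findInterval(probability, table$p_min)
  idx[idx < 1] <- 1
  table$score[idx]
}

#' Assign a risk category to a scaled score
#'
#' Low for scores at or below the low cutoff (default 45), intermediate for
#' scores between the intermediate band limits (default 50--85), high above
#' (default > 85). On the 5-point grid the bands partition every attainable
#' score.
#'
#' @param scaled_score scores on the 5-point grid 5..100.
#' @param cutoffs a [criteria_config()].
#' @return factor with levels `low`, `intermediate`, `high`.
#' @export
assign_category <- function(scaled_score, cutoffs = criteria_config()) {
  if (!all(scaled_score %in% SCORE_GRID)) {
    abort_iv("scaled scores must be multiples of 5 in [5, 100]",
             "immunoval_invalid_score")
  }
  category_of_value(scaled_score, cutoffs)
}

# category of an arbitrary (possibly off-grid) score value, used for the
# consensus category of a mean score
category_of_value <- function(score, cutoffs = criteria_config()) {
  out <- ifelse(score <= cutoffs$risk_cutoff_low_max, "low",
                ifelse(score > cutoffs$risk_cutoff_int_max, "high",
                       "intermediate"))
  factor(out, levels = c("low", "intermediate", "high"))
}

#' Construct a replicate risk-score set
#'
#' One row per replicate measurement of a patient sample: the biomarker
#' triplet, the predicted probability, the scaled score and the category.
#' Scores and categories are derived from the probabilities when omitted.
#'
#' @param replicates data frame with columns `sample`, `probability`, and
#'   optionally `kim1`, `stnfr1`, `stnfr2`, `day`, `run`, `operator`, `lot`,
#'   `replicate`, `scaled_score`, `category`.
#' @param score_table lookup from [make_score_table()].
#' @param cutoffs a [criteria_config()].
#' @return A `risk_replicates` data frame with `scaled_score` and `category`
#'   filled in and validated (probabilities in \[0,1\], scores on the grid,
#'   categories consistent with the cutoffs).
#' @export
risk_replicates <- function(replicates, score_table = make_score_table(),
                            cutoffs = criteria_config()) {
  if (!all(c("sample", "probability") %in% names(replicates))) {
    abort_iv("replicates need columns sample, probability",
             "immunoval_schema_error")
  }
  if (any(replicates$probability < 0 | replicates$probability > 1)) {
    abort_iv("probabilities must lie in [0, 1]", "immunoval_invalid_measurement")
  }
  if (is.null(replicates$scaled_score)) {
    replicates$scaled_score <- scale_score(replicates$probability, score_table)
  }
  replicates$category <- assign_category(replicates$scaled_score, cutoffs)
  class(replicates) <- c("risk_replicates", "data.frame")
  replicates
}

#' Per-sample risk-score reproducibility summary
#'
#' For each sample: N, mean predicted probability, SD, and %CV (1 d.p.); the
#' overall reproducibility statistic is the arithmetic mean of the per-sample
#' CVs, rounded to 1 d.p.
#'
#' @param sets a `risk_replicates` data frame (>= 2 replicates per sample).
#' @return list with `per_sample` data frame and `overall_mean_cv`.
#' @export
score_cv_summary <- function(sets) {
  per <- do.call(rbind, lapply(split(sets$probability, sets$sample), function(p) {
    data.frame(n = length(p), mean_probability = mean(p),
               sd = stats::sd(p), cv = round_half_up(cv_percent(p), 1))
  }))
  per <- data.frame(sample = rownames(per), per, row.names = NULL)
  list(per_sample = per, overall_mean_cv = overall_mean_cv(per$cv))
}

#' Overall mean CV from per-sample CVs
#'
#' @param cvs per-sample CVs in percent.
#' @return Their arithmetic mean, rounded to 1 d.p.
#' @export
overall_mean_cv <- function(cvs) {
  round_half_up(mean(cvs), 1)
}

#' Risk-category concordance against the consensus category
#'
#' The consensus category of a sample is the category of its mean scaled
#' score; per-sample concordance is the percentage of replicates whose own
#' category matches the consensus, and the overall concordance pools matches
#' over all replicates of all samples.
#'
#' @param sets a `risk_replicates` data frame with `scaled_score` and
#'   `category` (>= 2 replicates per sample).
#' @param cutoffs a [criteria_config()].
#' @return list with `per_sample` (consensus category, N, matches,
#'   `concordance_percent`) and `overall_percent`.
#' @export
concordance <- function(sets, cutoffs = criteria_config()) {
  if (is.null(sets$scaled_score) || is.null(sets$category)) {
    abort_iv("replicates need scaled_score and category columns",
             "immunoval_schema_error")
  }
  by_sample <- split(sets, sets$sample)
  per <- do.call(rbind, lapply(names(by_sample), function(s) {
    d <- by_sample[[s]]
    if (nrow(d) < 2) {
      abort_iv("concordance needs >= 2 replicates per sample",
               "immunoval_insufficient_data")
    }
    consensus <- category_of_value(mean(d$scaled_score), cutoffs)
    matches <- sum(d$category == consensus)
    data.frame(sample = s, consensus = consensus, n = nrow(d),
               matches = matches,
               concordance_percent = 100 * matches / nrow(d))
  }))
  rownames(per) <- NULL
  list(per_sample = per,
       overall_percent = 100 * sum(per$matches) / sum(per$n))
}

#' Default pluggable score function for simulation
#'
#' A logistic function of the log biomarkers,
#' `plogis(b0 + b1 log(kim1) + b2 log(stnfr1) + b3 log(stnfr2))` -- a
#' deterministic stand-in used to exercise the reproducibility machinery on
#' synthetic data; it makes no claim about any validated clinical algorithm.
#' Default coefficients place typical panel concentrations in the 0.10--0.45
#' probability range.
#'
#' @param coef named numeric vector `c(b0, kim1, stnfr1, stnfr2)`.
#' @return function `(kim1, stnfr1, stnfr2) -> probability`.
#' @export
default_score_function <- function(coef = c(b0 = -9.6, kim1 = 0.35,
                                            stnfr1 = 0.35, stnfr2 = 0.35)) {
  force(coef)
  function(kim1, stnfr1, stnfr2) {
    stats::plogis(coef[["b0"]] + coef[["kim1"]] * log(kim1) +
                    coef[["stnfr1"]] * log(stnfr1) +
                    coef[["stnfr2"]] * log(stnfr2))
  }
}
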