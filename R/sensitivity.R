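# Detection limits by the classical approach: LoB from blanks, LoD from
# low-level samples, LoQ from a four-part criteria scan.

#' Small-sample 95th-percentile multiplier
#'
#' The Gaussian 95th-percentile multiplier 1.645 corrected for estimating the
#' SD from finite degrees of freedom: c_p = 1.645 / (1 - 1/(4 f)).
#'
#' @param f degrees of freedom (total observations minus number of pooled
#'   assays/samples).
#' @return The corrected multiplier.
#' @export
ep17_cp <- function(f) {
  if (any(f <= 0.25)) {
    abort_iv("degrees of freedom too small for the percentile correction",
             "immunoval_insufficient_data")
  }
  1.645 / (1 - 1 / (4 * f))
}

#' Limit of blank
#'
#' Estimates the concentration below which 95% of blank measurements fall.
#' Parametric: `LoB = mean_B + c_p * sd_B` with the pooled blank SD and
#' `f = n_B - K` degrees of freedom for `K` pooled assays. Nonparametric: the
#' interpolated 95th-percentile rank position of the sorted blanks. Blank
#' values are back-calculated blank-diluent results and may be negative.
#'
#' @param blanks numeric vector of blank determinations, or a list of vectors
#'   (one per assay) whose SDs are pooled.
#' @param method `"parametric"` or `"nonparametric"`.
#' @param min_n minimum total number of blank determinations (default 20).
#' @return LoB in pg/mL (in-well).
#' @export
limit_of_blank <- function(blanks, method = c("parametric", "nonparametric"),
                           min_n = 20) {
  method <- match.arg(method)
  groups <- if (is.list(blanks)) blanks else list(blanks)
  all_b <- unlist(groups)
  if (length(all_b) < min_n) {
    abort_iv(sprintf("need at least %d blank determinations, got %d",
                     min_n, length(all_b)),
             "immunoval_insufficient_data")
  }
  if (method == "nonparametric") {
    s <- sort(all_b)
    pos <- 0.5 + 0.95 * length(s)
    lo <- floor(pos); hi <- ceiling(pos)
    lo <- max(1, min(lo, length(s))); hi <- max(1, min(hi, length(s)))
    return(s[lo] + (pos - floor(pos)) * (s[hi] - s[lo]))
  }
  k <- length(groups)
  f <- length(all_b) - k
  ss <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  sd_b <- sqrt(ss / f)
  mean(all_b) + ep17_cp(f) * sd_b
}

#' Limit of detection
#'
#' `LoD = LoB + c_p * sd_L`, where `sd_L` is the pooled within-sample SD of
#' low-level samples measured near the LoB and `c_p` uses the pooled degrees
#' of freedom (total results minus number of samples).
#'
#' @param lob limit of blank (pg/mL).
#' @param low_levels list of numeric vectors, one per low-level sample.
#' @param min_samples minimum number of distinct low-level samples.
#' @return LoD in pg/mL (in-well).
#' @export
limit_of_detection <- function(lob, low_levels, min_samples = 4) {
  if (!is.list(low_levels)) low_levels <- list(low_levels)
  if (length(low_levels) < min_samples) {
    abort_iv(sprintf("need at least %d low-level samples, got %d",
                     min_samples, length(low_levels)),
             "immunoval_insufficient_data")
  }
  means <- vapply(low_levels, mean, numeric(1))
  if (lob > 0 && all(means > 10 * lob)) {
    warning("all low-level sample means exceed 10x LoB; ",
            "LoD may not reflect near-blank behaviour",
            call. = FALSE)
  }
  f <- sum(lengths(low_levels)) - length(low_levels)
  if (f < 1) {
    abort_iv("low-level samples provide no degrees of freedom",
             "immunoval_insufficient_data")
  }
  ss <- sum(vapply(low_levels, function(g) sum((g - mean(g))^2), numeric(1)))
  sd_l <- sqrt(ss / f)
  lob + ep17_cp(f) * sd_l
}

#' Scan candidate levels for the limits of quantification
#'
#' Applies the four-part quantification-limit rule to replicate measurements
#' of candidate concentration levels. A level passes the lower-limit scan
#' when its worst intra-plate replicate CV is below `loq_cv_max`, its mean
#' recovery lies inside the recovery band, and its mean signal is at least
#' `lloq_blank_signal_ratio_min` times the blank signal. It passes the
#' upper-limit scan when CV and recovery pass and its mean signal is at most
#' `uloq_top_signal_fraction_max` of the top-calibrator signal. LLoQ is the
#' larger of the LoD and the lowest level passing the low scan; ULoQ is the
#' highest level passing the high scan.
#'
#' @param candidates data frame with columns `level` (nominal pg/mL),
#'   `concentration` (back-calculated replicate results), `signal` (raw
#'   replicate signals) and optionally `plate` (intra-plate CVs are computed
#'   per plate and the worst plate governs).
#' @param blank_signal mean blank-diluent signal.
#' @param top_calibrator_signal observed signal at the highest calibrator.
#' @param lod limit of detection (pg/mL) restricting the LLoQ from below.
#' @param criteria a [criteria_config()].
#' @return list with `lloq`, `uloq`, `lloq_restricted_to_lod` flag and the
#'   per-level `criteria_evidence` table (CV, recovery, signal ratios, pass
#'   flags for every tested level).
#' @export
loq_scan <- function(candidates, blank_signal, top_calibrator_signal, lod,
                     criteria = criteria_config()) {
  need <- c("level", "concentration", "signal")
  if (!all(need %in% names(candidates))) {
    abort_iv("candidates need columns level, concentration, signal",
             "immunoval_schema_error")
  }
  if (is.null(candidates$plate)) candidates$plate <- 1L
  levels_ <- sort(unique(candidates$level))
  ev <- do.call(rbind, lapply(levels_, function(l) {
    d <- candidates[candidates$level == l, ]
    cv_by_plate <- vapply(split(d$concentration, d$plate), function(v) {
      if (length(v) >= 2) cv_percent(v) else NA_real_
    }, numeric(1))
    worst_cv <- max(cv_by_plate, na.rm = TRUE)
    rec <- recovery_percent(mean(d$concentration), l)
    msig <- mean(d$signal)
    data.frame(
      level = l, n = nrow(d), cv = worst_cv, recovery = rec,
      mean_signal = msig,
      blank_ratio = msig / blank_signal,
      top_fraction = msig / top_calibrator_signal
    )
  }))
  ev$pass_cv <- ev$cv < criteria$loq_cv_max
  ev$pass_recovery <- recovery_in_band(ev$recovery, criteria$loq_recovery_low,
                                       criteria$loq_recovery_high)
  ev$pass_blank_ratio <- ev$blank_ratio >= criteria$lloq_blank_signal_ratio_min
  ev$pass_top_fraction <- ev$top_fraction <= criteria$uloq_top_signal_fraction_max
  ev$pass_lloq <- ev$pass_cv & ev$pass_recovery & ev$pass_blank_ratio
  ev$pass_uloq <- ev$pass_cv & ev$pass_recovery & ev$pass_top_fraction

  if (!any(ev$pass_lloq) && !any(ev$pass_uloq)) {
    cond <- errorCondition(
      "no candidate level passes the quantification criteria",
      class = c("immunoval_no_quantifiable_range", "immunoval_error"),
      evidence = ev
    )
    stop(cond)
  }
  lloq <- if (any(ev$pass_lloq)) max(lod, min(ev$level[ev$pass_lloq])) else NA_real_
  uloq <- if (any(ev$pass_uloq)) max(ev$level[ev$pass_uloq]) else NA_real_
  list(
    lloq = lloq,
    uloq = uloq,
    lloq_restricted_to_lod = isTRUE(!is.na(lloq) && any(ev$pass_lloq) &&
                                      lod >= min(ev$level[ev$pass_lloq])),
    criteria_evidence = ev
  )
}

#' Assemble per-analyte detection limits
#'
#' Bundles LoB, LoD, LLoQ and ULoQ with their criteria evidence, enforcing
#' the ordering invariant `0 <= LoB <= LoD <= LLoQ < ULoQ`. When per-lot
#' results are supplied (lists named by lot), the reported limit is the
#' maximum across lots.
#'
#' @param analyte analyte label.
#' @param lob,lod numeric scalars or named vectors per lot.
#' @param lloq,uloq quantification limits (pg/mL).
#' @param method `"parametric"` or `"nonparametric"`.
#' @param criteria_evidence evidence table from [loq_scan()].
#' @return A `detection_limits` object; reported fields use the across-lot
#'   maximum, and per-lot values are retained.
#' @export
detection_limits <- function(analyte, lob, lod, lloq, uloq,
                             method = "parametric", criteria_evidence = NULL) {
  lob_r <- max(lob)
  lod_r <- max(lod)
  if (!(0 <= lob_r && lob_r <= lod_r && lod_r <= lloq && lloq < uloq)) {
    abort_iv(sprintf(
      "detection limits out of order for %s: LoB %.4g, LoD %.4g, LLoQ %.4g, ULoQ %.4g",
      analyte, lob_r, lod_r, lloq, uloq), "immunoval_limits_order")
  }
  structure(
    list(analyte = analyte, lob = lob_r, lod = lod_r, lloq = lloq,
         uloq = uloq, method = method,
         lob_by_lot = lob, lod_by_lot = lod,
         criteria_evidence = criteria_evidence),
    class = "detection_limits"
  )
}

#' @export
print.detection_limits <- function(x, ...) {
  cat(sprintf("%s detection limits (%s): LoB %.4g, LoD %.4g, LLoQ %.4g, ULoQ %.4g pg/mL\n",
              x$analyte, x$method, x$lob, x$lod, x$lloq, x$uloq))
  invisible(x)
}
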