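# Multiplex specificity: non-specific binding between analyte pairs,
# singleplex-vs-multiplex concordance, and interference recovery.

#' Non-specific binding percentage
#'
#' Blank-normalised non-specific signal as a percentage of the
#' blank-normalised specific signal:
#' `100 * (nonspecific - blank) / (specific - blank)`, floored at 0 (a
#' nonspecific signal at or below background means no measurable
#' cross-reactivity).
#'
#' @param specific_signal light counts on a detector spot from its own
#'   (target) analyte.
#' @param nonspecific_signal light counts on that spot from a non-target
#'   analyte.
#' @param blank_signal blank-diluent light counts on the spot.
#' @return NSB in percent (>= 0).
#' @export
nsb_percent <- function(specific_signal, nonspecific_signal, blank_signal) {
  if (any(specific_signal <= blank_signal)) {
    abort_iv("NSB undefined: specific signal must exceed blank signal",
             "immunoval_undefined_nsb")
  }
  pmax(0, 100 * (nonspecific_signal - blank_signal) /
         (specific_signal - blank_signal))
}

#' Singleplex vs multiplex concordance
#'
#' Pairs specimens measured with a single-analyte detection antibody
#' (singleplex) and with the blended multiplexed detection antibody, and
#' reports the per-specimen percentage difference
#' `100 * (multi - single) / single` of the specimen means, plus the mean and
#' maximum absolute difference. When a `day` column is present, the
#' inter-assay CV across days is also reported per specimen and format.
#'
#' @param singleplex,multiplex data frames with columns `specimen`,
#'   `concentration`, and optionally `day`.
#' @return list with `per_specimen` (single/multi means, `difference_percent`,
#'   optional per-format inter-assay CVs) and `summary`
#'   (`mean_difference_percent`, `max_abs_difference_percent`,
#'   `max_interassay_cv` when days are present).
#' @export
plex_concordance <- function(singleplex, multiplex) {
  for (d in list(singleplex, multiplex)) {
    if (!all(c("specimen", "concentration") %in% names(d))) {
      abort_iv("need columns specimen, concentration", "immunoval_schema_error")
    }
  }
  s_spec <- unique(singleplex$specimen)
  m_spec <- unique(multiplex$specimen)
  orphans <- c(setdiff(s_spec, m_spec), setdiff(m_spec, s_spec))
  if (length(orphans)) {
    abort_iv(paste0("unpaired specimens: ", paste(orphans, collapse = ", ")),
             "immunoval_pairing_error")
  }
  if (length(s_spec) < 2) {
    abort_iv("need >= 2 paired specimens", "immunoval_insufficient_data")
  }
  agg <- function(d) {
    means <- tapply(d$concentration, d$specimen, mean)
    cvs <- if (!is.null(d$day)) {
      tapply(d$concentration, d$specimen, function(v) {
        if (length(v) >= 2) cv_percent(v) else NA_real_
      })
    } else {
      NULL
    }
    list(means = means, cvs = cvs)
  }
  s <- agg(singleplex)
  m <- agg(multiplex)
  spec <- sort(s_spec)
  per <- data.frame(
    specimen = spec,
    single_mean = as.numeric(s$means[as.character(spec)]),
    multi_mean = as.numeric(m$means[as.character(spec)])
  )
  per$difference_percent <- 100 * (per$multi_mean - per$single_mean) /
    per$single_mean
  if (!is.null(s$cvs)) {
    per$single_interassay_cv <- as.numeric(s$cvs[as.character(spec)])
    per$multi_interassay_cv <- as.numeric(m$cvs[as.character(spec)])
  }
  summary <- list(
    mean_difference_percent = mean(per$difference_percent),
    max_abs_difference_percent = max(abs(per$difference_percent))
  )
  if (!is.null(s$cvs)) {
    summary$max_interassay_cv <- max(c(per$single_interassay_cv,
                                       per$multi_interassay_cv), na.rm = TRUE)
  }
  list(per_specimen = per, summary = summary)
}

#' Interference recovery record
#'
#' Computes spiked/mixed-sample recovery against the dilution-corrected
#' expectation. For a direct spike of an interfering substance into a plasma
#' sample the analyte expectation is the baseline concentration; for a 1:1
#' mix of two plasmas (e.g. an antibody-positive specimen mixed with a
#' patient sample) the expectation is the mean of the two baselines. The pass
#' flag applies the 80--120% recovery band.
#'
#' @param baseline_conc analyte concentration of the (primary) unspiked
#'   plasma, > 0.
#' @param measured_conc concentration measured after spiking/mixing.
#' @param mixing `"direct_spike"` or `"one_to_one_mix"`.
#' @param partner_baseline_conc baseline of the second plasma for a 1:1 mix.
#' @param substance,spiked_level optional metadata (interferent label and
#'   spiked amount in its own units).
#' @return An `interference_record` data frame row: substance, spiked level,
#'   baseline, measured and expected concentrations, `recovery_percent`, and
#'   `pass`.
#' @export
interference_recovery <- function(baseline_conc, measured_conc,
                                  mixing = c("direct_spike", "one_to_one_mix"),
                                  partner_baseline_conc = NULL,
                                  substance = NA_character_,
                                  spiked_level = NA_real_) {
  mixing <- match.arg(mixing)
  if (any(baseline_conc <= 0)) {
    abort_iv("baseline concentration must be > 0", "immunoval_invalid_expected")
  }
  expected <- if (mixing == "one_to_one_mix") {
    if (is.null(partner_baseline_conc)) {
      abort_iv("1:1 mix requires the partner plasma's baseline concentration",
               "immunoval_design_error")
    }
    (baseline_conc + partner_baseline_conc) / 2
  } else {
    baseline_conc
  }
  rec <- recovery_percent(measured_conc, expected)
  out <- data.frame(
    substance = substance, spiked_level = spiked_level,
    mixing = mixing,
    baseline_conc = baseline_conc, measured_conc = measured_conc,
    expected_conc = expected,
    recovery_percent = rec,
    pass = recovery_in_band(rec)
  )
  class(out) <- c("interference_record", "data.frame")
  out
}
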