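# 4PL calibration: signal = lower + (upper - lower) / (1 + (c50 / conc)^slope)
# Monotone increasing in concentration for slope > 0; the analytic inverse is
# conc = c50 * ((signal - lower) / (upper - signal))^(1 / slope).

fourpl <- function(conc, lower, upper, c50, slope) {
  lower + (upper - lower) / (1 + (c50 / conc)^slope)
}

fourpl_inverse <- function(signal, lower, upper, c50, slope) {
  c50 * ((signal - lower) / (upper - signal))^(1 / slope)
}

#' Fit a four-parameter logistic calibration curve
#'
#' Fits the sigmoid signal--concentration model to the 7-point standards of
#' one analyte by weighted nonlinear least squares (Levenberg--Marquardt via
#' \pkg{minpack.lm}) with multi-start initialisation: asymptotes seeded from
#' the extreme signals (the blank signal, when given, anchors the lower
#' asymptote), the inflection from the geometric mid-concentration, and a
#' grid of starting slopes. The default weighting 1/signal^2 reflects the
#' roughly concentration-proportional noise of electrochemiluminescence
#' readouts; alternatives are selectable to match instrument software.
#'
#' @param concentration calibrator concentrations, strictly increasing, > 0.
#' @param signal raw light counts at each calibrator (same length).
#' @param weighting one of `"inverse_signal_squared"`, `"inverse_signal"`,
#'   `"none"`.
#' @param blank_signal optional blank-diluent signal; not a curve point, used
#'   to seed the lower asymptote and retained for the quantification-limit
#'   blank-ratio rule.
#' @param analyte optional analyte label carried into the fit object.
#' @param monotone_tol fractional tolerance for the monotonicity check of
#'   level-mean signals; a drop larger than this triggers a fit-quality error.
#' @return A `calibration_fit` with fields `lower_asymptote`,
#'   `upper_asymptote`, `inflection`, `slope`, `weighting`,
#'   `per_level_recovery` (back-calculated recovery of every calibrator
#'   level, %), `converged`, `residual_norm` and `blank_signal`.
#' @export
fit_curve <- function(concentration, signal,
                      weighting = c("inverse_signal_squared",
                                    "inverse_signal", "none"),
                      blank_signal = NULL, analyte = NA_character_,
                      monotone_tol = 0.2) {
  weighting <- match.arg(weighting)
  if (length(concentration) != length(signal)) {
    abort_iv("concentration and signal lengths differ", "immunoval_schema_error")
  }
  if (any(signal < 0)) {
    abort_iv("signals must be >= 0", "immunoval_invalid_measurement")
  }
  lev <- sort(unique(concentration))
  if (length(lev) < 5) {
    abort_iv("need at least 5 distinct non-blank calibrator levels",
             "immunoval_incomplete_curve")
  }
  if (any(lev <= 0)) {
    abort_iv("calibrator concentrations must be > 0 (blank is not a curve point)",
             "immunoval_invalid_measurement")
  }
  mean_sig <- vapply(lev, function(l) mean(signal[concentration == l]),
                     numeric(1))
  drops <- diff(mean_sig) < -monotone_tol * mean_sig[-length(mean_sig)]
  if (any(drops)) {
    abort_iv("calibrator signals are non-monotone beyond noise tolerance",
             "immunoval_fit_quality")
  }

  w <- switch(weighting,
              none = rep(1, length(signal)),
              inverse_signal = 1 / pmax(signal, 1e-8),
              inverse_signal_squared = 1 / pmax(signal, 1e-8)^2)

  lower0 <- if (!is.null(blank_signal)) mean(blank_signal) else min(mean_sig)
  lower0 <- max(lower0, 1e-6)
  upper0 <- max(mean_sig) * 1.05
  c50_0 <- exp(mean(log(range(lev))))
  starts <- expand.grid(b = c(0.6, 1, 1.4, 2),
                        cmult = c(0.3, 1, 3))
  dat <- data.frame(conc = concentration, sig = signal)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- list(lower = lower0, upper = upper0,
               c50 = c50_0 * starts$cmult[i], slope = starts$b[i])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        sig ~ fourpl(conc, lower, upper, c50, slope),
        data = dat, start = st, weights = w,
        lower = c(lower = 0, upper = 1e-6, c50 = 1e-12, slope = 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(w * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    abort_iv("4PL fit failed to converge from any start",
             "immunoval_convergence")
  }
  p <- as.list(stats::coef(best$fit))
  if (p$upper <= p$lower) {
    abort_iv(sprintf("4PL fit degenerate (upper %.3g <= lower %.3g); best residual %.3g",
                     p$upper, p$lower, best$rss),
             "immunoval_convergence")
  }
  fit_obj <- structure(
    list(analyte = analyte,
         lower_asymptote = p$lower, upper_asymptote = p$upper,
         inflection = p$c50, slope = p$slope,
         weighting = weighting,
         converged = TRUE, residual_norm = best$rss,
         blank_signal = if (is.null(blank_signal)) NA_real_ else mean(blank_signal),
         calibrators = data.frame(concentration = concentration, signal = signal)),
    class = "calibration_fit"
  )
  bc <- backcalculate(fit_obj, mean_sig)
  fit_obj$per_level_recovery <- data.frame(
    concentration = lev,
    mean_signal = mean_sig,
    backcalculated = bc$concentration,
    recovery = recovery_percent(bc$concentration, lev)
  )
  fit_obj
}

#' Predicted signal of a calibration fit
#'
#' @param fit a `calibration_fit`.
#' @param concentration concentrations (pg/mL), > 0.
#' @return Predicted raw signals.
#' @export
predict_signal <- function(fit, concentration) {
  fourpl(concentration, fit$lower_asymptote, fit$upper_asymptote,
         fit$inflection, fit$slope)
}

#' Back-calculate concentrations from signals
#'
#' Applies the analytic inverse of the fitted sigmoid and multiplies by the
#' dilution factor. Signals at or below the lower asymptote, or at or above
#' the upper asymptote, yield an absent concentration (`NA`) flagged
#' `below_curve` / `above_curve` -- never zero -- so downstream stages must
#' handle missingness explicitly.
#'
#' @param fit a converged `calibration_fit`.
#' @param signal raw signals.
#' @param dilution_factor dilution correction (>= 1); in-well quantities use 1.
#' @return data frame with `signal`, `concentration` (pg/mL or `NA`) and
#'   `flag` in `{"ok", "below_curve", "above_curve"}`.
#' @export
backcalculate <- function(fit, signal, dilution_factor = 1) {
  if (!isTRUE(fit$converged)) {
    abort_iv("back-calculation requires a converged fit",
             "immunoval_convergence")
  }
  flag <- rep("ok", length(signal))
  flag[signal <= fit$lower_asymptote] <- "below_curve"
  flag[signal >= fit$upper_asymptote] <- "above_curve"
  conc <- rep(NA_real_, length(signal))
  ok <- flag == "ok"
  conc[ok] <- dilution_factor * fourpl_inverse(
    signal[ok], fit$lower_asymptote, fit$upper_asymptote,
    fit$inflection, fit$slope
  )
  data.frame(signal = signal, concentration = conc, flag = flag)
}

#' Back-calculate every measurement on a plate
#'
#' Fits a calibration curve per analyte from the plate's own calibrators and
#' blank, then back-calculates each row's concentration with its dilution
#' factor (calibrators and blanks are back-calculated in-well).
#'
#' @param plate a `plate_run`.
#' @param weighting passed to [fit_curve()].
#' @return The plate with `concentration` and `curve_flag` columns filled in,
#'   plus a `fits` attribute (list of `calibration_fit` per analyte).
#' @export
backcalculate_plate <- function(plate, weighting = "inverse_signal_squared") {
  m <- plate$measurements
  m$concentration <- NA_real_
  m$curve_flag <- NA_character_
  fits <- list()
  for (a in unique(m$analyte)) {
    idx <- m$analyte == a
    cal <- m[idx & m$role == "calibrator", ]
    blk <- m[idx & m$role == "blank", ]
    fit <- fit_curve(cal$expected_conc, cal$signal, weighting = weighting,
                     blank_signal = blk$signal, analyte = a)
    fits[[a]] <- fit
    dil <- ifelse(m$role[idx] %in% c("calibrator", "blank"), 1, m$dilution[idx])
    bc <- backcalculate(fit, m$signal[idx])
    m$concentration[idx] <- bc$concentration * dil
    m$curve_flag[idx] <- bc$flag
  }
  plate$measurements <- m
  attr(plate, "fits") <- fits
  plate
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("4PL fit%s: lower %.4g, upper %.4g, inflection %.4g pg/mL, slope %.4g (weighting %s)\n",
              if (is.na(x$analyte)) "" else paste0(" [", x$analyte, "]"),
              x$lower_asymptote, x$upper_asymptote, x$inflection, x$slope,
              x$weighting))
  cat(sprintf("  weighted RSS %.4g; per-level recovery %.1f-%.1f%%\n",
              x$residual_norm, min(x$per_level_recovery$recovery),
              max(x$per_level_recovery$recovery)))
  invisible(x)
}
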