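# Mixing-design linearity: a high pool is mixed into a low pool at known
# fractions, measured concentrations are regressed on the expected mixture
# values by weighted least squares, and levels whose deviation from the line
# exceeds the allowable deviation are trimmed from the extremes.

DEFAULT_MIX_FRACTIONS <- c(0, 0.025, 0.05, 0.10, 0.20, 0.30, 0.40, 0.50,
                           0.60, 0.70, 0.80, 0.90, 1.0)

#' Build a high/low pool mixing series
#'
#' Expected concentration at mixing fraction `f` of the high pool is
#' `f * high + (1 - f) * low`. The default 13 fractions run 0%, 2.5%, 5%,
#' 10%, then 10%-steps to 100% of the high pool.
#'
#' @param high_pool_value,low_pool_value pool concentrations, `high > low >= 0`.
#' @param fractions strictly increasing fractions in \[0, 1\] including 0 and 1.
#' @return A `mix_series` with `fractions` and `expected` per level.
#' @export
build_mix_series <- function(high_pool_value, low_pool_value,
                             fractions = DEFAULT_MIX_FRACTIONS) {
  if (high_pool_value <= low_pool_value || low_pool_value < 0) {
    abort_iv("pools must satisfy high > low >= 0", "immunoval_invalid_pools")
  }
  if (is.unsorted(fractions, strictly = TRUE) ||
      fractions[1] != 0 || fractions[length(fractions)] != 1) {
    abort_iv("fractions must be strictly increasing and include 0 and 1",
             "immunoval_invalid_pools")
  }
  structure(
    list(high_pool_value = high_pool_value,
         low_pool_value = low_pool_value,
         fractions = fractions,
         expected = fractions * high_pool_value +
           (1 - fractions) * low_pool_value),
    class = "mix_series"
  )
}

wls_fit <- function(expected, measured, weights) {
  f <- stats::lm(measured ~ expected, weights = weights)
  stats::coef(f)
}

level_deviations <- function(series_expected, level_stats, weights_per_level,
                             rep_expected, rep_measured, rep_weights) {
  cf <- wls_fit(rep_expected, rep_measured, rep_weights)
  fitted <- cf[1] + cf[2] * level_stats$expected
  data.frame(
    level_stats,
    fitted = fitted,
    deviation_percent = 100 * (level_stats$mean_measured - fitted) / fitted,
    row.names = NULL
  )
}

#' Assess linearity of a mixing series
#'
#' Fits measured concentration on expected concentration by weighted least
#' squares with an intercept over the replicate measurements, computes each
#' level's percentage deviation of its replicate mean from the fitted line,
#' and trims levels violating the allowable deviation `adl_delta` from the
#' extremes (re-fitting after each trim by default) until a contiguous run of
#' at least 4 passing levels remains. Default weights are the inverse
#' replicate variance per level, falling back to `1/expected^2` for levels
#' with zero variance (or under `weighting = "inverse_expected_squared"`).
#'
#' @param series a [build_mix_series()] result.
#' @param measurements data frame with `fraction` (matching the series) and
#'   `measured` (one row per replicate); the design uses 5 replicates/level.
#' @param adl_delta allowable deviation from linearity, % (default from
#'   [criteria_config()]).
#' @param weighting `"inverse_level_variance"` or `"inverse_expected_squared"`.
#' @param iterative re-fit after every trim (`TRUE`, default) or evaluate all
#'   levels against the single initial fit (`FALSE`).
#' @return A `linearity_result`: `slope`, `intercept` (final fit),
#'   `per_level` table with deviations and `retained` flags,
#'   `linear_interval` (expected-concentration endpoints of the retained
#'   run), and `max_abs_deviation_percent` over retained levels.
#' @export
assess_linearity <- function(series, measurements,
                             adl_delta = criteria_config()$adl_delta,
                             weighting = c("inverse_level_variance",
                                           "inverse_expected_squared"),
                             iterative = TRUE) {
  weighting <- match.arg(weighting)
  if (!all(c("fraction", "measured") %in% names(measurements))) {
    abort_iv("measurements need columns fraction, measured",
             "immunoval_schema_error")
  }
  idx <- match(measurements$fraction, series$fractions)
  if (anyNA(idx)) {
    abort_iv("measurement fractions not found in the mix series",
             "immunoval_schema_error")
  }
  measurements$expected <- series$expected[idx]
  lev_split <- split(measurements$measured, measurements$expected)
  lev_expected <- as.numeric(names(lev_split))
  o <- order(lev_expected)
  lev_expected <- lev_expected[o]
  lev_split <- lev_split[o]
  n_lev <- length(lev_expected)
  if (n_lev < 4 || sum(lengths(lev_split) >= 2) < 4) {
    abort_iv("linearity needs >= 4 levels with >= 2 replicates each",
             "immunoval_insufficient_design")
  }
  lev_stats <- data.frame(
    expected = lev_expected,
    n = lengths(lev_split),
    mean_measured = vapply(lev_split, mean, numeric(1)),
    var_measured = vapply(lev_split, function(v) stats::var(v), numeric(1))
  )
  floor_e <- min(lev_expected[lev_expected > 0]) / 10
  w_level <- if (weighting == "inverse_expected_squared") {
    1 / pmax(lev_stats$expected, floor_e)^2
  } else {
    ifelse(lev_stats$var_measured > 0, 1 / lev_stats$var_measured,
           1 / pmax(lev_stats$expected, floor_e)^2)
  }

  retained <- rep(TRUE, n_lev)
  trim_order <- integer(0)
  repeat {
    keep <- which(retained)
    if (length(keep) < 4) {
      abort_iv("fewer than 4 levels remain within the allowable deviation",
               "immunoval_nonlinear_assay")
    }
    rows <- measurements$expected %in% lev_expected[keep]
    rep_w <- w_level[match(measurements$expected[rows], lev_expected)]
    dev_tab <- level_deviations(lev_expected[keep], lev_stats[keep, ],
                                w_level[keep],
                                measurements$expected[rows],
                                measurements$measured[rows], rep_w)
    fails <- abs(dev_tab$deviation_percent) > adl_delta
    if (!any(fails)) break
    at_low <- fails[1]
    at_high <- fails[length(fails)]
    if (!at_low && !at_high) {
      cond <- errorCondition(
        "interior level(s) exceed the allowable deviation; no contiguous linear interval",
        class = c("immunoval_nonlinear_assay", "immunoval_error"),
        per_level = dev_tab
      )
      stop(cond)
    }
    drop_side <- if (at_low && at_high) {
      if (abs(dev_tab$deviation_percent[1]) >=
          abs(dev_tab$deviation_percent[length(fails)])) "low" else "high"
    } else if (at_low) "low" else "high"
    drop_idx <- if (drop_side == "low") keep[1] else keep[length(keep)]
    retained[drop_idx] <- FALSE
    trim_order <- c(trim_order, drop_idx)
    if (!iterative) {
      # one-pass: keep the initial fit, drop every failing extreme inward
      dev_all <- dev_tab$deviation_percent
      keep_rel <- seq_along(keep)
      lo <- 1; hi <- length(keep)
      while (lo < hi && abs(dev_all[lo]) > adl_delta) lo <- lo + 1
      while (hi > lo && abs(dev_all[hi]) > adl_delta) hi <- hi - 1
      retained[] <- FALSE
      retained[keep[lo:hi]] <- TRUE
      keep <- which(retained)
      if (length(keep) < 4) {
        abort_iv("fewer than 4 levels remain within the allowable deviation",
                 "immunoval_nonlinear_assay")
      }
      interior <- dev_all[lo:hi]
      if (any(abs(interior) > adl_delta)) {
        abort_iv("interior level(s) exceed the allowable deviation",
                 "immunoval_nonlinear_assay")
      }
      break
    }
  }

  keep <- which(retained)
  rows <- measurements$expected %in% lev_expected[keep]
  rep_w <- w_level[match(measurements$expected[rows], lev_expected)]
  cf <- wls_fit(measurements$expected[rows], measurements$measured[rows], rep_w)
  fitted_all <- cf[1] + cf[2] * lev_stats$expected
  per_level <- data.frame(
    lev_stats,
    fitted = fitted_all,
    deviation_percent = 100 * (lev_stats$mean_measured - fitted_all) / fitted_all,
    retained = retained,
    row.names = NULL
  )
  structure(
    list(slope = unname(cf[2]), intercept = unname(cf[1]),
         per_level = per_level,
         adl_delta = adl_delta,
         linear_interval = range(lev_expected[keep]),
         max_abs_deviation_percent =
           max(abs(per_level$deviation_percent[retained])),
         trimmed_levels = lev_expected[!retained],
         weighting = weighting),
    class = "linearity_result"
  )
}

#' @export
print.linearity_result <- function(x, ...) {
  cat(sprintf("Linearity: interval %.4g-%.4g pg/mL, slope %.4g, intercept %.4g\n",
              x$linear_interval[1], x$linear_interval[2], x$slope, x$intercept))
  cat(sprintf("  max |deviation| %.2f%% (allowable %.1f%%); %d level(s) trimmed\n",
              x$max_abs_deviation_percent, x$adl_delta,
              length(x$trimmed_levels)))
  invisible(x)
}
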