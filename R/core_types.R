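# Domain constants -------------------------------------------------------

#' Analytes of the three-biomarker kidney panel
#'
#' The panel measures plasma kidney injury molecule-1 (KIM-1) and the soluble
#' tumour necrosis factor receptors 1 and 2 in a single multiplexed well.
#' @export
ANALYTES <- c("KIM1", "sTNFR1", "sTNFR2")

#' Well roles recognised on a plate map
#' @export
ROLES <- c("calibrator", "blank", "qc", "sample", "spiked_sample")

PLATE_COLUMNS <- c(
  "plate_id", "well", "spot", "analyte", "role", "sample_label", "signal",
  "day", "run", "operator", "lot", "replicate", "dilution", "expected_conc"
)

# Elementary statistics ---------------------------------------------------

#' Coefficient of variation in percent
#'
#' `cv_percent()` computes 100 * SD / mean from raw replicate values using the
#' sample standard deviation (n - 1 denominator). `cv_from_stats()` computes
#' the same quantity from an already-summarised mean and SD, as needed when
#' reworking printed summary tables.
#'
#' @param values numeric vector of at least two replicate measurements.
#' @param mean,sd summary statistics of a replicate set.
#' @return The CV as a percentage (not rounded).
#' @examples
#' cv_percent(c(1, 2, 3))        # 50
#' cv_from_stats(3633, 98.7)     # 2.716...
#' @export
cv_percent <- function(values) {
  if (length(values) < 2) {
    abort_iv("CV requires at least 2 values", "immunoval_insufficient_data")
  }
  m <- mean(values)
  if (m == 0) {
    abort_iv("CV undefined: mean of values is zero", "immunoval_undefined_cv")
  }
  100 * stats::sd(values) / m
}

#' @rdname cv_percent
#' @export
cv_from_stats <- function(mean, sd) {
  if (any(mean == 0)) {
    abort_iv("CV undefined: mean is zero", "immunoval_undefined_cv")
  }
  100 * sd / mean
}

#' Recovery of a measured concentration against its expected value
#'
#' Recovery = 100 * measured / expected; the validation pass band is
#' 80--120% throughout the package.
#'
#' @param measured measured concentration (pg/mL).
#' @param expected expected (nominal) concentration, strictly positive.
#' @return Recovery in percent.
#' @export
recovery_percent <- function(measured, expected) {
  if (any(expected <= 0)) {
    abort_iv("recovery undefined: expected concentration must be > 0",
             "immunoval_invalid_expected")
  }
  100 * measured / expected
}

#' Is a recovery inside the acceptance band?
#'
#' @param recovery recovery in percent.
#' @param low,high band limits in percent (defaults 80 and 120).
#' @return logical vector.
#' @export
recovery_in_band <- function(recovery, low = 80, high = 120) {
  recovery >= low & recovery <= high
}

# Criteria configuration --------------------------------------------------

#' Acceptance criteria and risk-category cutoffs
#'
#' Bundles the tunable pass/fail criteria used across the validation suite:
#' the four-part quantification-limit rule (replicate CV ceiling, recovery
#' band, blank-signal multiple for the lower limit, top-calibrator signal
#' fraction for the upper limit), the allowable deviation from linearity, and
#' the scaled risk-score category cutoffs (low <= 45; intermediate 50--85;
#' high > 85).
#'
#' @param loq_cv_max intra-plate CV ceiling (%) at the quantification limits.
#' @param loq_recovery_low,loq_recovery_high recovery band (%) at the limits.
#' @param lloq_blank_signal_ratio_min minimum mean-signal / blank-signal ratio
#'   at the lower limit of quantification.
#' @param uloq_top_signal_fraction_max maximum mean signal as a fraction of
#'   the top calibrator signal at the upper limit.
#' @param adl_delta allowable deviation from linearity (%).
#' @param risk_cutoff_low_max largest scaled score called low risk.
#' @param risk_cutoff_int_min,risk_cutoff_int_max scaled-score range called
#'   intermediate risk; anything above `risk_cutoff_int_max` is high risk.
#' @return An object of class `criteria_config`.
#' @export
criteria_config <- function(loq_cv_max = 10,
                            loq_recovery_low = 80,
                            loq_recovery_high = 120,
                            lloq_blank_signal_ratio_min = 3,
                            uloq_top_signal_fraction_max = 0.70,
                            adl_delta = 15,
                            risk_cutoff_low_max = 45,
                            risk_cutoff_int_min = 50,
                            risk_cutoff_int_max = 85) {
  cfg <- list(
    loq_cv_max = loq_cv_max,
    loq_recovery_low = loq_recovery_low,
    loq_recovery_high = loq_recovery_high,
    lloq_blank_signal_ratio_min = lloq_blank_signal_ratio_min,
    uloq_top_signal_fraction_max = uloq_top_signal_fraction_max,
    adl_delta = adl_delta,
    risk_cutoff_low_max = risk_cutoff_low_max,
    risk_cutoff_int_min = risk_cutoff_int_min,
    risk_cutoff_int_max = risk_cutoff_int_max
  )
  if (!(0 < cfg$loq_recovery_low && cfg$loq_recovery_low < 100 &&
        100 < cfg$loq_recovery_high)) {
    abort_iv("recovery band must satisfy 0 < low < 100 < high",
             "immunoval_invalid_criteria")
  }
  if (!(cfg$uloq_top_signal_fraction_max > 0 &&
        cfg$uloq_top_signal_fraction_max < 1)) {
    abort_iv("top-calibrator signal fraction must be in (0, 1)",
             "immunoval_invalid_criteria")
  }
  if (!(cfg$risk_cutoff_low_max < cfg$risk_cutoff_int_min &&
        cfg$risk_cutoff_int_min <= cfg$risk_cutoff_int_max)) {
    abort_iv("risk cutoffs must satisfy low_max < int_min <= int_max",
             "immunoval_invalid_criteria")
  }
  structure(lapply(cfg, as.numeric), class = "criteria_config")
}

#' Read a criteria configuration from a YAML file
#'
#' Keys are the arguments of [criteria_config()]; any key omitted keeps its
#' default. Reports echoing criteria should echo the object returned here.
#'
#' @param path path to a YAML file.
#' @return A `criteria_config`.
#' @export
read_criteria_config <- function(path) {
  if (!file.exists(path)) {
    abort_iv(paste0("criteria file not found: ", path), "immunoval_io_error")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(criteria_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort_iv(paste0("unknown criteria keys: ", paste(unknown, collapse = ", ")),
             "immunoval_invalid_criteria")
  }
  do.call(criteria_config, vals)
}

#' @export
print.criteria_config <- function(x, ...) {
  cat("Validation acceptance criteria:\n")
  cat(sprintf("  LoQ: CV < %g%%, recovery %g-%g%%, LLoQ signal >= %gx blank, ULoQ signal <= %g%% of top calibrator\n",
              x$loq_cv_max, x$loq_recovery_low, x$loq_recovery_high,
              x$lloq_blank_signal_ratio_min,
              100 * x$uloq_top_signal_fraction_max))
  cat(sprintf("  Linearity: allowable deviation %g%%\n", x$adl_delta))
  cat(sprintf("  Risk categories: low <= %g, intermediate %g-%g, high > %g\n",
              x$risk_cutoff_low_max, x$risk_cutoff_int_min,
              x$risk_cutoff_int_max, x$risk_cutoff_int_max))
  invisible(x)
}

# PlateRun ----------------------------------------------------------------

#' Construct a plate run
#'
#' A plate run is one physical plate's worth of well-level measurements plus
#' the design annotations (day, run, operator, lot) shared by the plate. The
#' measurement table has one row per (well, spot): `well` ("A1".."H12"),
#' `spot` (1--10), `analyte`, `role`, `sample_label`, `signal` (raw light
#' counts), `dilution` (>= 1) and `expected_conc` (pg/mL; required for
#' calibrators, QCs and spiked samples, `NA` otherwise). A `concentration`
#' column is added by back-calculation and may be absent.
#'
#' @param plate_id plate label.
#' @param design named list with `day`, `run`, `operator`, `lot`.
#' @param measurements data frame as described above.
#' @return A validated object of class `plate_run`.
#' @export
plate_run <- function(plate_id, design, measurements) {
  for (k in c("day", "run")) design[[k]] <- as.numeric(design[[k]])
  for (k in c("spot", "signal", "replicate", "dilution", "expected_conc")) {
    if (!is.null(measurements[[k]])) {
      measurements[[k]] <- as.numeric(measurements[[k]])
    }
  }
  x <- structure(
    list(plate_id = as.character(plate_id),
         design = design,
         measurements = measurements),
    class = "plate_run"
  )
  validate_plate_run(x)
}

#' Validate a plate run's invariants
#'
#' Checks the plate-map invariants: non-negative signals, dilution factors
#' >= 1, valid wells and spots, no duplicate (well, spot), and per analyte at
#' least 7 distinct calibrator levels, a blank, and 4 distinct QC samples.
#'
#' @param x a `plate_run`.
#' @return `x`, invisibly for chaining, if valid; otherwise a classed error.
#' @export
validate_plate_run <- function(x) {
  m <- x$measurements
  need <- c("well", "spot", "analyte", "role", "sample_label", "signal",
            "dilution", "expected_conc")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols)) {
    abort_iv(paste0("measurements missing columns: ",
                    paste(missing_cols, collapse = ", ")),
             "immunoval_schema_error")
  }
  for (k in c("day", "run")) {
    if (is.null(x$design[[k]]) || x$design[[k]] < 1) {
      abort_iv(paste0("design ", k, " must be a positive index"),
               "immunoval_schema_error")
    }
  }
  if (any(m$signal < 0, na.rm = TRUE)) {
    abort_iv("signals must be >= 0", "immunoval_invalid_measurement")
  }
  if (any(m$dilution < 1, na.rm = TRUE)) {
    abort_iv("dilution factors must be >= 1", "immunoval_invalid_measurement")
  }
  bad_role <- setdiff(unique(m$role), ROLES)
  if (length(bad_role)) {
    abort_iv(paste0("unknown roles: ", paste(bad_role, collapse = ", ")),
             "immunoval_invalid_measurement")
  }
  if (!all(grepl("^[A-H](1[0-2]|[1-9])$", m$well))) {
    abort_iv("wells must be plate coordinates A1..H12",
             "immunoval_invalid_measurement")
  }
  if (!all(m$spot %in% 1:10)) {
    abort_iv("spot indices must be 1..10", "immunoval_invalid_measurement")
  }
  needs_expected <- m$role %in% c("calibrator", "qc", "spiked_sample")
  if (any(is.na(m$expected_conc[needs_expected]))) {
    abort_iv("calibrator/qc/spiked rows need an expected concentration",
             "immunoval_invalid_measurement")
  }
  if (any(m$expected_conc < 0, na.rm = TRUE)) {
    abort_iv("expected concentrations must be >= 0",
             "immunoval_invalid_measurement")
  }
  key <- paste(m$well, m$spot)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    abort_iv(paste0("duplicate (well, spot): ", paste(dup, collapse = "; ")),
             "immunoval_duplicate_well")
  }
  for (a in unique(m$analyte)) {
    ma <- m[m$analyte == a, ]
    n_cal <- length(unique(ma$expected_conc[ma$role == "calibrator"]))
    if (n_cal < 7) {
      abort_iv(sprintf("analyte %s: %d calibrator levels found, need >= 7",
                       a, n_cal), "immunoval_incomplete_curve")
    }
    if (!any(ma$role == "blank")) {
      abort_iv(sprintf("analyte %s: no blank on plate", a),
               "immunoval_incomplete_curve")
    }
    n_qc <- length(unique(ma$sample_label[ma$role == "qc"]))
    if (n_qc < 4) {
      abort_iv(sprintf("analyte %s: %d QC samples found, need >= 4", a, n_qc),
               "immunoval_invalid_measurement")
    }
  }
  invisible(x)
}

#' @export
print.plate_run <- function(x, ...) {
  m <- x$measurements
  cat(sprintf("Plate %s (day %s, run %s, operator %s, lot %s): %d wells x spots, %d analytes\n",
              x$plate_id, x$design$day, x$design$run,
              x$design$operator %||% "?", x$design$lot %||% "?",
              nrow(m), length(unique(m$analyte))))
  cat("  roles:", paste(sprintf("%s=%d", names(table(m$role)), table(m$role)),
                        collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Plate file I/O ----------------------------------------------------------

#' Read a delimited plate-run file
#'
#' The file is delimited text (comma by default, tab accepted via `sep`) with
#' a mandatory header naming the columns `plate_id, well, spot, analyte,
#' role, sample_label, signal, day, run, operator, lot, replicate, dilution,
#' expected_conc`. Rows with unparseable numerics are rejected with
#' row-numbered diagnostics; the resulting plate is validated against all
#' plate-map invariants.
#'
#' @param path path to the file.
#' @param sep field separator, `","` or `"\t"`.
#' @return A `plate_run`.
#' @export
read_plate_file <- function(path, sep = ",") {
  if (!file.exists(path)) {
    abort_iv(paste0("plate file not found: ", path), "immunoval_io_error")
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character())
  missing_cols <- setdiff(PLATE_COLUMNS, names(raw))
  if (length(missing_cols)) {
    abort_iv(paste0("plate file missing required columns: ",
                    paste(missing_cols, collapse = ", ")),
             "immunoval_schema_error")
  }
  num_cols <- c("spot", "signal", "day", "run", "replicate", "dilution",
                "expected_conc")
  parsed <- raw
  for (cn in num_cols) {
    v <- raw[[cn]]
    v[v == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) {
      abort_iv(sprintf("column '%s': unparseable numeric in data row(s) %s",
                       cn, paste(bad, collapse = ", ")),
               "immunoval_parse_error")
    }
    if (cn != "expected_conc" && anyNA(num)) {
      abort_iv(sprintf("column '%s': missing value in data row(s) %s",
                       cn, paste(which(is.na(num)), collapse = ", ")),
               "immunoval_parse_error")
    }
    parsed[[cn]] <- num
  }
  plate_id <- unique(parsed$plate_id)
  if (length(plate_id) != 1) {
    abort_iv("plate file must contain exactly one plate_id",
             "immunoval_schema_error")
  }
  for (cn in c("day", "run", "operator", "lot")) {
    if (length(unique(parsed[[cn]])) != 1) {
      abort_iv(sprintf("design column '%s' must be constant across a plate", cn),
               "immunoval_schema_error")
    }
  }
  design <- list(day = parsed$day[1], run = parsed$run[1],
                 operator = parsed$operator[1], lot = parsed$lot[1])
  meas <- parsed[, c("well", "spot", "analyte", "role", "sample_label",
                     "signal", "replicate", "dilution", "expected_conc")]
  rownames(meas) <- NULL
  plate_run(plate_id, design, meas)
}

#' Write a plate run to a delimited file
#'
#' Numeric fields are written with full precision so that
#' `read_plate_file(write_plate_file(x))` reproduces `x` exactly.
#'
#' @param x a `plate_run`.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_plate_file <- function(x, path, sep = ",") {
  m <- x$measurements
  out <- data.frame(
    plate_id = x$plate_id,
    well = m$well,
    spot = fmt_num(m$spot),
    analyte = m$analyte,
    role = m$role,
    sample_label = m$sample_label,
    signal = fmt_num(m$signal),
    day = fmt_num(rep(x$design$day, nrow(m))),
    run = fmt_num(rep(x$design$run, nrow(m))),
    operator = x$design$operator,
    lot = x$design$lot,
    replicate = fmt_num(m$replicate),
    dilution = fmt_num(m$dilution),
    expected_conc = fmt_num(m$expected_conc),
    check.names = FALSE
  )
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
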