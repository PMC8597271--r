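# Seeded synthetic-data generator. Every input the validation modules need
# (plate runs, precision datasets, blank/low-level panels, mixing series,
# paired singleplex/multiplex sets, risk-replicate sets) is generated from a
# known ground truth with a hierarchical multiplicative noise model:
# signals (or concentrations) are scaled by lognormal factor effects drawn
# once per design-factor level, plus lognormal replicate noise, so that each
# requested CV component is realised exactly in expectation. A small additive
# Gaussian floor keeps blank signals from being noiseless.

cv_to_sdlog <- function(cv) sqrt(log(1 + (cv / 100)^2))

# mean-one lognormal factors
ln_factor <- function(n, cv) {
  s <- cv_to_sdlog(cv)
  exp(stats::rnorm(n, -s^2 / 2, s))
}

#' Ground truth for the synthetic assay
#'
#' Defines the simulated instrument: per-analyte 4PL curve parameters, the
#' 7-level calibrator series, QC and sample concentrations anchored to
#' realistic panel magnitudes, the hierarchical CV components (lot, operator,
#' day, run, replicate, in percent), a 3x3 crosstalk matrix of fractional
#' signal bleed between analytes, the additive blank floor SD, and the seed.
#'
#' @param fourpl named list per analyte of `c(lower, upper, c50, slope)`.
#' @param calibrators named list per analyte of 7 increasing concentrations.
#' @param qc named list per analyte of 4 QC concentrations.
#' @param samples named list per analyte of true sample concentrations.
#' @param cv_components named vector `c(lot, operator, day, run, rep)` in %.
#' @param crosstalk 3x3 matrix, entries in \[0, 0.05\], zero diagonal:
#'   `crosstalk[i, j]` is the fraction of analyte `j`'s signal bleeding onto
#'   analyte `i`'s spot.
#' @param blank_floor_sd additive signal floor SD (light counts).
#' @param seed default seed for the simulators.
#' @return A validated `sim_truth` object.
#' @export
sim_truth <- function(
    fourpl = list(
      KIM1   = c(lower = 120, upper = 2.5e5, c50 = 800,   slope = 1.1),
      sTNFR1 = c(lower = 150, upper = 6.0e5, c50 = 6000,  slope = 1.1),
      sTNFR2 = c(lower = 150, upper = 8.0e5, c50 = 15000, slope = 1.1)
    ),
    calibrators = list(
      KIM1 = 10000 / 4^(6:0),
      sTNFR1 = 50000 / 4^(6:0),
      sTNFR2 = 150000 / 4^(6:0)
    ),
    qc = list(
      KIM1 = c(20, 200, 1000, 4000),
      sTNFR1 = c(300, 2000, 10000, 30000),
      sTNFR2 = c(1000, 8000, 30000, 80000)
    ),
    samples = list(
      KIM1 = c(3633, 1957, 1177, 669, 443, 109, 24),
      sTNFR1 = c(18550, 17364, 10214, 4970, 3415, 2359, 1541),
      sTNFR2 = c(50809, 34280, 30055, 23239, 15150, 7727, 6057)
    ),
    cv_components = c(lot = 3, operator = 2, day = 6, run = 2, rep = 3),
    crosstalk = matrix(0, 3, 3, dimnames = list(ANALYTES, ANALYTES)),
    blank_floor_sd = 0.5,
    seed = 1L) {
  if (any(cv_components < 0)) {
    abort_iv("CV components must be >= 0", "immunoval_invalid_truth")
  }
  if (any(crosstalk < 0 | crosstalk > 0.05) || any(diag(crosstalk) != 0)) {
    abort_iv("crosstalk entries must lie in [0, 0.05] with zero diagonal",
             "immunoval_invalid_truth")
  }
  if (!all(c("lot", "operator", "day", "run", "rep") %in%
           names(cv_components))) {
    abort_iv("cv_components needs lot, operator, day, run, rep",
             "immunoval_invalid_truth")
  }
  structure(
    list(fourpl = fourpl, calibrators = calibrators, qc = qc,
         samples = samples, cv_components = cv_components,
         crosstalk = crosstalk, blank_floor_sd = blank_floor_sd,
         seed = as.integer(seed)),
    class = "sim_truth"
  )
}

truth_signal <- function(truth, analyte, conc) {
  p <- truth$fourpl[[analyte]]
  ifelse(conc <= 0, p[["lower"]],
         fourpl(conc, p[["lower"]], p[["upper"]], p[["c50"]], p[["slope"]]))
}

#' Simulate one plate run
#'
#' Lays out a 96-well plate holding, per analyte (spots 1--3 of the 10-spot
#' array), a blank, the 7-point calibrator series, 4 QC samples and replicate
#' wells of the true samples. Signals are the 4PL response scaled by
#' lognormal lot / operator / day / run effects (drawn once per plate) and
#' per-well replicate noise; crosstalk adds the configured fraction of each
#' other analyte's specific signal; the additive floor is applied last.
#'
#' @param truth a [sim_truth()].
#' @param design named list with `day`, `run`, `operator`, `lot`.
#' @param n_sample_reps replicate wells per sample (default 2).
#' @param seed RNG seed (default `truth$seed`).
#' @return A validated `plate_run`.
#' @export
simulate_plate_run <- function(truth, design = list(day = 1, run = 1,
                                                    operator = "OP1",
                                                    lot = "LOT1"),
                               n_sample_reps = 2, seed = truth$seed) {
  with_seed(seed, {
    cv <- truth$cv_components
    analytes <- names(truth$fourpl)
    # one effect per varying factor per plate, one per analyte
    eff <- vapply(analytes, function(a) {
      prod(ln_factor(1, cv[["lot"]]), ln_factor(1, cv[["operator"]]),
           ln_factor(1, cv[["day"]]), ln_factor(1, cv[["run"]]))
    }, numeric(1))

    wells <- paste0(rep(LETTERS[1:8], times = 12),
                    rep(1:12, each = 8))
    rows <- list()
    wi <- 0
    add_well <- function(role, label, conc_by_analyte, expected_by_analyte,
                         replicate = 1) {
      wi <<- wi + 1
      if (wi > length(wells)) {
        abort_iv("plate layout exceeds 96 wells", "immunoval_invalid_truth")
      }
      specific <- vapply(seq_along(analytes), function(i) {
        a <- analytes[i]
        truth_signal(truth, a, conc_by_analyte[i]) * eff[i] *
          ln_factor(1, cv[["rep"]])
      }, numeric(1))
      bled <- specific + as.numeric(truth$crosstalk %*% specific)
      sig <- pmax(0, bled + stats::rnorm(length(analytes), 0,
                                         truth$blank_floor_sd))
      rows[[length(rows) + 1]] <<- data.frame(
        well = wells[wi], spot = as.numeric(seq_along(analytes)),
        analyte = analytes,
        role = role, sample_label = label, signal = sig,
        replicate = as.numeric(replicate), dilution = 1,
        expected_conc = expected_by_analyte
      )
    }

    add_well("blank", "BLANK", rep(0, length(analytes)),
             rep(0, length(analytes)))
    for (k in 1:7) {
      conc <- vapply(analytes, function(a) truth$calibrators[[a]][k],
                     numeric(1))
      add_well("calibrator", paste0("CAL", k), conc, conc)
    }
    for (k in 1:4) {
      conc <- vapply(analytes, function(a) truth$qc[[a]][k], numeric(1))
      add_well("qc", paste0("QC", k), conc, conc)
    }
    n_samples <- length(truth$samples[[1]])
    for (s in seq_len(n_samples)) {
      conc <- vapply(analytes, function(a) truth$samples[[a]][s], numeric(1))
      for (r in seq_len(n_sample_reps)) {
        add_well("sample", paste0("S", s), conc, rep(NA_real_,
                                                     length(analytes)),
                 replicate = r)
      }
    }
    plate_run(sprintf("SIM-D%s-R%s", design$day, design$run), design,
              do.call(rbind, rows))
  })
}

#' Simulate a precision study dataset
#'
#' Generates replicate concentrations for every sample of the truth under
#' either the nested repeatability design (days x runs/day x replicates/run;
#' only day, run and replicate components act) or the multi-factor
#' within-laboratory design (two operators alternating runs within a day,
#' days split evenly across lots, every component acting). Concentrations
#' are the true value scaled by mean-one lognormal effects per factor level,
#' so the generated per-factor CVs equal the truth's components.
#'
#' @param truth a [sim_truth()].
#' @param design_kind `"nested_day_run_rep"` or `"multifactor"`.
#' @param analyte which analyte's sample panel to use.
#' @param n_days,n_runs,n_reps design dimensions (defaults: 20x2x2 nested,
#'   10x2x5 multifactor).
#' @param n_operators,n_lots multifactor factor sizes (2 each; `n_days` must
#'   split evenly across lots).
#' @param seed RNG seed.
#' @return A `precision_dataset`.
#' @export
simulate_precision_study <- function(truth,
                                     design_kind = c("nested_day_run_rep",
                                                     "multifactor"),
                                     analyte = "KIM1",
                                     n_days = NULL, n_runs = 2, n_reps = NULL,
                                     n_operators = 2, n_lots = 2,
                                     seed = truth$seed) {
  design_kind <- match.arg(design_kind)
  nested <- design_kind == "nested_day_run_rep"
  if (is.null(n_days)) n_days <- if (nested) 20 else 10
  if (is.null(n_reps)) n_reps <- if (nested) 2 else 5
  if (!nested && n_days %% n_lots != 0) {
    abort_iv("multifactor design needs days split evenly across lots",
             "immunoval_design_error")
  }
  cv <- truth$cv_components
  concs <- truth$samples[[analyte]]
  with_seed(seed, {
    recs <- lapply(seq_along(concs), function(s) {
      lot_eff <- ln_factor(n_lots, if (nested) 0 else cv[["lot"]])
      op_eff <- ln_factor(n_operators, if (nested) 0 else cv[["operator"]])
      day_eff <- ln_factor(n_days, cv[["day"]])
      run_eff <- ln_factor(n_days * n_runs, cv[["run"]])
      g <- expand.grid(replicate = seq_len(n_reps), run = seq_len(n_runs),
                       day = seq_len(n_days))
      lot_of_day <- ((g$day - 1) %/% (n_days / n_lots)) + 1
      op_of_run <- ((g$run - 1) %% n_operators) + 1
      run_id <- (g$day - 1) * n_runs + g$run
      fac <- day_eff[g$day] * run_eff[run_id] *
        (if (nested) 1 else lot_eff[lot_of_day] * op_eff[op_of_run]) *
        ln_factor(nrow(g), cv[["rep"]])
      data.frame(
        sample = paste0(if (nested) "R" else "P", s),
        analyte = analyte,
        day = g$day, run = g$run, replicate = g$replicate,
        operator = paste0("OP", op_of_run),
        lot = paste0("LOT", lot_of_day),
        concentration = concs[s] * fac
      )
    })
    precision_dataset(do.call(rbind, recs), design_kind)
  })
}

#' Simulate blank determinations
#'
#' Back-calculated blank-diluent results near zero: additive Gaussian,
#' allowing negative values as real blank back-calculations do.
#'
#' @param n blanks per assay.
#' @param mean,sd blank distribution parameters (pg/mL).
#' @param n_assays number of assays (returned as a list when > 1).
#' @param seed RNG seed.
#' @return numeric vector, or list of vectors when `n_assays > 1`.
#' @export
simulate_blank_panel <- function(n = 25, mean = 0.1, sd = 0.2, n_assays = 1,
                                 seed = 1L) {
  with_seed(seed, {
    out <- lapply(seq_len(n_assays), function(i) stats::rnorm(n, mean, sd))
    if (n_assays == 1) out[[1]] else out
  })
}

#' Simulate low-level sample panels for LoD estimation
#'
#' @param means true concentrations of the low-level samples (pg/mL).
#' @param n_reps replicates per sample.
#' @param sd within-sample SD (recycled across samples).
#' @param seed RNG seed.
#' @return list of replicate vectors, one per sample.
#' @export
simulate_low_level_panel <- function(means, n_reps = 5, sd = 0.5, seed = 1L) {
  sd <- rep_len(sd, length(means))
  with_seed(seed, {
    lapply(seq_along(means), function(i) {
      stats::rnorm(n_reps, means[i], sd[i])
    })
  })
}

#' Simulate candidate-level replicates for a quantification-limit scan
#'
#' Replicate back-calculated concentrations (lognormal around each level) and
#' the matching raw signals through the truth's 4PL curve.
#'
#' @param truth a [sim_truth()].
#' @param analyte analyte name.
#' @param levels candidate concentrations (pg/mL).
#' @param n_reps replicates per level.
#' @param cv replicate CV in percent.
#' @param seed RNG seed.
#' @return list with `candidates` (data frame for [loq_scan()]),
#'   `blank_signal` and `top_calibrator_signal`.
#' @export
simulate_loq_candidates <- function(truth, analyte = "KIM1", levels,
                                    n_reps = 5, cv = 5, seed = truth$seed) {
  with_seed(seed, {
    cand <- do.call(rbind, lapply(levels, function(l) {
      conc <- l * ln_factor(n_reps, cv)
      data.frame(level = l, plate = 1L, concentration = conc,
                 signal = truth_signal(truth, analyte, conc))
    }))
    list(
      candidates = cand,
      blank_signal = truth$fourpl[[analyte]][["lower"]],
      top_calibrator_signal =
        truth_signal(truth, analyte, max(truth$calibrators[[analyte]]))
    )
  })
}

#' Simulate replicate measurements of a mixing series
#'
#' Measured concentrations are the expected mixture values under lognormal
#' replicate noise; an optional saturation suppresses the top (100% high
#' pool) level by a fixed fraction to emulate an assay running out of linear
#' range.
#'
#' @param series a [build_mix_series()].
#' @param n_reps replicates per level (5 in the reference design).
#' @param cv replicate CV in percent.
#' @param saturation_top fractional suppression of the top level (e.g. 0.25
#'   measures the top level 25% low); 0 disables.
#' @param seed RNG seed.
#' @return data frame with `fraction`, `expected`, `measured` (one row per
#'   replicate).
#' @export
simulate_mix_measurements <- function(series, n_reps = 5, cv = 3,
                                      saturation_top = 0, seed = 1L) {
  with_seed(seed, {
    do.call(rbind, lapply(seq_along(series$fractions), function(i) {
      f <- series$fractions[i]
      e <- series$expected[i]
      mu <- if (i == length(series$fractions)) e * (1 - saturation_top) else e
      data.frame(fraction = f, expected = e,
                 measured = mu * ln_factor(n_reps, cv))
    }))
  })
}

#' Simulate a non-specific binding panel
#'
#' For every source analyte, simulates a specimen containing only that
#' analyte at its top calibrator concentration and records, for every other
#' analyte's detector spot, the specific signal (the spot's own analyte at
#' top concentration), the nonspecific signal (background plus the
#' crosstalk bleed from the source analyte) and the blank signal, each under
#' lognormal signal noise.
#'
#' @param truth a [sim_truth()].
#' @param noise_cv signal CV in percent.
#' @param seed RNG seed.
#' @return data frame of NSB records: `target`, `source`, `specific_signal`,
#'   `nonspecific_signal`, `blank_signal`, `nsb_percent`.
#' @export
simulate_nsb_panel <- function(truth, noise_cv = 2, seed = truth$seed) {
  analytes <- names(truth$fourpl)
  with_seed(seed, {
    top_sig <- vapply(analytes, function(a) {
      truth_signal(truth, a, max(truth$calibrators[[a]]))
    }, numeric(1))
    base_sig <- vapply(analytes, function(a) {
      truth$fourpl[[a]][["lower"]]
    }, numeric(1))
    out <- list()
    for (j in seq_along(analytes)) {
      source_specific <- top_sig[j] * ln_factor(1, noise_cv)
      for (i in seq_along(analytes)) {
        if (i == j) next
        specific <- top_sig[i] * ln_factor(1, noise_cv)
        nonspec <- base_sig[i] * ln_factor(1, noise_cv) +
          truth$crosstalk[i, j] * source_specific
        blank <- base_sig[i] * ln_factor(1, noise_cv)
        out[[length(out) + 1]] <- data.frame(
          target = analytes[i], source = analytes[j],
          specific_signal = specific, nonspecific_signal = nonspec,
          blank_signal = blank,
          nsb_percent = nsb_percent(specific, nonspec, blank)
        )
      }
    }
    do.call(rbind, out)
  })
}

#' Simulate paired singleplex / multiplex specimen sets
#'
#' Specimens share a true concentration; singleplex and multiplex
#' measurements get independent lognormal noise per day.
#'
#' @param true_concs true specimen concentrations.
#' @param n_days testing days (measurements per specimen per format).
#' @param cv measurement CV in percent.
#' @param seed RNG seed.
#' @return list with `singleplex` and `multiplex` data frames
#'   (`specimen`, `day`, `concentration`).
#' @export
simulate_plex_pairs <- function(true_concs, n_days = 5, cv = 4, seed = 1L) {
  with_seed(seed, {
    mk <- function() {
      do.call(rbind, lapply(seq_along(true_concs), function(i) {
        data.frame(specimen = paste0("SP", i), day = seq_len(n_days),
                   concentration = true_concs[i] * ln_factor(n_days, cv))
      }))
    }
    list(singleplex = mk(), multiplex = mk())
  })
}

#' Default patient panel for risk-score simulation
#'
#' Ten biomarker triplets spanning the panel's score range along an
#' increasing severity axis, chosen so the [default_score_function()] yields
#' probabilities from about 0.13 to 0.43 (one low, six intermediate, three
#' high sample under the default score table and cutoffs).
#'
#' @return data frame with `sample`, `kim1`, `stnfr1`, `stnfr2`.
#' @export
default_risk_panel <- function() {
  t <- c(0.781, 1.070, 1.135, 1.254, 1.310, 1.365, 1.470, 1.750, 2.040, 2.270)
  data.frame(
    sample = paste0("S", seq_along(t)),
    kim1 = 40 * exp(1.5 * t),
    stnfr1 = 1600 * exp(0.8 * t),
    stnfr2 = 5000 * exp(0.8 * t)
  )
}

#' Simulate replicate risk-score sets
#'
#' Emulates the reproducibility design: each patient sample measured in
#' duplicate, 2 runs/day over `n_days` days, two operators (one run per
#' operator per day) and two reagent lots rotated between them. Biomarker
#' replicates get the hierarchical noise model per analyte; probabilities,
#' scaled scores and categories are then computed through the pluggable
#' score function and table.
#'
#' @param truth a [sim_truth()] (its CV components drive the noise).
#' @param panel data frame like [default_risk_panel()].
#' @param score_function deterministic `(kim1, stnfr1, stnfr2) -> probability`.
#' @param score_table monotone lookup from [make_score_table()].
#' @param cutoffs a [criteria_config()].
#' @param n_days,n_runs,n_dups design dimensions (defaults 5 x 2 x 2 = 20
#'   replicates per sample).
#' @param seed RNG seed.
#' @return A `risk_replicates` data frame.
#' @export
simulate_risk_replicates <- function(truth, panel = default_risk_panel(),
                                     score_function = default_score_function(),
                                     score_table = make_score_table(),
                                     cutoffs = criteria_config(),
                                     n_days = 5, n_runs = 2, n_dups = 2,
                                     seed = truth$seed) {
  cv <- truth$cv_components
  with_seed(seed, {
    reps <- do.call(rbind, lapply(seq_len(nrow(panel)), function(s) {
      g <- expand.grid(replicate = seq_len(n_dups), run = seq_len(n_runs),
                       day = seq_len(n_days))
      run_id <- (g$day - 1) * n_runs + g$run
      op <- g$run                        # one run per operator per day
      lot <- ((g$day + g$run) %% 2) + 1  # lots rotated between operators
      val <- function(true) {
        day_eff <- ln_factor(n_days, cv[["day"]])
        run_eff <- ln_factor(n_days * n_runs, cv[["run"]])
        op_eff <- ln_factor(2, cv[["operator"]])
        lot_eff <- ln_factor(2, cv[["lot"]])
        true * day_eff[g$day] * run_eff[run_id] * op_eff[op] *
          lot_eff[lot] * ln_factor(nrow(g), cv[["rep"]])
      }
      data.frame(
        sample = panel$sample[s],
        day = g$day, run = g$run, replicate = g$replicate,
        operator = paste0("OP", op), lot = paste0("LOT", lot),
        kim1 = val(panel$kim1[s]),
        stnfr1 = val(panel$stnfr1[s]),
        stnfr2 = val(panel$stnfr2[s])
      )
    }))
    reps$probability <- score_function(reps$kim1, reps$stnfr1, reps$stnfr2)
    risk_replicates(reps, score_table, cutoffs)
  })
}
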