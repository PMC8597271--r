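# Precision variance components for two study designs:
#  - nested day/run/replicate repeatability study (ANOVA method-of-moments)
#  - multi-factor within-laboratory study with operators and reagent lots
#    (REML; day nested in lot, operator crossed)

#' Construct a precision dataset
#'
#' @param records data frame with columns `sample`, `concentration`, `day`,
#'   `run`, `replicate`, and for the multi-factor design also `operator` and
#'   `lot`; `analyte` is optional metadata.
#' @param design_kind `"nested_day_run_rep"` or `"multifactor"`.
#' @return A `precision_dataset` (the validated data frame with a
#'   `design_kind` attribute).
#' @export
precision_dataset <- function(records,
                              design_kind = c("nested_day_run_rep",
                                              "multifactor")) {
  design_kind <- match.arg(design_kind)
  need <- c("sample", "concentration", "day", "run", "replicate")
  if (design_kind == "multifactor") need <- c(need, "operator", "lot")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    abort_iv(paste0("precision records missing columns: ",
                    paste(missing_cols, collapse = ", ")),
             "immunoval_schema_error")
  }
  structure(records, design_kind = design_kind, class = c("precision_dataset",
                                                          "data.frame"))
}

mom_nested <- function(day, run, value) {
  day <- as.character(day)
  run_in_day <- paste(day, run, sep = ":")
  n_day <- length(unique(day))
  cells <- split(value, run_in_day)
  reps <- lengths(cells)
  n_rep <- reps[1]
  n_run <- length(unique(run))
  grand <- mean(value)

  # within-run (repeatability) mean square
  ss_within <- sum(vapply(cells, function(v) sum((v - mean(v))^2), numeric(1)))
  df_within <- sum(reps - 1)
  ms_within <- ss_within / df_within

  cell_means <- vapply(cells, mean, numeric(1))
  cell_day <- sub(":.*$", "", names(cells))
  day_means <- tapply(value, day, mean)

  ss_run <- n_rep * sum((cell_means - day_means[cell_day])^2)
  df_run <- n_day * (n_run - 1)
  ms_run <- ss_run / df_run

  ss_day <- n_run * n_rep * sum((day_means - grand)^2)
  df_day <- n_day - 1
  ms_day <- ss_day / df_day

  truncated <- character(0)
  s2_rep <- ms_within
  s2_run <- (ms_run - ms_within) / n_rep
  if (s2_run < 0) { s2_run <- 0; truncated <- c(truncated, "run") }
  s2_day <- (ms_day - ms_run) / (n_run * n_rep)
  if (s2_day < 0) { s2_day <- 0; truncated <- c(truncated, "day") }
  list(components = c(rep = unname(s2_rep), run = unname(s2_run),
                      day = unname(s2_day)),
       mean = grand, truncated = truncated,
       mean_squares = c(within = unname(ms_within), run = unname(ms_run),
                        day = unname(ms_day)))
}

make_vc <- function(components, mean, estimator, truncated,
                    n = NA_integer_, sample = NA_character_) {
  s2_within_lab <- sum(components)
  structure(
    list(sample = sample, n = n,
         components = components,
         sigma2_rep = unname(components["rep"]),
         sigma2_within_lab = s2_within_lab,
         mean = mean,
         cv_repeatability = 100 * sqrt(components[["rep"]]) / mean,
         cv_within_lab = 100 * sqrt(s2_within_lab) / mean,
         estimator = estimator,
         truncated_components = truncated),
    class = "variance_components"
  )
}

#' Estimate variance components for the nested repeatability design
#'
#' ANOVA method-of-moments decomposition of the day / run-within-day /
#' replicate nesting (the 20 days x 2 runs x 2 replicates repeatability
#' design): `sigma2_rep = MS_within`, `sigma2_run = (MS_run(day) -
#' MS_within) / n_rep`, `sigma2_day = (MS_day - MS_run(day)) / (n_run *
#' n_rep)`. Negative estimates are truncated to zero and recorded. Data
#' missing more than 10% of the design cells fall back to REML with a
#' warning.
#'
#' @param dataset a `precision_dataset` (or plain data frame) with columns
#'   `day`, `run`, `replicate`, `concentration`.
#' @param sample optional sample label carried into the result.
#' @return A `variance_components` object: per-factor variances (pg/mL)^2,
#'   grand mean, repeatability and within-laboratory CVs (% of the grand
#'   mean), estimator used, and any truncated components.
#' @export
estimate_nested <- function(dataset, sample = NA_character_) {
  d <- as.data.frame(dataset)
  if (length(unique(d$day)) < 2) {
    abort_iv("nested design needs >= 2 days", "immunoval_insufficient_design")
  }
  runs_per_day <- tapply(d$run, d$day, function(r) length(unique(r)))
  reps_per_cell <- as.vector(table(paste(d$day, d$run)))
  if (any(runs_per_day < 2) || max(reps_per_cell) < 2) {
    abort_iv("nested design needs >= 2 runs/day and >= 2 replicates/run",
             "immunoval_insufficient_design")
  }
  balanced <- length(unique(reps_per_cell)) == 1 &&
    length(unique(runs_per_day)) == 1 && min(reps_per_cell) >= 2
  if (!balanced) {
    warning("unbalanced nested layout; falling back to REML", call. = FALSE)
    return(reml_nested(d, sample))
  }
  est <- mom_nested(d$day, d$run, d$concentration)
  make_vc(est$components, est$mean, "anova_mom", est$truncated,
          n = nrow(d), sample = sample)
}

reml_nested <- function(d, sample = NA_character_) {
  d$day_f <- factor(d$day)
  d$run_f <- factor(paste(d$day, d$run, sep = ":"))
  fit <- lme4::lmer(concentration ~ 1 + (1 | day_f) + (1 | run_f), data = d,
                    REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- c(
    rep = vc$vcov[vc$grp == "Residual"],
    run = vc$vcov[vc$grp == "run_f"],
    day = vc$vcov[vc$grp == "day_f"]
  )
  make_vc(comp, mean(d$concentration), "reml",
          names(comp)[comp < 1e-10 & names(comp) != "rep"],
          n = nrow(d), sample = sample)
}

#' Estimate variance components for the multi-factor design
#'
#' REML fit (via \pkg{lme4}) of a variance-components model with random
#' effects for reagent lot, operator (crossed), day nested in lot, and run
#' nested in day, with the residual as the within-run (repeatability)
#' component. This mirrors a within-laboratory study in which two operators
#' run two lots rotated over the study days. Boundary (zero) estimates are
#' reported as 0. Factors with a single level are dropped from the model; if
#' nothing but day/run/replicate varies the model collapses to the nested
#' estimator. Non-convergence falls back to the method-of-moments nested
#' collapse with a warning.
#'
#' @param dataset a `precision_dataset` with columns `day`, `run`,
#'   `replicate`, `operator`, `lot`, `concentration`.
#' @param sample optional sample label.
#' @return A `variance_components` with components among
#'   `rep, run, day, operator, lot`.
#' @export
estimate_multifactor <- function(dataset, sample = NA_character_) {
  d <- as.data.frame(dataset)
  need <- c("day", "run", "operator", "lot", "concentration")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    abort_iv(paste0("multifactor records missing columns: ",
                    paste(missing_cols, collapse = ", ")),
             "immunoval_schema_error")
  }
  d$lot_f <- factor(d$lot)
  d$op_f <- factor(d$operator)
  d$day_f <- factor(paste(d$lot, d$day, sep = ":"))
  d$run_f <- factor(paste(d$lot, d$day, d$run, sep = ":"))
  terms <- c(
    if (nlevels(d$lot_f) > 1) "(1 | lot_f)",
    if (nlevels(d$op_f) > 1) "(1 | op_f)",
    if (nlevels(d$day_f) > 1) "(1 | day_f)",
    if (nlevels(d$run_f) > 1) "(1 | run_f)"
  )
  if (is.null(terms)) {
    abort_iv("no varying design factor in multifactor dataset",
             "immunoval_insufficient_design")
  }
  form <- stats::as.formula(paste("concentration ~ 1 +",
                                  paste(terms, collapse = " + ")))
  fit <- tryCatch(
    lme4::lmer(form, data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warning("REML did not converge; method-of-moments on the day/run/rep collapse",
            call. = FALSE)
    est <- mom_nested(d$day_f, d$run, d$concentration)
    return(make_vc(est$components, est$mean, "anova_mom",
                   c(est$truncated, "operator", "lot"),
                   n = nrow(d), sample = sample))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else NULL
  }
  comp <- c(rep = get_vc("Residual"))
  for (nm in c("run", "day", "operator", "lot")) {
    g <- switch(nm, run = "run_f", day = "day_f", operator = "op_f",
                lot = "lot_f")
    v <- get_vc(g)
    if (!is.null(v)) comp[nm] <- v
  }
  boundary <- names(comp)[comp < 1e-10 & names(comp) != "rep"]
  make_vc(comp, mean(d$concentration), "reml", boundary,
          n = nrow(d), sample = sample)
}

#' Estimate components for every sample of a precision study
#'
#' @param dataset a `precision_dataset` covering one analyte.
#' @return Named list of `variance_components`, one per sample.
#' @export
estimate_precision <- function(dataset) {
  kind <- attr(dataset, "design_kind") %||% "nested_day_run_rep"
  d <- as.data.frame(dataset)
  out <- lapply(split(d, d$sample), function(ds) {
    if (kind == "multifactor") {
      estimate_multifactor(ds, sample = ds$sample[1])
    } else {
      estimate_nested(ds, sample = ds$sample[1])
    }
  })
  out[order(names(out))]
}

#' Summarise per-sample precision against the measuring interval
#'
#' Builds the per-sample precision table (N, mean, SD, %CV to 1 d.p.) from a
#' set of variance-component estimates, excluding samples whose grand mean
#' lies outside the analytical measuring interval \[LLoQ, ULoQ\] (their rows
#' are retained but rendered with `NA` statistics and flagged). The SD column
#' is the within-laboratory SD for REML fits and the repeatability SD
#' otherwise, matching the design that produced the estimates.
#'
#' @param vc_by_sample list of `variance_components` (from
#'   [estimate_precision()]).
#' @param ami optional measuring interval `c(lloq, uloq)` in pg/mL.
#' @param which `"within_lab"` or `"repeatability"`; default picks
#'   within-laboratory SD for REML estimates.
#' @return data frame with per-sample rows and attributes `cv_min`,
#'   `cv_max`, `cv_mean` over retained samples.
#' @export
precision_summary <- function(vc_by_sample, ami = NULL, which = NULL) {
  rows <- lapply(vc_by_sample, function(v) {
    use_wl <- if (is.null(which)) v$estimator == "reml" else which == "within_lab"
    sdv <- sqrt(if (use_wl) v$sigma2_within_lab else v$sigma2_rep)
    cv <- if (use_wl) v$cv_within_lab else v$cv_repeatability
    excluded <- !is.null(ami) && (v$mean < ami[1] || v$mean > ami[2])
    data.frame(
      sample = v$sample, n = v$n,
      mean = if (excluded) NA_real_ else v$mean,
      sd = if (excluded) NA_real_ else sdv,
      cv = if (excluded) NA_real_ else round_half_up(cv, 1),
      excluded = excluded
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  kept <- out$cv[!out$excluded]
  attr(out, "cv_min") <- min(kept)
  attr(out, "cv_max") <- max(kept)
  attr(out, "cv_mean") <- round_half_up(mean(kept), 1)
  out
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("Variance components (%s)%s: mean %.4g pg/mL, n = %s\n",
              x$estimator,
              if (is.na(x$sample)) "" else paste0(" sample ", x$sample),
              x$mean, x$n))
  comp <- x$components
  for (nm in names(comp)) {
    cat(sprintf("  %-9s %.6g  (CV %.2f%%)\n", nm, comp[[nm]],
                100 * sqrt(comp[[nm]]) / x$mean))
  }
  cat(sprintf("  repeatability CV %.1f%%, within-laboratory CV %.1f%%\n",
              x$cv_repeatability, x$cv_within_lab))
  if (length(x$truncated_components)) {
    cat("  truncated at zero:", paste(x$truncated_components, collapse = ", "),
        "\n")
  }
  invisible(x)
}
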