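#' Packaged validation summary tables
#'
#' Summary statistics (N, mean concentration, SD, and the CV as reported)
#' from a completed analytical validation of the three-biomarker panel,
#' shipped as plain-text data under `inst/extdata/`:
#' `"repeatability"` (per-sample repeatability of the 20x2x2 nested design,
#' 7 samples per analyte), `"within_lab"` (within-laboratory precision of
#' the multi-factor design, 8 samples per analyte; samples beyond the
#' measuring interval carry `NA`), and `"risk"` (risk-score reproducibility:
#' 10 patient samples x 20 replicate predicted probabilities).
#'
#' These tables serve as reference inputs for reworking summary statistics
#' (e.g. recomputing CVs via [cv_from_stats()]) and for worked examples.
#'
#' @param table one of `"repeatability"`, `"within_lab"`, `"risk"`.
#' @return data frame.
#' @export
validation_summary <- function(table = c("repeatability", "within_lab",
                                         "risk")) {
  table <- match.arg(table)
  file <- switch(table,
                 repeatability = "repeatability_summary.csv",
                 within_lab = "within_lab_summary.csv",
                 risk = "risk_reproducibility_summary.csv")
  path <- system.file("extdata", file, package = "immunoval", mustWork = TRUE)
  utils::read.csv(path)
}
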