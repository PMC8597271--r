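test_that("simulation is deterministic in the seed, down to file bytes", {
  tr <- sim_truth()
  p1 <- simulate_plate_run(tr, seed = 21)
  p2 <- simulate_plate_run(tr, seed = 21)
  expect_identical(p1, p2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_plate_file(p1, f1); write_plate_file(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
  p3 <- simulate_plate_run(tr, seed = 22)
  expect_false(identical(p1$measurements$signal, p3$measurements$signal))

  d1 <- simulate_precision_study(tr, "multifactor", seed = 7)
  d2 <- simulate_precision_study(tr, "multifactor", seed = 7)
  expect_identical(d1, d2)
  r1 <- simulate_risk_replicates(tr, seed = 7)
  r2 <- simulate_risk_replicates(tr, seed = 7)
  expect_identical(r1, r2)
})

test_that("the noiseless pipeline is an identity through calibration", {
  tr <- quiet_truth()
  pl <- backcalculate_plate(simulate_plate_run(tr, seed = 2))
  m <- pl$measurements
  for (a in ANALYTES) {
    sm <- m[m$role == "sample" & m$analyte == a, ]
    truth_conc <- rep(tr$samples[[a]], each = 2)
    expect_equal(sm$concentration, truth_conc, tolerance = 1e-6)
    qc <- m[m$role == "qc" & m$analyte == a, ]
    expect_equal(qc$concentration, tr$qc[[a]], tolerance = 1e-6)
  }
})

test_that("simulated plates satisfy every plate-map invariant", {
  tr <- sim_truth()
  for (s in c(1, 5)) {
    pl <- simulate_plate_run(tr, seed = s)
    expect_silent(validate_plate_run(pl))
    tab <- table(pl$measurements$role) / length(ANALYTES)
    expect_equal(as.numeric(tab[c("blank", "calibrator", "qc")]), c(1, 7, 4))
  }
})

test_that("design shapes match the study layouts", {
  tr <- sim_truth()
  mf <- simulate_precision_study(tr, "multifactor", seed = 1)
  counts <- table(mf$sample)
  expect_true(all(counts == 100)) # 5 reps x 2 runs x 10 days
  expect_equal(length(unique(mf$operator)), 2)
  expect_equal(length(unique(mf$lot)), 2)
  # days split evenly across lots
  expect_true(all(table(unique(mf[c("day", "lot")])$lot) == 5))
  expect_error(simulate_precision_study(tr, "multifactor", n_days = 9),
               class = "immunoval_design_error")

  ne <- simulate_precision_study(tr, "nested_day_run_rep", seed = 1)
  expect_true(all(table(ne$sample) == 80)) # 20 days x 2 runs x 2 reps

  rr <- simulate_risk_replicates(tr, seed = 1)
  expect_true(all(table(rr$sample) == 20)) # duplicate x 2 runs x 5 days
  expect_equal(length(unique(rr$sample)), 10)
})

test_that("requested replicate CV is realised in the generated data", {
  tr <- sim_truth(cv_components = c(lot = 0, operator = 0, day = 0, run = 0,
                                    rep = 5))
  cvs <- vapply(1:200, function(s) {
    d <- simulate_precision_study(tr, "nested_day_run_rep", n_days = 2,
                                  n_reps = 10, seed = s)
    mean(tapply(seq_len(nrow(d)), paste(d$sample, d$day, d$run),
                function(i) cv_percent(d$concentration[i])))
  }, numeric(1))
  expect_equal(mean(cvs), 5, tolerance = 0.2) # within 1 percentage point
})

test_that("back-calculated within-plate CV tracks the replicate component", {
  tr <- sim_truth(cv_components = c(lot = 0, operator = 0, day = 0, run = 0,
                                    rep = 5), blank_floor_sd = 0)
  cvs <- vapply(1:15, function(s) {
    pl <- backcalculate_plate(simulate_plate_run(tr, n_sample_reps = 4,
                                                 seed = s))
    m <- pl$measurements
    sm <- m[m$role == "sample" & m$analyte == "sTNFR2" & !is.na(m$concentration), ]
    mean(tapply(sm$concentration, sm$sample_label, cv_percent))
  }, numeric(1))
  # back-calculation amplifies signal CV by the local inverse slope of the
  # sigmoid, so the concentration CV tracks the component within a small factor
  expect_gt(mean(cvs), 2.5)
  expect_lt(mean(cvs), 15)
})

test_that("crosstalk drives NSB and its absence keeps NSB at the noise floor", {
  x <- matrix(0, 3, 3, dimnames = list(ANALYTES, ANALYTES))
  x["KIM1", "sTNFR1"] <- 0.01
  tr <- sim_truth(crosstalk = x)
  panel <- simulate_nsb_panel(tr, noise_cv = 2, seed = 3)
  hit <- panel[panel$target == "KIM1" & panel$source == "sTNFR1", ]
  expect_gt(hit$nsb_percent, 0.3)
  others <- panel[!(panel$target == "KIM1" & panel$source == "sTNFR1"), ]
  expect_true(all(others$nsb_percent < 0.3))

  tr0 <- sim_truth()
  p0 <- simulate_nsb_panel(tr0, noise_cv = 2, seed = 4)
  expect_true(all(p0$nsb_percent < 0.3))
})

test_that("truth validation rejects impossible configurations", {
  expect_error(sim_truth(cv_components = c(lot = -1, operator = 0, day = 0,
                                           run = 0, rep = 0)),
               class = "immunoval_invalid_truth")
  x <- matrix(0.1, 3, 3); diag(x) <- 0
  expect_error(sim_truth(crosstalk = x), class = "immunoval_invalid_truth")
})
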