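test_that("category assignment follows the cutoffs on the 5-point grid", {
  expect_identical(as.character(assign_category(c(5, 45, 50, 85, 90, 100))),
                   c("low", "low", "intermediate", "intermediate",
                     "high", "high"))
  expect_error(assign_category(47), class = "immunoval_invalid_score")
  # the grid is partitioned: every score maps to exactly one category
  cats <- assign_category(seq(5, 100, by = 5))
  expect_false(anyNA(cats))
  expect_identical(levels(cats), c("low", "intermediate", "high"))
})

test_that("probability scaling is monotone and validated", {
  tab <- make_score_table()
  expect_true(all(diff(tab$p_min) >= 0))
  expect_identical(tab$score, seq(5, 100, by = 5))
  p <- seq(0, 1, by = 0.01)
  s <- scale_score(p, tab)
  expect_true(all(diff(s) >= 0))
  expect_true(all(s %in% seq(5, 100, by = 5)))
  expect_error(scale_score(1.5), class = "immunoval_invalid_measurement")
  expect_error(make_score_table(p_low = 0.5, p_high = 0.2),
               class = "immunoval_invalid_criteria")
})

test_that("score CV summary reproduces the summary-form worked example", {
  p1 <- vector_with_stats(20, 0.138, 0.002)
  reps <- data.frame(sample = "S1", probability = p1)
  r <- score_cv_summary(risk_replicates(reps))
  expect_equal(r$per_sample$cv, 1.4)
  expect_equal(r$per_sample$n, 20)

  # constant replicates give zero CV
  r0 <- score_cv_summary(risk_replicates(
    data.frame(sample = "S", probability = rep(0.2, 5))))
  expect_equal(r0$per_sample$cv, 0)
  expect_equal(r0$overall_mean_cv, 0)

  # overall reproducibility is the mean of the per-sample CVs, 1 d.p.
  expect_equal(overall_mean_cv(c(1.4, 10.4, 7.0, 0.3, 4.7, 0.8, 6.6, 6.2,
                                 4.3, 4.8)), 4.7)
})

test_that("concordance compares replicates with the mean-score category", {
  # 10 samples x 20 replicates with 4 planted discordances -> 98%
  mk <- function(sample, scores) {
    data.frame(sample = sample, probability = 0.2, scaled_score = scores)
  }
  sets <- rbind(
    mk("L1", rep(25, 20)),
    mk("I1", c(rep(45, 3), rep(60, 17))),   # 3 replicates fall to low
    do.call(rbind, lapply(2:6, function(i) mk(paste0("I", i), rep(60, 20)))),
    mk("H1", c(90, rep(95, 19))[c(2:20, 1)]), # order must not matter
    mk("H2", rep(90, 20)),
    mk("H3", c(rep(90, 19), 85))            # 1 replicate falls to intermediate
  )
  rr <- risk_replicates(sets)
  cc <- concordance(rr)
  expect_equal(cc$overall_percent, 98)
  i1 <- cc$per_sample[cc$per_sample$sample == "I1", ]
  expect_identical(as.character(i1$consensus), "intermediate")
  expect_equal(i1$concordance_percent, 85)
  expect_true(all(cc$per_sample$concordance_percent[
    cc$per_sample$consensus == "low"] == 100))

  # permuting replicate rows leaves every statistic unchanged
  perm <- rr[withr::with_seed(1, sample(nrow(rr))), ]
  cc2 <- concordance(perm)
  expect_equal(cc2$overall_percent, cc$overall_percent)
  expect_equal(cc2$per_sample[order(cc2$per_sample$sample), ],
               cc$per_sample[order(cc$per_sample$sample), ],
               ignore_attr = TRUE)
})

test_that("half-discordant replicates give 50% concordance", {
  sets <- data.frame(sample = "S", probability = 0.2,
                     scaled_score = c(rep(40, 10), rep(60, 10)))
  cc <- concordance(risk_replicates(sets))
  # mean score 50 -> intermediate consensus; the ten low replicates miss
  expect_equal(cc$overall_percent, 50)
})

test_that("replicate sets validate probabilities and category consistency", {
  expect_error(risk_replicates(data.frame(sample = "S", probability = 1.2)),
               class = "immunoval_invalid_measurement")
  rr <- risk_replicates(data.frame(sample = "S",
                                   probability = c(0.1, 0.2, 0.3)))
  expect_identical(rr$category,
                   assign_category(rr$scaled_score))
})

test_that("noise-free replicate simulation yields perfect concordance", {
  tr <- quiet_truth()
  rr <- simulate_risk_replicates(tr, seed = 5)
  expect_equal(concordance(rr)$overall_percent, 100)
  expect_equal(score_cv_summary(rr)$overall_mean_cv, 0)
})

test_that("calibrated noise keeps concordance high for off-cutoff samples", {
  tr <- sim_truth()
  # severity axis chosen to keep every sample's probability well clear of the
  # category cutpoints of the default score table
  t <- c(0.507, 1.195, 1.254, 1.310, 1.363, 1.752, 1.961, 2.158)
  panel <- data.frame(sample = paste0("S", seq_along(t)),
                      kim1 = 40 * exp(1.5 * t),
                      stnfr1 = 1600 * exp(0.8 * t),
                      stnfr2 = 5000 * exp(0.8 * t))
  conc <- vapply(1:20, function(s) {
    concordance(simulate_risk_replicates(tr, panel = panel,
                                         seed = s))$overall_percent
  }, numeric(1))
  expect_gte(mean(conc >= 95), 0.9)
})
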