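test_that("parametric LoB follows the corrected-percentile formula", {
  # all-zero blanks: sd = 0 so LoB = 0
  expect_equal(limit_of_blank(rep(0, 25)), 0)

  # 25 blanks with exact mean 0.1 and SD 0.2, single assay: f = 24
  b <- vector_with_stats(25, 0.1, 0.2)
  expect_equal(ep17_cp(24), 1.645 / (1 - 1 / 96))
  expect_equal(limit_of_blank(b), 0.1 + ep17_cp(24) * 0.2, tolerance = 1e-12)
  expect_equal(round(limit_of_blank(b), 4), 0.4325)

  expect_error(limit_of_blank(rep(0, 10)),
               class = "immunoval_insufficient_data")
})

test_that("LoB is monotone in blank SD and pools degrees of freedom", {
  lobs <- vapply(c(0.1, 0.2, 0.4), function(s) {
    limit_of_blank(vector_with_stats(30, 0.1, s))
  }, numeric(1))
  expect_true(all(diff(lobs) > 0))

  # two assays pool to f = n - 2
  two <- list(vector_with_stats(15, 0.1, 0.2, seed = 1),
              vector_with_stats(15, 0.1, 0.2, seed = 2))
  expect_equal(limit_of_blank(two), 0.1 + ep17_cp(28) * 0.2, tolerance = 1e-12)
})

test_that("nonparametric and parametric LoB agree on large normal blanks", {
  b <- withr::with_seed(42, rnorm(1000, 0.1, 0.2))
  p <- limit_of_blank(b, "parametric")
  np <- limit_of_blank(b, "nonparametric")
  expect_lt(abs(np - p) / p, 0.10)
})

test_that("LoD adds the corrected multiple of the pooled low-level SD", {
  # zero low-level scatter: LoD = LoB
  lows0 <- lapply(1:4, function(i) rep(0.5, 5))
  expect_equal(limit_of_detection(0.4, lows0), 0.4)

  # pooled SD 0.5 at large df: c_p -> 1.645, LoD -> 1.2225
  lows <- lapply(1:4, function(i) vector_with_stats(1000, 0.5, 0.5, seed = i))
  expect_equal(limit_of_detection(0.4, lows), 0.4 + 1.645 * 0.5,
               tolerance = 1e-3)

  expect_error(limit_of_detection(0.4, lows[1:2]),
               class = "immunoval_insufficient_data")
  expect_warning(limit_of_detection(0.01,
    lapply(1:4, function(i) vector_with_stats(10, 5, 0.1, seed = i))),
    "10x LoB")
})

test_that("LoD-level samples exceed the LoB about 95% of the time", {
  frac <- vapply(1:50, function(s) {
    withr::with_seed(s, {
      blanks <- rnorm(30, 0.1, 0.2)
      lob <- limit_of_blank(blanks)
      lows <- lapply(1:4, function(i) rnorm(10, 0.6, 0.2))
      lod <- limit_of_detection(lob, lows)
      mean(rnorm(500, lod, 0.2) > lob)
    })
  }, numeric(1))
  expect_gt(mean(frac), 0.93)
})

test_that("the four-part quantification rule gates levels as specified", {
  blank_sig <- 100
  top_sig <- 200000
  mk_level <- function(level, cv, recovery = 100, signal = 50 * level + 500) {
    conc <- vector_with_stats(5, level * recovery / 100, level * cv / 100,
                              seed = level)
    data.frame(level = level, plate = 1L, concentration = conc,
               signal = rep(signal, 5))
  }

  # CV 12% with perfect recovery fails on the CV criterion alone
  cand <- rbind(mk_level(10, cv = 12), mk_level(20, cv = 3),
                mk_level(50, cv = 3), mk_level(100, cv = 3),
                mk_level(200, cv = 3))
  res <- loq_scan(cand, blank_sig, top_sig, lod = 1)
  ev10 <- res$criteria_evidence[res$criteria_evidence$level == 10, ]
  expect_false(ev10$pass_cv)
  expect_true(ev10$pass_recovery)
  expect_equal(res$lloq, 20)

  # all low levels pass but sit below the LoD: LLoQ is restricted to the LoD
  cand2 <- rbind(mk_level(100, cv = 3), mk_level(150, cv = 3),
                 mk_level(200, cv = 3), mk_level(300, cv = 3),
                 mk_level(500, cv = 3))
  res2 <- loq_scan(cand2, blank_sig, top_sig, lod = 248)
  expect_equal(res2$lloq, 248)
  expect_true(res2$lloq_restricted_to_lod)

  # brute-force oracle: evaluate every criterion per level independently
  cand3 <- rbind(mk_level(2, cv = 15), mk_level(5, cv = 15),
                 mk_level(10, cv = 3), mk_level(20, cv = 3),
                 mk_level(50, cv = 3))
  oracle_pass <- vapply(c(2, 5, 10, 20, 50), function(l) {
    d <- cand3[cand3$level == l, ]
    cv <- 100 * sd(d$concentration) / mean(d$concentration)
    rec <- 100 * mean(d$concentration) / l
    cv < 10 && rec >= 80 && rec <= 120 && mean(d$signal) >= 3 * blank_sig
  }, logical(1))
  expect_identical(which(oracle_pass), 3:5)
  res3 <- loq_scan(cand3, blank_sig, top_sig, lod = 0.5)
  expect_equal(res3$lloq, 10)

  # rerunning on identical inputs reproduces identical limits and evidence
  res3b <- loq_scan(cand3, blank_sig, top_sig, lod = 0.5)
  expect_identical(res3b, res3)
})

test_that("no passing level raises the evidence-bearing error", {
  cand <- do.call(rbind, lapply(c(5, 10, 20, 40, 80), function(l) {
    data.frame(level = l, plate = 1L,
               concentration = vector_with_stats(5, l, 0.3 * l, seed = l),
               signal = rep(10, 5))
  }))
  err <- tryCatch(loq_scan(cand, 100, 2e5, lod = 1), condition = identity)
  expect_s3_class(err, "immunoval_no_quantifiable_range")
  expect_s3_class(err$evidence, "data.frame")
  expect_equal(nrow(err$evidence), 5)
})

test_that("detection limits enforce the ordering invariant", {
  dl <- detection_limits("KIM1", lob = c(lot1 = 0.3, lot2 = 0.4), lod = 1.3,
                         lloq = 7, uloq = 4640)
  expect_equal(dl$lob, 0.4) # maximum across lots is reported
  expect_error(detection_limits("KIM1", lob = 2, lod = 1, lloq = 7,
                                uloq = 4640),
               class = "immunoval_limits_order")
  expect_error(detection_limits("KIM1", lob = 0.4, lod = 1.3, lloq = 5000,
                                uloq = 4640),
               class = "immunoval_limits_order")
})
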