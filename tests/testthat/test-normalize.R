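# Hand fixtures for the median-of-ratios normalization chain.

test_that("hybridization normalization: identity, known ratio, and the median identity", {
  # 2 samples x 2 analytes + 2 hybridization controls
  vals <- matrix(c(100, 200, 300, 400), 2, 2)
  hyb <- rbind(c(50, 500), c(50, 500))
  tab <- make_table(vals, hyb = hyb)
  r <- hybridization_normalize(tab)
  # controls equal the plate medians -> factor 1, data unchanged
  expect_equal(r$factors$hyb$factor, c(1, 1))
  expect_equal(r$table$rfu, tab$rfu)

  # third sample's controls at half the plate median -> factor 2, RFUs doubled
  hyb2 <- rbind(c(50, 500), c(50, 500), c(25, 250))
  vals3 <- rbind(vals, c(150, 350))
  tab2 <- make_table(vals3, hyb = hyb2)
  r2 <- hybridization_normalize(tab2)
  expect_equal(r2$factors$hyb$factor, c(1, 1, 2))
  expect_equal(r2$table$rfu[3, 1:2], tab2$rfu[3, 1:2] * 2,
               ignore_attr = TRUE)

  # random plate: post hoc, each sample's median ratio to the defining
  # (pre-normalization) plate reference is exactly 1
  set.seed(4)
  tab3 <- make_table(matrix(runif(8 * 5, 100, 1000), 8, 5),
                     hyb = matrix(runif(8 * 12, 40, 4000), 8, 12))
  r3 <- hybridization_normalize(tab3)
  hyb_cols <- which(tab3$somamer_meta$is_hyb_control)
  ref <- apply(tab3$rfu[, hyb_cols], 2, median)
  for (i in 1:8) {
    expect_equal(median(ref / r3$table$rfu[i, hyb_cols]), 1)
  }
  expect_error(hybridization_normalize(make_table(vals)), "no hybridization")
})

test_that("intraplate normalization reproduces hand-computed median-of-ratios factors", {
  # 3 calibrators, 3 analytes (one per dilution), values 2/4/8 per SOMAmer:
  # local reference is the median 4; ratios per sample are 2, 1, 0.5.
  vals <- matrix(rep(c(2, 4, 8), 3), nrow = 3, byrow = FALSE)
  tab <- make_table(vals, dilution = 1:3,
                    sample_type = rep("calibrator", 3))
  r <- intraplate_median_normalize(tab)
  f <- r$factors$intraplate
  expect_equal(f$factor[f$sample_id == "S001"], c(2, 2, 2))
  expect_equal(f$factor[f$sample_id == "S002"], c(1, 1, 1))
  expect_equal(f$factor[f$sample_id == "S003"], c(0.5, 0.5, 0.5))

  # identity case: calibrator equal to the per-SOMAmer medians
  vals2 <- matrix(4, 3, 6)
  tab2 <- make_table(vals2, sample_type = rep("calibrator", 3))
  r2 <- intraplate_median_normalize(tab2)
  expect_true(all(r2$factors$intraplate$factor == 1))

  # post hoc: per-dilution median ratio to the defining (pre-step) local
  # reference is 1
  set.seed(8)
  tab3 <- make_table(matrix(runif(4 * 9, 50, 5000), 4, 9),
                     sample_type = rep("calibrator", 4))
  r3 <- intraplate_median_normalize(tab3)
  sm <- tab3$somamer_meta
  ref <- apply(tab3$rfu, 2, median)
  for (i in 1:4) {
    for (d in 1:3) {
      cols <- which(sm$dilution_set == d)
      expect_equal(median(ref[cols] / r3$table$rfu[i, cols]), 1)
    }
  }
})

test_that("the global reference is the pooled calibrator median", {
  # two calibrators with values 3 and 5 -> reference 4
  tab <- make_table(rbind(c(3, 3), c(5, 5)),
                    sample_type = rep("calibrator", 2))
  ref <- build_global_reference(tab)
  expect_equal(unname(ref$calibrator_ref), c(4, 4))

  # many plates: equals the brute-force pooled median
  set.seed(15)
  tabs <- lapply(1:3, function(p) {
    make_table(matrix(runif(5 * 4, 100, 1000), 5, 4), plate_id = sprintf("P%d", p),
               sample_type = c("calibrator", "calibrator", "calibrator",
                               "qc", "study"))
  })
  ref2 <- build_global_reference(tabs)
  pooled <- do.call(rbind, lapply(tabs, function(t) {
    t$rfu[t$sample_meta$sample_type == "calibrator", ]
  }))
  expect_equal(unname(ref2$calibrator_ref), unname(apply(pooled, 2, median)))
  expect_error(build_global_reference(make_table(matrix(1, 1, 1))),
               "no calibrator")
})

test_that("plate scaling: identity, known factor, and application to every measurement", {
  base <- matrix(rep(c(100, 200, 400), each = 3), 3, 3)
  tab <- make_table(base, sample_type = rep("calibrator", 3))
  ref <- build_global_reference(tab)
  r <- plate_scale(tab, ref)
  expect_equal(r$factors$plate_scale$factor, 1)

  # plate uniformly at twice the reference -> plate factor 0.5
  tab2 <- make_table(2 * base, sample_type = rep("calibrator", 3))
  r2 <- plate_scale(tab2, ref)
  expect_equal(r2$factors$plate_scale$factor, 0.5)
  expect_equal(r2$table$rfu, base, ignore_attr = TRUE)
})

test_that("calibration forces plate calibrator medians onto the global reference", {
  set.seed(21)
  tab <- make_table(matrix(runif(6 * 5, 100, 2000), 6, 5),
                    plate_id = rep(c("P1", "P2"), each = 3),
                    sample_type = rep(c("calibrator", "calibrator", "study"),
                                      2))
  ref <- build_global_reference(tab)
  cal <- calibrate(plate_scale(tab, ref)$table, ref)
  for (p in c("P1", "P2")) {
    rows <- which(cal$table$sample_meta$plate_id == p &
                    cal$table$sample_meta$sample_type == "calibrator")
    med <- apply(cal$table$rfu[rows, , drop = FALSE], 2, median)
    expect_equal(unname(med), unname(ref$calibrator_ref))
  }
  # after a perfect plate scale the per-plate calibration factors have median 1
  ps <- plate_scale(tab, ref)
  cal2 <- calibrate(ps$table, ref)
  for (p in c("P1", "P2")) {
    f <- cal2$factors$calibration$factor[cal2$factors$calibration$plate_id == p]
    expect_equal(median(f), 1)
  }
})

test_that("median normalization to the reference hits known factors", {
  base <- matrix(rep(c(100, 200, 400), each = 3), 3, 3)
  cal_tab <- make_table(base, sample_type = rep("calibrator", 3))
  ref <- build_global_reference(cal_tab)

  vals <- rbind(base[1, ], 2 * base[1, ], base[1, ] * c(1, 2, 4))
  tab <- make_table(rbind(base, vals),
                    sample_type = c(rep("calibrator", 3), rep("study", 3)),
                    dilution = rep(1L, 3))
  r <- median_normalize_to_reference(tab, ref)
  f <- r$factors$ref_median
  s1 <- f$factor[f$sample_id == "S004" & f$dilution_set == 1]
  s2 <- f$factor[f$sample_id == "S005" & f$dilution_set == 1]
  expect_equal(s1, 1)       # sample equal to reference
  expect_equal(s2, 0.5)     # sample at 2x the reference
  # brute-force median of ratios for the mixed sample
  s3 <- f$factor[f$sample_id == "S006" & f$dilution_set == 1]
  expect_equal(s3, median(ref$normalization_ref / vals[3, ]))
})

test_that("QC verdicts follow the printed acceptance bands", {
  f <- somastrat:::empty_factors()
  f$hyb <- data.frame(sample_id = "s", plate_id = "P1", factor = 1)
  f$intraplate <- data.frame(sample_id = "s", plate_id = "P1",
                             dilution_set = 1, factor = 1)
  f$plate_scale <- data.frame(plate_id = "P1", factor = 1)
  f$qc_ratios <- data.frame(sample_id = "q", somamer_id = "sm", ratio = 1)
  expect_true(qc_report(f)$pass)

  # 84% of QC ratios in band -> fail; 86% -> pass
  n <- 100
  mk <- function(frac_in) c(rep(1, frac_in * n), rep(2, n - frac_in * n))
  f84 <- f
  f84$qc_ratios <- data.frame(sample_id = "q", somamer_id = seq_len(n),
                              ratio = mk(0.84))
  expect_false(qc_report(f84)$pass)
  f86 <- f
  f86$qc_ratios <- data.frame(sample_id = "q", somamer_id = seq_len(n),
                              ratio = mk(0.86))
  expect_true(qc_report(f86)$pass)

  # a hybridization factor of 3.0 fails its class
  f3 <- f
  f3$hyb$factor <- 3
  rep3 <- qc_report(f3)
  expect_false(rep3$factor_checks$pass[rep3$factor_checks$class == "hyb"])
  expect_false(rep3$pass)
})

test_that("the full chain passes QC on clean plates and is idempotent", {
  coh <- simulate_cohort(small_cfg(seed = 31L))
  res <- normalize_pipeline(coh$somamer_table)
  expect_true(res$report$pass)
  banded <- subset(res$report$factor_checks, class != "ref_median")
  expect_true(all(banded$pass))
  # deterministic
  res_b <- normalize_pipeline(coh$somamer_table)
  expect_identical(res$table$rfu, res_b$table$rfu)
  # the reference-anchored steps are exactly idempotent: re-running plate
  # scaling, calibration and median normalization against the same global
  # reference yields unit factors
  r_ps <- plate_scale(res$table, res$reference)
  expect_equal(r_ps$factors$plate_scale$factor,
               rep(1, nrow(r_ps$factors$plate_scale)), tolerance = 1e-12)
  r_cal <- calibrate(r_ps$table, res$reference)
  expect_equal(r_cal$factors$calibration$factor,
               rep(1, nrow(r_cal$factors$calibration)), tolerance = 1e-12)
  r_mn <- median_normalize_to_reference(r_cal$table, res$reference)
  expect_equal(r_mn$factors$ref_median$factor,
               rep(1, nrow(r_mn$factors$ref_median)), tolerance = 1e-12)
  # locally-referenced steps re-estimate their reference from the cleaned
  # data, so their second-pass factors are only near 1
  res2 <- normalize_pipeline(res$table, ref = res$reference)
  expect_equal(res2$factors$hyb$factor,
               rep(1, nrow(res2$factors$hyb)), tolerance = 0.05)
  # the per-sample scalar steps preserve within-sample ordering
  h <- hybridization_normalize(coh$somamer_table)
  for (i in c(1, 5)) {
    expect_identical(order(h$table$rfu[i, ]),
                     order(coh$somamer_table$rfu[i, ]))
  }
})
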