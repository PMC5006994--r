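test_that("undetectable features count missing and zero cells", {
  m <- matrix(1, 10, 2)
  m[1:3, 1] <- NA          # 3 missing
  m[4:5, 2] <- NA          # 2 missing + 1 zero
  m[6, 2] <- 0
  tab <- make_table(m, c("RQC", "RQC"))
  expect_equal(count_undetectable(tab, "inj01"), 3L)
  expect_equal(count_undetectable(tab, "inj02"), 3L)
  expect_error(count_undetectable(tab, "nope"), "unknown injection")
})

test_that("the RQC reliability rule is strict at the threshold", {
  nf <- 1500L
  m <- matrix(1, nf, 3)
  m[seq_len(999L), 1] <- NA
  m[seq_len(1000L), 2] <- NA
  tab <- make_table(m, c("RQC", "RQC", "study"))
  expect_true(is_reliable_rqc(tab, "inj01"))    # 999 undetectable
  expect_false(is_reliable_rqc(tab, "inj02"))   # 1000: "1,000 or more"
  expect_error(is_reliable_rqc(tab, "inj03"), "not RQC")
  # fractional threshold scales to the table size
  expect_false(is_reliable_rqc(tab, "inj01", threshold = 999 / nf))
})

test_that("segmentation pairs reliable RQCs and skips unreliable ones", {
  tab <- make_segment_table(M1 = c(100, 50), M2 = c(190, 60), x = c(220, 55))
  seg <- segment_run(tab, threshold = 0.5)
  expect_length(seg$segments, 1L)
  expect_equal(seg$segments[[1]]$S, 8L)

  # an unreliable RQC in the middle merges its neighbours' segments
  m <- cbind(matrix(1, 2, 1) * c(100, 50),
             matrix(c(220, 55), 2, 4),
             matrix(NA_real_, 2, 1),
             matrix(c(220, 55), 2, 4),
             matrix(1, 2, 1) * c(190, 60))
  roles <- c("RQC", rep("study", 4), "RQC", rep("study", 4), "RQC")
  tab2 <- make_table(m, roles)
  seg2 <- segment_run(tab2, threshold = 0.5)
  expect_length(seg2$segments, 1L)
  expect_equal(seg2$segments[[1]]$S, 8L)
  expect_equal(seg2$unreliable$injection_id, "inj06")

  # two adjacent RQCs: a degenerate but valid segment
  tab3 <- make_table(matrix(c(1, 2), 1, 2), c("RQC", "RQC"))
  seg3 <- segment_run(tab3, threshold = 0.5)
  expect_equal(seg3$segments[[1]]$S, 0L)

  # fewer than two reliable RQCs: advise raw passthrough
  tab4 <- make_table(matrix(1, 1, 2), c("RQC", "study"))
  expect_error(segment_run(tab4, threshold = 0.5), "raw")
})

test_that("sensitivity interpolation matches the printed divisor", {
  expect_equal(interpolate_sensitivity(100, 190, n = 1, S = 8), 110)
  expect_equal(interpolate_sensitivity(100, 190, n = 0, S = 8), 100)
  expect_equal(interpolate_sensitivity(100, 190, n = 9, S = 8), 190)
  expect_equal(interpolate_sensitivity(123, 123, n = 4, S = 8), 123)
  expect_error(interpolate_sensitivity(0, 190, 1, 8), "positive")
  expect_error(interpolate_sensitivity(100, 190, 10, 8), "\\[0, S \\+ 1\\]")
})

test_that("the correction equation is applied verbatim in literal mode", {
  tab <- make_segment_table(M1 = 100, M2 = 190, x = 220)
  res <- normalize_table(tab, threshold = 0.5, mode = "literal")
  # first study injection: n = 1, divisor 9 -> sensitivity 110, y = 200
  expect_equal(res$table$intensities[1, 2], 200)
  # last study injection: n = 8 -> sensitivity 180, y = 220*100/180
  expect_equal(res$table$intensities[1, 9], 220 * 100 / 180)
  # the closing RQC maps onto the left flank's value
  expect_equal(res$table$intensities[1, 10], 100)
})

test_that("equal RQC intensities make normalization the identity", {
  x <- c(220.1, 55.3, 17.9)
  tab <- make_segment_table(M1 = c(100, 50, 3), M2 = c(100, 50, 3), x = x)
  for (mode in c("literal", "anchored")) {
    res <- normalize_table(tab, threshold = 0.5, mode = mode)
    expect_identical(res$table$intensities, tab$intensities)
  }
})

test_that("missingness is preserved and intensities stay nonnegative", {
  tab <- make_segment_table(M1 = c(100, 50), M2 = c(190, 60), x = c(220, 55))
  m <- tab$intensities
  m[1, 4] <- NA
  m[2, 5] <- 0
  tab2 <- feature_table(tab$features, tab$injections, m)
  res <- normalize_table(tab2, threshold = 0.5)
  expect_true(is.na(res$table$intensities[1, 4]))
  expect_equal(res$table$intensities[2, 5], 0)
  expect_true(all(res$table$intensities[!is.na(res$table$intensities)] >= 0))
})

test_that("unquantified flanks fall back to the nearest quantified RQC", {
  # three RQCs; feature 2 is missing in the middle RQC, so its second
  # segment must interpolate from RQC1 to RQC3
  m <- rbind(c(100, 220, 150, 220, 200),
             c(100, 220, NA, 220, 200))
  roles <- c("RQC", "study", "RQC", "study", "RQC")
  tab <- make_table(m, roles)
  res <- normalize_table(tab, threshold = 0.8, mode = "literal")
  # feature 1, segment 2: M1 = 150, M2 = 200, D = 2, n = 1 -> denom 175
  expect_equal(res$table$intensities[1, 4], 220 * 150 / 175)
  # feature 2 spans RQC1 -> RQC3: D = 4; study at n = 3 -> denom 175
  expect_equal(res$table$intensities[2, 4], 220 * 100 / 175)
  expect_equal(res$report$fallback_features, 2L)  # both segments of f2

  # a feature quantified in no RQC stays raw and is reported
  m2 <- rbind(m, c(NA, 300, NA, 300, NA))
  tab2 <- make_table(m2, roles)
  res2 <- normalize_table(tab2, threshold = 0.9, mode = "anchored")
  expect_equal(unname(res2$table$intensities[3, c(2, 4)]), c(300, 300))
  expect_equal(res2$report$raw_feature_segments, 2L)
})

test_that("anchored mode aligns every segment and RQC to the first RQC", {
  cfg <- sim_config(n_plates = 2, n_study_per_plate = 16, n_features = 20,
                    noise_cv = 0, drift_amplitude = 0.25, plate_jump = 0.3,
                    seed = 42)
  sim <- simulate_intensities(cfg)
  res <- normalize_table(sim$table, threshold = 0.5, mode = "anchored")
  inj <- res$table$injections
  rqcs <- inj$injection_id[inj$role == "RQC"]
  first_vals <- res$table$intensities[, rqcs[1]]
  for (id in rqcs) {
    expect_equal(res$table$intensities[, id], first_vals,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("piecewise-linear drift is removed exactly (algebraic oracle)", {
  cfg <- sim_config(n_plates = 2, n_study_per_plate = 24, n_features = 25,
                    n_donors = 3, noise_cv = 0, drift_amplitude = 0.3,
                    plate_jump = 0.3, seed = 7)
  sim <- simulate_intensities(cfg)
  inj <- sim$table$injections
  study <- inj$injection_id[inj$role == "study"]
  truth <- sim$truth$truth[, inj$sample_id[match(study, inj$injection_id)]]

  # anchored: output = truth * g(first RQC) = truth (g starts at 1)
  anch <- normalize_table(sim$table, threshold = 0.5, mode = "anchored")
  expect_lt(max(abs(anch$table$intensities[, study] / truth - 1)), 1e-9)

  # literal: output = truth * g(left RQC) within each segment
  lit <- normalize_table(sim$table, threshold = 0.5, mode = "literal")
  seg <- segment_run(sim$table, threshold = 0.5)
  for (s in seg$segments) {
    st <- s$study_injections
    if (!length(st)) next
    gl <- sim$truth$g[, s$left_rqc]
    tr <- sim$truth$truth[, inj$sample_id[match(st, inj$injection_id)],
                          drop = FALSE]
    expect_lt(max(abs(lit$table$intensities[, st, drop = FALSE] /
                        (tr * gl) - 1)), 1e-9)
  }
})

test_that("a degraded RQC is excluded and its block absorbed", {
  cfg <- sim_config(n_plates = 1, n_study_per_plate = 24, n_features = 50,
                    noise_cv = 0, drift_amplitude = 0.2,
                    degrade_rqc_index = 2L, seed = 3)
  sim <- simulate_intensities(cfg)
  seg <- segment_run(sim$table, threshold = 0.5)
  expect_equal(seg$unreliable$injection_id, sim$truth$degraded_rqcs)
  expect_length(seg$segments, 2L)       # 4 RQCs, one skipped
  expect_equal(seg$segments[[1]]$S, 16L)  # merged block
})
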