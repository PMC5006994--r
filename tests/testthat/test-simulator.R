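test_that("plate layout reproduces the 96-well design", {
  lay <- make_plate_layout(sim_config())
  expect_equal(sum(lay$role == "study"), 88L)
  expect_identical(lay$well[lay$role == "RQC"], "A12")
  expect_identical(lay$well[lay$role == "SQC"], "B12")
  expect_identical(lay$well[lay$role == "dQC"],
                   c("C12", "D12", "E12", "F12"))
  expect_identical(lay$dilution_fold[lay$role == "dQC"], c(2L, 4L, 8L, 16L))
  expect_identical(lay$well[lay$role == "blank"], "H12")
  # all identifiers are valid 96-well coordinates
  expect_true(all(grepl("^[A-H](1[0-2]|[1-9])$", lay$well)))
  lay24 <- make_plate_layout(sim_config(n_study_per_plate = 24))
  expect_equal(sum(lay24$role == "study"), 24L)
  expect_equal(sum(lay24$role != "study"), 7L)
  expect_error(make_plate_layout(
    `class<-`(list(n_study_per_plate = 89), "sim_config")), "88")
})

test_that("the run order follows the QC cadence", {
  ro <- make_run_order(sim_config(seed = 5))
  expect_identical(ro$role[1:10], rep("SQC", 10L))  # conditioning block
  expect_equal(sum(ro$role == "study"), 88L)
  expect_equal(sum(ro$role == "RQC"), 12L)          # 11 blocks + closing
  # every 8-study block is bracketed by RQCs
  runs <- rle(ro$role[ro$role != "SQC"])
  blocks <- runs$lengths[runs$values == "study"]
  expect_true(all(blocks == 8L))
  # closing dilution series: 3 x (d16, d8, d4, d2) then an SQC triplet
  tail16 <- utils::tail(ro, 15L)
  expect_identical(tail16$role, c(rep("dQC", 12L), rep("SQC", 3L)))
  expect_identical(tail16$dilution_fold,
                   c(rep(c(16L, 8L, 4L, 2L), each = 3L), rep(1L, 3L)))
  # run indices are the global total order
  expect_identical(ro$run_index, seq_len(nrow(ro)) - 1L)
})

test_that("identical configurations give bit-identical simulations", {
  cfg <- sim_config(n_features = 30, n_study_per_plate = 16, seed = 99,
                    rqc_failure_prob = 0.2)
  s1 <- simulate_intensities(cfg)
  s2 <- simulate_intensities(cfg)
  expect_identical(s1$table$intensities, s2$table$intensities)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_intensities(sim_config(n_features = 30,
                                        n_study_per_plate = 16, seed = 100))
  expect_false(identical(s1$table$intensities, s3$table$intensities))
})

test_that("emitted injections, truth and manifest are mutually consistent", {
  cfg <- sim_config(n_features = 20, n_study_per_plate = 16, n_donors = 2,
                    seed = 13)
  sim <- simulate_intensities(cfg)
  tab <- sim$table
  expect_false(anyDuplicated(tab$injections$injection_id) > 0)
  expect_identical(dim(sim$truth$g), dim(tab$intensities))
  expect_setequal(colnames(sim$truth$truth),
                  unique(tab$injections$sample_id[tab$injections$role ==
                                                  "study"]))
})

test_that("zero noise and zero drift give exact replicates and 1/fold dQCs", {
  cfg <- sim_config(n_features = 15, n_study_per_plate = 16, n_donors = 2,
                    noise_cv = 0, drift_amplitude = 0, plate_jump = 0,
                    seed = 8)
  sim <- simulate_intensities(cfg)
  tab <- sim$table
  inj <- tab$injections
  for (d in c("D1", "D2")) {
    cols <- inj$injection_id[inj$role == "study" & !is.na(inj$sample_id) &
                             inj$sample_id == d]
    m <- tab$intensities[, cols]
    expect_true(all(m == m[, 1]))
  }
  sqc <- tab$intensities[, inj$injection_id[inj$role == "SQC"][1]]
  for (fold in c(2, 8, 16)) {
    dq <- inj$injection_id[inj$role == "dQC" & inj$dilution_fold == fold][1]
    expect_equal(tab$intensities[, dq], sqc / fold, tolerance = 1e-12)
  }
})

test_that("designated RQC degradation defeats the reliability rule", {
  cfg <- sim_config(n_features = 40, n_study_per_plate = 16,
                    degrade_rqc_index = 2L, degrade_fraction = 0.6,
                    seed = 55)
  sim <- simulate_intensities(cfg)
  expect_length(sim$truth$degraded_rqcs, 1L)
  expect_false(is_reliable_rqc(sim$table, sim$truth$degraded_rqcs,
                               threshold = 0.5))
  seg <- segment_run(sim$table, threshold = 0.5)
  expect_identical(seg$unreliable$injection_id, sim$truth$degraded_rqcs)
})

test_that("the storage series realizes the 66-sample design", {
  mk <- load_marker_table()
  cfg <- sim_config(noise_cv = 0.05, seed = 17)
  sim <- simulate_storage_series(cfg, mk, n_null_features = 20)
  inj <- sim$table$injections
  samples <- unique(inj$sample_id[inj$role == "study"])
  expect_length(samples, 66L)  # 6 donors x (control + 2 temps x 5 times)
  expect_length(sim$truth$marker_ids, 40L)
  # marker features carry the compound annotation for scoring
  ann <- sim$table$features$annotation[
    match(sim$truth$marker_ids, sim$table$features$feature_id)]
  expect_setequal(ann, mk$name)
  # determinism holds for the storage generator too
  sim2 <- simulate_storage_series(cfg, mk, n_null_features = 20)
  expect_identical(sim$table$intensities, sim2$table$intensities)
})

test_that("25C truths track the trendlines, 4C truths stay flat", {
  mk <- load_marker_table()
  cfg <- sim_config(noise_cv = 0.05, drift_amplitude = 0, plate_jump = 0,
                    seed = 23)
  sim <- simulate_storage_series(cfg, mk, n_null_features = 0)
  tab <- sim$table
  inj <- tab$injections
  # the 48-h 25C mean across donors approximates the trendline value
  ids48 <- inj$injection_id[inj$role == "study" &
                            grepl("_25C_48h$", inj$sample_id)]
  m48 <- rowMeans(tab$intensities[, ids48])
  expected <- pmax(marker_values(mk, 48), 1)
  ratio <- m48 / expected
  expect_true(all(ratio > 0.7 & ratio < 1.4))
  # at 4C the marker features show no storage-time trend
  p_slopes <- vapply(seq_len(40), function(f) {
    rows <- lapply(c(3, 6, 12, 24, 48), function(t) {
      ids <- inj$injection_id[inj$role == "study" &
                              grepl(sprintf("_4C_%gh$", t), inj$sample_id)]
      data.frame(t = t, v = tab$intensities[f, ids])
    })
    df <- do.call(rbind, rows)
    summary(stats::lm(v ~ t, df))$coefficients["t", 4]
  }, numeric(1))
  expect_gte(mean(p_slopes > 0.05), 0.95)
})
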