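# Programmatic fixtures shared across the test files.

# Minimal hand-written table: `nf` features, injections given as a list of
# (role, fold) in run order; intensities supplied as a features x injections
# matrix.
make_table <- function(intensities, roles, folds = NULL, plate = "P1",
                       sample_ids = NULL, mz = NULL,
                       assay_mode = "C18pos") {
  intensities <- as.matrix(intensities)
  dimnames(intensities) <- NULL  # columns are taken in run order
  nf <- nrow(intensities)
  nj <- ncol(intensities)
  stopifnot(length(roles) == nj)
  if (is.null(folds)) folds <- rep(NA_integer_, nj)
  if (is.null(sample_ids)) {
    sample_ids <- ifelse(roles == "study",
                         sprintf("S%02d", seq_len(nj)), NA_character_)
  }
  if (is.null(mz)) mz <- seq(100, 500, length.out = nf)
  features <- data.frame(
    feature_id = sprintf("F%03d", seq_len(nf)),
    mz = mz, rt = rep(1, nf),
    assay_mode = rep_len(assay_mode, nf),
    stringsAsFactors = FALSE)
  injections <- data.frame(
    injection_id = sprintf("inj%02d", seq_len(nj)),
    run_index = seq_len(nj) - 1L,
    plate_id = rep_len(plate, nj),
    role = roles, sample_id = sample_ids,
    dilution_fold = as.integer(folds),
    stringsAsFactors = FALSE)
  feature_table(features, injections, intensities)
}

# One canonical segment: RQC, eight study injections, RQC. Per feature the
# flanks are (M1, M2) and every study injection holds `x`.
make_segment_table <- function(M1, M2, x) {
  nf <- length(M1)
  m <- cbind(M1, matrix(rep(x, 8L), nf, 8L), M2)
  make_table(m, c("RQC", rep("study", 8L), "RQC"))
}

# Engineered 100-feature QC-filter fixture with disjoint, known violators:
# features 1-10 fail the SQC repeatability CV, 11-15 fail dQC monotonicity,
# 16-18 exceed the m/z cap, the remaining 82 pass everything. Sequence:
# 2 conditioning SQCs, 6 intercalated SQCs, dQC triplets (d16,d8,d4,d2),
# closing SQC triplet. Use cfg_qc_fixture() with it.
make_filter_fixture <- function() {
  roles <- c(rep("SQC", 2L), rep("SQC", 6L),
             rep("dQC", 12L), rep("SQC", 3L))
  folds <- c(rep(1L, 8L), rep(c(16L, 8L, 4L, 2L), each = 3L), rep(1L, 3L))
  nf <- 100L
  nj <- length(roles)
  m <- matrix(NA_real_, nf, nj)
  sqc_cols <- 1:8
  dqc_cols <- list(`16` = 9:11, `8` = 12:14, `4` = 15:17, `2` = 18:20)
  closing <- 21:23
  good_dqc <- function(f) {
    m[f, closing] <<- 1000
    m[f, dqc_cols$`2`] <<- 500
    m[f, dqc_cols$`4`] <<- 250
    m[f, dqc_cols$`8`] <<- 125
    m[f, dqc_cols$`16`] <<- 62.5
  }
  for (f in 1:nf) {
    m[f, sqc_cols] <- 1000
    good_dqc(f)
  }
  # SQC-CV violators: alternating levels, CV ~ 0.37 over the 6 eligible SQCs
  for (f in 1:10) m[f, 3:8] <- rep(c(100, 200), 3L)
  # monotonicity violators: d8 mean above d4 mean
  for (f in 11:15) {
    m[f, dqc_cols$`4`] <- 125
    m[f, dqc_cols$`8`] <- 250
  }
  mz <- seq(100, 500, length.out = nf)
  mz[16:18] <- c(951, 1000, 1100)  # C18 cap is 950
  make_table(m, roles, folds, mz = mz)
}

cfg_qc_fixture <- function(...) filter_config(skip_initial_sqc = 2L, ...)

# Noiseless exact data from every packaged marker equation at the storage
# time points.
marker_curves <- function(markers, hours = c(3, 6, 12, 24, 48)) {
  lapply(seq_len(nrow(markers)), function(i) {
    list(name = markers$name[i], kind = markers$kind[i],
         kind_equation = markers$kind_equation[i],
         a = markers$a[i], b = markers$b[i], hours = hours,
         nla = marker_values(markers[i, , drop = FALSE], hours))
  })
}

# Reference sample NLAs: every marker exactly at its 48-h reference.
reference_nlas <- function(markers) {
  data.frame(assay_mode = markers$assay_mode, name = markers$name,
             nla = markers$nla_48h, stringsAsFactors = FALSE)
}
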