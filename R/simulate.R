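# Synthetic-data generator. Emits 96-well plate layouts, injection
# sequences and feature intensities with the statistical structure the
# protocol assumes — multiplicative per-feature sensitivity drift that is
# piecewise linear between RQC injections (with discontinuities at plate
# boundaries), dilution-proportional dQC response, lognormal donor effects
# and multiplicative noise — together with the ground truth for every
# emitted value.

#' Simulation configuration
#'
#' Defaults encode the reference study conditions: 88 study samples per
#' 96-well plate, ten conditioning SQC injections, an SQC after every block
#' of eight study injections with RQCs bracketing each block, a closing dQC
#' series (3 injections per fold 16/8/4/2 plus a closing SQC triplet),
#' multiplicative noise and drift, and a six-donor storage design over
#' 0/3/6/12/24/48 h at 4 and 25 degC.
#'
#' @param n_plates number of plates in one analytical sequence.
#' @param n_study_per_plate study samples per plate (max 88).
#' @param n_features number of features to simulate.
#' @param assay_mode assay mode(s) assigned to features (recycled).
#' @param n_donors,replicates_per_donor optional replicate design: each
#'   plate carries `n_donors * replicates_per_donor` study injections of
#'   `n_donors` distinct plasmas (must equal `n_study_per_plate`).
#' @param drift_amplitude maximum relative sensitivity change between
#'   consecutive RQC nodes (default 0.30).
#' @param plate_jump maximum extra relative sensitivity discontinuity at a
#'   plate boundary (default 0.30).
#' @param noise_cv standard deviation of the multiplicative lognormal
#'   noise exponent (default 0.05, i.e. about 5% CV).
#' @param donor_cv lognormal sigma of the between-donor abundance effect
#'   (default 0.20).
#' @param rqc_failure_prob probability that an RQC injection is degraded
#'   (a large fraction of its features set missing, so it fails the
#'   reliability rule).
#' @param degrade_fraction fraction of features knocked out in a degraded
#'   RQC (default 0.6).
#' @param degrade_rqc_index optional integer vector: ordinals of RQC
#'   injections to degrade deterministically.
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of the
#'   per-feature baseline abundance.
#' @param dqc_folds dilution folds of the closing dQC series.
#' @param n_dqc_replicates injections per dQC fold (and closing SQCs).
#' @param qc_block study injections per RQC-bracketed block (default 8).
#' @param n_conditioning_sqc conditioning SQC injections at the start
#'   (default 10).
#' @param storage_times,storage_temps,storage_donors the whole-blood
#'   storage design for [simulate_storage_series()].
#' @param seed integer seed; identical configurations give bit-identical
#'   output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_plates = 1L, n_study_per_plate = 88L,
                       n_features = 200L, assay_mode = "C18pos",
                       n_donors = NULL, replicates_per_donor = NULL,
                       drift_amplitude = 0.30, plate_jump = 0.30,
                       noise_cv = 0.05, donor_cv = 0.20,
                       rqc_failure_prob = 0, degrade_fraction = 0.6,
                       degrade_rqc_index = integer(0),
                       baseline_meanlog = log(1e5), baseline_sdlog = 1,
                       dqc_folds = c(16L, 8L, 4L, 2L),
                       n_dqc_replicates = 3L, qc_block = 8L,
                       n_conditioning_sqc = 10L,
                       storage_times = c(0, 3, 6, 12, 24, 48),
                       storage_temps = c(4, 25), storage_donors = 6L,
                       seed = 1L) {
  stopifnot(n_plates >= 1, n_study_per_plate >= 1, n_study_per_plate <= 88,
            n_features >= 1, drift_amplitude >= 0, drift_amplitude < 1,
            plate_jump >= 0, plate_jump < 1, noise_cv >= 0, donor_cv >= 0,
            rqc_failure_prob >= 0, rqc_failure_prob <= 1,
            degrade_fraction > 0, degrade_fraction <= 1, qc_block >= 1,
            n_conditioning_sqc >= 0, n_dqc_replicates >= 2)
  if (!is.null(n_donors)) {
    if (is.null(replicates_per_donor)) {
      replicates_per_donor <- n_study_per_plate %/% n_donors
    }
    stopifnot(n_donors * replicates_per_donor == n_study_per_plate)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' 96-well plate layout
#'
#' Study samples occupy wells A1-H11 (column-major); the QC column holds
#' the RQC at A12, the SQC at B12, the 2/4/8/16-fold dilution QCs at
#' C12-F12 and a blank at H12.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with columns `well`, `role`, `sample_index`,
#'   `dilution_fold`.
#' @export
make_plate_layout <- function(cfg) {
  if (cfg$n_study_per_plate > 88L) stop("at most 88 study wells per plate")
  wells <- as.vector(outer(LETTERS[1:8], 1:11, paste0))  # A1,B1,...,H11
  study <- data.frame(well = wells[seq_len(cfg$n_study_per_plate)],
                      role = "study",
                      sample_index = seq_len(cfg$n_study_per_plate),
                      dilution_fold = NA_integer_, stringsAsFactors = FALSE)
  qc <- data.frame(
    well = c("A12", "B12", "C12", "D12", "E12", "F12", "H12"),
    role = c("RQC", "SQC", "dQC", "dQC", "dQC", "dQC", "blank"),
    sample_index = NA_integer_,
    dilution_fold = c(NA, 1L, 2L, 4L, 8L, 16L, NA),
    stringsAsFactors = FALSE)
  rbind(study, qc)
}

# Deterministic construction given the current RNG stream.
build_run_order <- function(cfg) {
  rows <- list()
  idx <- 0L
  add <- function(role, plate, sample_id = NA_character_,
                  fold = NA_integer_, tag = role) {
    rows[[length(rows) + 1L]] <<- data.frame(
      injection_id = sprintf("%s_i%03d_%s", plate, idx, tag),
      run_index = idx, plate_id = plate, role = role, sample_id = sample_id,
      dilution_fold = fold, stringsAsFactors = FALSE)
    idx <<- idx + 1L
  }
  for (k in seq_len(cfg$n_conditioning_sqc)) add("SQC", "P1", fold = 1L)
  for (p in seq_len(cfg$n_plates)) {
    plate <- sprintf("P%d", p)
    ids <- if (!is.null(cfg$n_donors)) {
      rep(sprintf("D%d", seq_len(cfg$n_donors)),
          each = cfg$replicates_per_donor)
    } else {
      sprintf("S%03d", (p - 1L) * cfg$n_study_per_plate +
                seq_len(cfg$n_study_per_plate))
    }
    ids <- sample(ids)  # randomized injection order
    blocks <- split(ids, ceiling(seq_along(ids) / cfg$qc_block))
    for (b in blocks) {
      add("RQC", plate)
      for (s in b) add("study", plate, sample_id = s, tag = "study")
      add("SQC", plate, fold = 1L)
    }
    add("RQC", plate)  # closing RQC of the plate
  }
  last_plate <- sprintf("P%d", cfg$n_plates)
  for (fold in cfg$dqc_folds) {
    for (k in seq_len(cfg$n_dqc_replicates)) {
      add("dQC", last_plate, fold = as.integer(fold),
          tag = sprintf("d%d", fold))
    }
  }
  for (k in seq_len(cfg$n_dqc_replicates)) add("SQC", last_plate, fold = 1L)
  do.call(rbind, rows)
}

#' Injection sequence (run order) for a simulated study
#'
#' Ten conditioning SQC injections, then per plate repeating blocks of
#' [RQC, eight randomized study injections, SQC] with a closing RQC, and a
#' final dilution-QC series (three injections each of d16, d8, d4, d2)
#' followed by a closing SQC triplet. Study order is randomized under the
#' configuration seed.
#'
#' @param cfg a [sim_config()].
#' @return An injection-manifest data.frame (see [feature_table()]).
#' @export
make_run_order <- function(cfg) {
  local_seed(cfg$seed, build_run_order(cfg))
}

# Piecewise-linear per-feature sensitivity surface over the run order:
# nodes at every RQC injection, constant before the first and after the
# last node, with an extra jump factor where the plate changes.
build_drift <- function(cfg, ro, n_features) {
  node_rows <- which(ro$role == "RQC")
  n_nodes <- length(node_rows)
  v <- matrix(1, nrow = n_features, ncol = max(1L, n_nodes))
  if (n_nodes >= 2L) {
    for (k in 2:n_nodes) {
      mult <- 1 + stats::runif(n_features, -cfg$drift_amplitude,
                               cfg$drift_amplitude)
      if (ro$plate_id[node_rows[k]] != ro$plate_id[node_rows[k - 1L]]) {
        mult <- mult * (1 + stats::runif(n_features, -cfg$plate_jump,
                                         cfg$plate_jump))
      }
      v[, k] <- v[, k - 1L] * mult
    }
  }
  if (n_nodes == 0L) return(matrix(1, n_features, nrow(ro)))
  node_ri <- ro$run_index[node_rows]
  g <- matrix(NA_real_, n_features, nrow(ro))
  for (i in seq_len(nrow(ro))) {
    r <- ro$run_index[i]
    if (r <= node_ri[1L]) {
      g[, i] <- v[, 1L]
    } else if (r >= node_ri[n_nodes]) {
      g[, i] <- v[, n_nodes]
    } else {
      k <- findInterval(r, node_ri)
      w <- (r - node_ri[k]) / (node_ri[k + 1L] - node_ri[k])
      g[, i] <- v[, k] * (1 - w) + v[, k + 1L] * w
    }
  }
  g
}

# Assemble a feature table from per-sample truths, QC truths, drift and
# noise; shared by both simulators.
emit_table <- function(cfg, ro, features, truth, rqc_truth) {
  nf <- nrow(features)
  pool <- rowMeans(truth)  # SQC: pooled mixture of every study sample
  g <- build_drift(cfg, ro, nf)
  X <- matrix(NA_real_, nf, nrow(ro))
  for (i in seq_len(nrow(ro))) {
    base <- switch(ro$role[i],
      study = truth[, ro$sample_id[i]],
      SQC = pool,
      dQC = pool / ro$dilution_fold[i],
      RQC = rqc_truth,
      blank = rep(0, nf))
    noise <- if (cfg$noise_cv > 0) {
      exp(stats::rnorm(nf, 0, cfg$noise_cv))
    } else 1
    X[, i] <- base * g[, i] * noise
  }
  rqc_rows <- which(ro$role == "RQC")
  degraded <- ro$injection_id[rqc_rows[unique(c(
    which(stats::runif(length(rqc_rows)) < cfg$rqc_failure_prob),
    cfg$degrade_rqc_index))]]
  for (id in degraded) {
    i <- which(ro$injection_id == id)
    knock <- sample(nf, ceiling(cfg$degrade_fraction * nf))
    X[knock, i] <- NA_real_
  }
  dimnames(X) <- list(features$feature_id, ro$injection_id)
  list(table = feature_table(features, ro, X),
       g = `dimnames<-`(g, list(features$feature_id, ro$injection_id)),
       degraded_rqcs = degraded)
}

random_features <- function(n, assay_mode, prefix = "F") {
  mode <- rep_len(assay_mode, n)
  cap <- ifelse(startsWith(mode, "C18"), 940, 690)  # stay under the caps
  data.frame(feature_id = sprintf("%s%04d", prefix, seq_len(n)),
             mz = stats::runif(n, 60, cap), rt = stats::runif(n, 0.5, 13),
             assay_mode = mode, annotation = NA_character_,
             stringsAsFactors = FALSE)
}

#' Simulate a QC-bracketed analytical sequence
#'
#' Study-sample truths are lognormal around per-feature baselines with a
#' lognormal donor effect; the SQC truth is the pooled mean of every study
#' sample, each dQC truth is the pool divided by its dilution fold, and
#' the RQC truth is the feature baseline (the reference plasma). Emitted
#' intensities are `truth * g * exp(noise)` with `g` the piecewise-linear
#' drift surface of [sim_config()]. Degraded RQC injections (by
#' probability or by explicit index) have a large fraction of their
#' features set missing so that the reliability rule rejects them.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `gmet_simulation`: a list with `table` (the
#'   [feature_table()]), and `truth` (per-sample true abundances,
#'   per-injection sensitivities `g`, degraded RQC ids, baselines).
#' @export
simulate_intensities <- function(cfg) {
  local_seed(cfg$seed, {
    ro <- build_run_order(cfg)
    features <- random_features(cfg$n_features, cfg$assay_mode)
    nf <- cfg$n_features
    baseline <- stats::rlnorm(nf, cfg$baseline_meanlog, cfg$baseline_sdlog)
    samples <- unique(ro$sample_id[ro$role == "study"])
    truth <- vapply(samples, function(s) {
      baseline * stats::rlnorm(nf, 0, cfg$donor_cv)
    }, numeric(nf))
    dimnames(truth) <- list(features$feature_id, samples)
    em <- emit_table(cfg, ro, features, truth, rqc_truth = baseline)
    structure(list(table = em$table,
                   truth = list(truth = truth, g = em$g,
                                degraded_rqcs = em$degraded_rqcs,
                                baseline = baseline)),
              class = "gmet_simulation")
  })
}

# Baseline abundance of a marker before any 25 degC storage: the trendline
# at x = 0 for the linear kind and at x = 1 h for the power/logarithmic
# kinds (whose curves are undefined at 0); floored at 1 intensity unit.
marker_baselines <- function(markers) {
  pmax(ifelse(markers$kind_equation == "power", markers$a, markers$b), 1)
}

#' Simulate a whole-blood storage series
#'
#' Re-creates the storage design behind the quality-marker panel: each
#' donor contributes one immediately processed control sample and one
#' sample per storage temperature and time. At 25 degC a marker feature's
#' truth follows its trendline at the storage time (floored at 1, times a
#' lognormal donor effect); at 4 degC and in the control it stays at the
#' marker baseline. Null features are time-independent. The full QC
#' structure (conditioning SQCs, RQC-bracketed blocks, closing dQC series)
#' and the drift/noise model of [simulate_intensities()] apply, so the
#' output exercises the whole normalize/filter/score/select pipeline.
#'
#' All assay modes are combined in one [feature_table()] (each feature
#' carries its own `assay_mode`); per-assay subsets can be taken with the
#' feature metadata.
#'
#' @param cfg a [sim_config()]; the storage design is taken from
#'   `storage_donors`, `storage_times`, `storage_temps`.
#' @param markers a [load_marker_table()] panel; one annotated feature is
#'   emitted per marker.
#' @param n_null_features number of time-independent null features.
#' @return An object of class `gmet_simulation` whose `truth` also carries
#'   `marker_ids` (the true marker feature ids) and the sample condition
#'   map.
#' @export
simulate_storage_series <- function(cfg, markers = load_marker_table(),
                                    n_null_features = 100L) {
  nm <- nrow(markers)
  donors <- sprintf("D%d", seq_len(cfg$storage_donors))
  times <- sort(cfg$storage_times)
  stopifnot(0 %in% times)
  conds <- c("T0", as.vector(outer(
    cfg$storage_temps, setdiff(times, 0),
    function(temp, t) sprintf("%gC_%gh", temp, t))))
  samples <- as.vector(outer(donors, conds, paste, sep = "_"))

  local_seed(cfg$seed, {
    mk_feat <- random_features(nm, markers$assay_mode, prefix = "MK")
    mk_feat$annotation <- markers$name
    null_modes <- rep_len(ASSAY_MODES, max(1L, n_null_features))
    nul_feat <- if (n_null_features > 0L) {
      random_features(n_null_features, null_modes, prefix = "NF")
    } else NULL
    features <- rbind(mk_feat, nul_feat)
    nf <- nrow(features)

    base <- c(marker_baselines(markers),
              if (n_null_features > 0L) {
                stats::rlnorm(n_null_features, cfg$baseline_meanlog,
                              cfg$baseline_sdlog)
              })
    donor_eff <- matrix(stats::rlnorm(nf * length(donors), 0, cfg$donor_cv),
                        nf, length(donors), dimnames = list(NULL, donors))
    truth <- matrix(NA_real_, nf, length(samples),
                    dimnames = list(features$feature_id, samples))
    for (s in samples) {
      parts <- strsplit(s, "_")[[1L]]
      d <- parts[1L]
      stored25 <- length(parts) == 3L && parts[2L] == "25C"
      t_h <- if (stored25) as.numeric(sub("h$", "", parts[3L])) else 0
      v <- base
      if (stored25) {
        v <- c(pmax(marker_values(markers, t_h), 1),
               utils::tail(base, nf - nm))
      }
      truth[, s] <- v * donor_eff[, d]
    }

    cfg_run <- cfg
    cfg_run$n_plates <- 1L
    cfg_run$n_study_per_plate <- length(samples)
    cfg_run$n_donors <- NULL
    ro <- build_run_order(cfg_run)
    ro$sample_id[ro$role == "study"] <-
      sample(samples)[match(ro$sample_id[ro$role == "study"],
                            sprintf("S%03d", seq_along(samples)))]
    em <- emit_table(cfg_run, ro, features, truth,
                     rqc_truth = base)
    structure(list(table = em$table,
                   truth = list(truth = truth, g = em$g,
                                degraded_rqcs = em$degraded_rqcs,
                                baseline = base,
                                marker_ids = mk_feat$feature_id,
                                samples = samples)),
              class = "gmet_simulation")
  })
}

#' @export
print.gmet_simulation <- function(x, ...) {
  cat("gmet_simulation\n")
  print(x$table)
  if (!is.null(x$truth$marker_ids)) {
    cat(sprintf("  true marker features: %d\n", length(x$truth$marker_ids)))
  }
  if (length(x$truth$degraded_rqcs)) {
    cat("  degraded RQCs:", paste(x$truth$degraded_rqcs, collapse = ", "),
        "\n")
  }
  invisible(x)
}
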