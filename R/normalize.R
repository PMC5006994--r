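# Reference-QC (RQC) based drift normalization. A commercial reference
# plasma is injected at intervals through the sequence; between two reliable
# RQC injections the per-feature sensitivity is assumed to drift linearly,
# and every intensity in between is divided by the interpolated sensitivity
# and re-expressed on the scale of an anchor RQC.

#' Count undetectable features in one injection
#'
#' A feature is undetectable when its cell is missing or exactly zero (a
#' zero is kept as 0 in arithmetic where present, but counts as undetected
#' for RQC reliability assessment).
#'
#' @param table a [feature_table()].
#' @param injection an `injection_id` present in the table.
#' @return Integer count.
#' @export
count_undetectable <- function(table, injection) {
  v <- table$intensities[, injection_column(table, injection)]
  sum(is.na(v) | v == 0)
}

# A threshold < 1 is read as a fraction of the feature count, so the
# absolute default (1000 undetectable compounds) can be scaled to small
# synthetic tables.
resolve_rqc_threshold <- function(table, threshold) {
  if (threshold < 1) max(1, ceiling(threshold * n_features(table)))
  else threshold
}

#' Is an RQC injection reliable?
#'
#' An RQC injection is reliable when fewer than `threshold` features are
#' undetectable in it; with the threshold at its default of 1000, an RQC
#' with exactly 1000 undetectable compounds is unreliable. A `threshold`
#' below 1 is interpreted as a fraction of the feature count.
#'
#' @inheritParams count_undetectable
#' @param threshold undetectable-feature count (or fraction) above or at
#'   which the injection is deemed unreliable.
#' @return `TRUE` or `FALSE`.
#' @export
is_reliable_rqc <- function(table, injection, threshold = 1000) {
  role <- table$injections$role[injection_column(table, injection)]
  if (role != "RQC") stop("injection ", injection, " has role ", role,
                          ", not RQC")
  count_undetectable(table, injection) < resolve_rqc_threshold(table, threshold)
}

#' Segment an analytical sequence between reliable RQC injections
#'
#' Consecutive reliable RQCs are paired into segments; an unreliable RQC is
#' skipped, so the injections around it fall into the enclosing, longer
#' segment. Injections before the first or after the last reliable RQC are
#' reported as uncovered.
#'
#' @inheritParams is_reliable_rqc
#' @return An object of class `rqc_segmentation`: a list with `segments`
#'   (each holding `left_rqc`, `right_rqc`, `members` — every injection
#'   strictly between the flanks — `study_injections` and their count `S`),
#'   `reliable`, `unreliable` (with undetectable counts) and `uncovered`.
#' @export
segment_run <- function(table, threshold = 1000) {
  inj <- table$injections
  rqc <- inj$injection_id[inj$role == "RQC"]
  if (!length(rqc)) stop("the sequence contains no RQC injections")
  ok <- vapply(rqc, function(id) is_reliable_rqc(table, id, threshold),
               logical(1L))
  rel <- rqc[ok]
  if (length(rel) < 2L) {
    stop("fewer than two reliable RQC injections; drift correction is ",
         "impossible - use the raw intensities")
  }
  ri <- inj$run_index[match(rel, inj$injection_id)]
  segments <- vector("list", length(rel) - 1L)
  for (k in seq_len(length(rel) - 1L)) {
    between <- inj$run_index > ri[k] & inj$run_index < ri[k + 1L]
    members <- inj$injection_id[between]
    study <- inj$injection_id[between & inj$role == "study"]
    segments[[k]] <- list(left_rqc = rel[k], right_rqc = rel[k + 1L],
                          members = members, study_injections = study,
                          S = length(study))
  }
  uncovered <- inj$injection_id[inj$run_index < ri[1L] |
                                inj$run_index > ri[length(ri)]]
  unrel <- rqc[!ok]
  structure(list(
    segments = segments,
    reliable = rel,
    unreliable = data.frame(
      injection_id = unrel,
      n_undetectable = vapply(unrel, function(id) {
        count_undetectable(table, id)
      }, integer(1L)),
      stringsAsFactors = FALSE, row.names = NULL),
    uncovered = uncovered,
    threshold = resolve_rqc_threshold(table, threshold)
  ), class = "rqc_segmentation")
}

#' @export
print.rqc_segmentation <- function(x, ...) {
  cat(sprintf("rqc_segmentation: %d segment(s), %d reliable RQC(s), %d unreliable, %d uncovered injection(s)\n",
              length(x$segments), length(x$reliable), nrow(x$unreliable),
              length(x$uncovered)))
  invisible(x)
}

#' Linearly interpolated per-feature sensitivity between two RQCs
#'
#' With `S` study injections between the flanking RQCs, the sensitivity at
#' 1-based position `n` is `M1 + n * (M2 - M1) / (S + 1)`; for the canonical
#' block of eight study injections this is the divisor 9 of the correction
#' equation. `n = 0` returns `M1` and `n = S + 1` returns `M2`.
#'
#' @param M1,M2 intensity of the feature in the left and right RQC; both
#'   must be positive.
#' @param n position within the segment, `0 <= n <= S + 1`.
#' @param S number of injections strictly between the two RQCs.
#' @return Interpolated sensitivity (intensity units).
#' @export
interpolate_sensitivity <- function(M1, M2, n, S) {
  if (any(!is.finite(M1)) || any(!is.finite(M2)) || any(M1 <= 0) ||
      any(M2 <= 0)) {
    stop("flanking RQC intensities must be positive")
  }
  if (any(n < 0) || any(n > S + 1)) stop("n must lie in [0, S + 1]")
  M1 + n * (M2 - M1) / (S + 1)
}

#' Correct sensitivity drift against the reference QC injections
#'
#' Every injection covered by a pair of reliable RQCs is corrected by
#' `y = x * M1 / (M1 + n * (M2 - M1) / D)`, where `M1` and `M2` are the
#' feature's intensities at the left and right interpolation node, `n` is
#' the injection's run-index offset from the left node and `D` the node
#' run-index gap (equal to `S + 1` when exactly `S` injections sit between
#' adjacent RQCs, hence the divisor 9 for the canonical 8-study block).
#' Interpolation is linear in run index, so a sensitivity that drifts
#' linearly between RQC injections is removed exactly.
#'
#' Two output scales are offered. In `literal` mode each segment is anchored
#' to its own left RQC, the correction equation verbatim. In `anchored` mode
#' (the default) every segment is additionally rescaled per feature by
#' `M1_first / M1_segment`, with `M1_first` the feature's intensity at the
#' first reliable RQC of the sequence, making intensities comparable across
#' segments and plates; after anchored normalization every reliable RQC
#' equals the first RQC's value per feature.
#'
#' When a feature is unquantified (missing, zero or nonpositive) in a
#' flanking RQC, the nearest reliable RQC on that side in which the feature
#' is quantified is substituted as the interpolation node; if no quantified
#' reliable RQC exists on one side, the feature is left raw for that
#' segment. Both fallbacks are counted in the report. Injections before the
#' first or after the last reliable RQC pass through unchanged and are
#' flagged as uncovered. Missingness is preserved; no negative intensity
#' can be produced.
#'
#' @inheritParams is_reliable_rqc
#' @param mode `"anchored"` (default) or `"literal"`.
#' @return A list with `table` (the normalized [feature_table()]) and
#'   `report` (class `normalization_report`: unreliable RQCs, fallback and
#'   raw (segment, feature) pair counts, uncovered injections, mode,
#'   resolved threshold).
#' @export
normalize_table <- function(table, threshold = 1000,
                            mode = c("anchored", "literal")) {
  mode <- match.arg(mode)
  seg <- segment_run(table, threshold)
  inj <- table$injections
  X <- table$intensities
  Y <- X

  rel <- seg$reliable
  relpos <- match(rel, inj$injection_id)
  relri <- inj$run_index[relpos]
  K <- length(rel)
  Q <- X[, relpos, drop = FALSE]
  qok <- is.finite(Q) & Q > 0

  n_fallback <- 0L
  n_raw <- 0L

  # Precompute, per segment, the covered columns (everything strictly after
  # the left flank up to and including the right flank; the first reliable
  # RQC is attached to segment 1 with offset handled by the generic formula).
  seg_cols <- vector("list", K - 1L)
  for (k in seq_len(K - 1L)) {
    cols <- which(inj$run_index > relri[k] & inj$run_index <= relri[k + 1L])
    if (k == 1L) cols <- c(relpos[1L], cols)
    seg_cols[[k]] <- cols
  }

  for (f in seq_len(nrow(X))) {
    qf <- which(qok[f, ])
    if (!length(qf)) {
      n_raw <- n_raw + (K - 1L)
      next
    }
    anchor <- Q[f, qf[1L]]
    for (k in seq_len(K - 1L)) {
      lcand <- qf[qf <= k]
      rcand <- qf[qf >= k + 1L]
      if (!length(lcand) || !length(rcand)) {
        n_raw <- n_raw + 1L
        next
      }
      li <- max(lcand)
      riidx <- min(rcand)
      if (li != k || riidx != k + 1L) n_fallback <- n_fallback + 1L
      M1 <- Q[f, li]
      M2 <- Q[f, riidx]
      r1 <- relri[li]
      r2 <- relri[riidx]
      cols <- seg_cols[[k]]
      n <- inj$run_index[cols] - r1
      denom <- M1 + n * (M2 - M1) / (r2 - r1)
      scale_to <- if (mode == "anchored") anchor else M1
      # ratio first: when M1 == M2 == scale_to the factor is exactly 1
      Y[f, cols] <- X[f, cols] * (scale_to / denom)
    }
  }

  report <- structure(list(
    mode = mode,
    threshold = seg$threshold,
    n_segments = length(seg$segments),
    unreliable_rqcs = seg$unreliable,
    fallback_features = n_fallback,
    raw_feature_segments = n_raw,
    uncovered = seg$uncovered
  ), class = "normalization_report")

  list(table = feature_table(table$features, inj, Y), report = report)
}

#' @export
print.normalization_report <- function(x, ...) {
  cat(sprintf("normalization_report (%s mode): %d segment(s)\n", x$mode,
              x$n_segments))
  cat(sprintf("  unreliable RQCs: %d; fallback (segment, feature) pairs: %d; raw pairs: %d\n",
              nrow(x$unreliable_rqcs), x$fallback_features,
              x$raw_feature_segments))
  cat(sprintf("  uncovered injections: %d\n", length(x$uncovered)))
  invisible(x)
}
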