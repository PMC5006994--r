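# Plasma quality scoring. A packaged panel of 40 quality-marker
# metabolites, each with a storage-time trendline, converts normalized
# abundances into per-marker points P_k and a 0-100 quality score; samples
# below the 85-point threshold are triaged as low quality.

MARKER_GROUPS <- c(C18pos = "CP", C18neg = "CN", HILICpos = "HP",
                   HILICneg = "HN")

#' Load the quality-marker panel
#'
#' The packaged panel holds 40 plasma metabolites whose abundance changes
#' systematically with whole-blood storage time at 25 degC: 10 HILIC
#' positive, 15 HILIC negative, 10 C18 positive and 5 C18 negative markers;
#' 30 increase and 10 (glucose, uric acid, some amino acids, ...) decrease.
#' Each row carries the marker's trendline (kind and coefficients a, b),
#' the published R-squared, and the reference abundance `nla_48h`, which
#' defaults to the trendline evaluated at 48 h, floored at 1 intensity
#' unit (an abundance reference cannot be negative, but a steep linear
#' decrease can extrapolate past zero; the affected markers are recorded
#' in the `floored_reference` attribute).
#'
#' Two rows of the source panel pair a trendline label with the other
#' form's equation (Uric acid: a "logarithmic" label over a linear-form
#' equation; Ribonic acid: a "linear" label over a log-form equation).
#' Numerical evaluation always follows the equation's form; `variant`
#' selects which label the `kind` column reports: `"as_printed"` keeps the
#' original labels, `"swap_corrected"` makes them match the equations.
#'
#' @param path CSV with columns name, assay_mode, direction, kind_printed,
#'   kind_equation, a, b, r2_printed; `NULL` (default) loads the packaged
#'   panel.
#' @param variant `"as_printed"` (default) or `"swap_corrected"`.
#' @return A data.frame of class `quality_marker_table` with one row per
#'   marker and columns name, assay_mode, group, direction, kind,
#'   kind_equation, a, b, r2_printed, nla_48h.
#' @export
load_marker_table <- function(path = NULL,
                              variant = c("as_printed", "swap_corrected")) {
  variant <- match.arg(variant)
  if (is.null(path)) {
    path <- system.file("extdata", "quality_markers.csv", package = "gmetkit",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) stop("no such marker table: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("name", "assay_mode", "direction", "kind_printed",
            "kind_equation", "a", "b", "r2_printed")
  if (!all(need %in% names(m))) {
    stop("marker table lacks column(s): ",
         paste(setdiff(need, names(m)), collapse = ", "))
  }
  for (i in seq_len(nrow(m))) {
    ok <- nzchar(m$name[i]) && m$assay_mode[i] %in% ASSAY_MODES &&
      m$direction[i] %in% c("increasing", "decreasing") &&
      m$kind_printed[i] %in% TRENDLINE_KINDS &&
      m$kind_equation[i] %in% TRENDLINE_KINDS &&
      is.finite(m$a[i]) && is.finite(m$b[i])
    if (!ok) stop("malformed marker table row ", i)
  }
  dup <- duplicated(paste(m$assay_mode, m$name))
  if (any(dup)) stop("duplicate marker name within an assay mode: ",
                     paste(m$name[dup], collapse = ", "))
  m$group <- unname(MARKER_GROUPS[m$assay_mode])
  m$kind <- if (variant == "as_printed") m$kind_printed else m$kind_equation
  # the 48-h reference is a measured abundance and cannot be negative; a
  # steep linear decrease can extrapolate past zero at 48 h, so the default
  # is floored at 1 intensity unit (the same floor the simulator applies)
  raw48 <- marker_values(m, 48)
  m$nla_48h <- pmax(raw48, 1)
  out <- m[, c("name", "assay_mode", "group", "direction", "kind",
               "kind_equation", "a", "b", "r2_printed", "nla_48h")]
  class(out) <- c("quality_marker_table", "data.frame")
  attr(out, "floored_reference") <- out$name[raw48 < 1]
  out
}

#' Evaluate every marker's trendline at given storage times
#'
#' Vectorized over markers; evaluation follows each marker's equation form
#' (`kind_equation`), i.e. the curve the coefficients were fitted for.
#'
#' @param markers a [load_marker_table()] data.frame (or any data.frame
#'   with kind_equation, a, b).
#' @param hours a single storage time or one per marker (h, > 0 for
#'   power/logarithmic markers); with a single marker, a vector of times.
#' @return Numeric vector of abundances, one per marker (or one per time
#'   for a single marker).
#' @export
marker_values <- function(markers, hours) {
  if (nrow(markers) == 1L) {
    return(evaluate_trendline(
      trendline_fit(markers$kind_equation, markers$a, markers$b), hours))
  }
  hours <- rep_len(hours, nrow(markers))
  vapply(seq_len(nrow(markers)), function(i) {
    evaluate_trendline(
      trendline_fit(markers$kind_equation[i], markers$a[i], markers$b[i]),
      hours[i])
  }, numeric(1L))
}

#' Per-marker quality points P_k
#'
#' The literal rule awards `scale * (nla_48h - nla_sample) / nla_48h`
#' points (with `scale = 100/40` for the full panel): 0 when the sample
#' sits at the 48-h degraded reference, `scale` when the marker is absent.
#' In direction-aware mode the sign is flipped for decreasing markers, so
#' a fresh sample (e.g. glucose above its 48-h level) is not penalized.
#' The result is clamped to `[-scale, scale]`.
#'
#' @param marker one marker (a one-row data.frame or list with `nla_48h`
#'   and `direction`).
#' @param nla_sample the sample's normalized abundance for this marker
#'   (>= 0).
#' @param direction_aware flip the sign for decreasing markers?
#' @param scale maximum points per marker (default 100/40 = 2.5).
#' @param clamp clamp to `[-scale, scale]`? (default TRUE).
#' @return Points for this marker.
#' @export
compute_pk <- function(marker, nla_sample, direction_aware = FALSE,
                       scale = 100 / 40, clamp = TRUE) {
  if (any(!is.finite(nla_sample)) || any(nla_sample < 0)) {
    stop("nla_sample must be a nonnegative number")
  }
  p <- scale * (marker$nla_48h - nla_sample) / marker$nla_48h
  if (direction_aware && identical(marker$direction, "decreasing")) p <- -p
  if (clamp) p <- pmax(pmin(p, scale), -scale)
  p
}

#' Plasma quality score over the marker panel
#'
#' Sums the per-marker points within the four assay groups (CP = C18pos,
#' CN = C18neg, HP = HILICpos, HN = HILICneg) and totals them; a sample
#' passes at `total >= threshold` (default 85 points). When fewer than the
#' full panel of markers is matched, the per-marker factor 100/40 is
#' rescaled to 100/n so the score keeps its 0-100 range.
#'
#' @param sample_nlas data.frame with columns `assay_mode`, `name`, `nla`:
#'   the sample's normalized abundance per marker.
#' @param markers a [load_marker_table()] panel.
#' @param mode `"literal"` (default; the published rule) or
#'   `"direction_aware"` (sign-flipped for decreasing markers).
#' @param threshold pass/fail boundary (default 85; pass at >= 85).
#' @param clamp clamp each P_k to `[-100/n, 100/n]`?
#' @return An object of class `quality_score_result`: per-marker points,
#'   per-group subtotals, total, `n_markers_used`, `pass`.
#' @export
compute_quality_score <- function(sample_nlas, markers = load_marker_table(),
                                  mode = c("literal", "direction_aware"),
                                  threshold = 85, clamp = TRUE) {
  mode <- match.arg(mode)
  stopifnot(all(c("assay_mode", "name", "nla") %in% names(sample_nlas)))
  key <- paste(markers$assay_mode, markers$name, sep = ":")
  skey <- paste(sample_nlas$assay_mode, sample_nlas$name, sep = ":")
  idx <- match(key, skey)
  matched <- which(!is.na(idx) & is.finite(sample_nlas$nla[idx]))
  n <- length(matched)
  if (n == 0L) stop("no sample abundance matches any marker")
  scale <- 100 / n
  mm <- markers[matched, , drop = FALSE]
  nla <- sample_nlas$nla[idx[matched]]
  pts <- vapply(seq_len(n), function(i) {
    compute_pk(mm[i, ], nla[i], direction_aware = mode == "direction_aware",
               scale = scale, clamp = clamp)
  }, numeric(1L))
  per_marker <- data.frame(name = mm$name, assay_mode = mm$assay_mode,
                           group = mm$group, nla_48h = mm$nla_48h,
                           nla_sample = nla, points = pts,
                           stringsAsFactors = FALSE)
  subtotals <- vapply(unname(MARKER_GROUPS), function(g) {
    sum(pts[mm$group == g])
  }, numeric(1L))
  names(subtotals) <- unname(MARKER_GROUPS)
  total <- sum(subtotals)
  structure(list(per_marker = per_marker, subtotals = subtotals,
                 total = total, n_markers_used = n,
                 pass = total >= threshold, threshold = threshold,
                 mode = mode),
            class = "quality_score_result")
}

#' @export
print.quality_score_result <- function(x, ...) {
  cat(sprintf("quality score (%s mode): %.2f points over %d marker(s) -> %s (threshold %g)\n",
              x$mode, x$total, x$n_markers_used,
              if (x$pass) "PASS" else "FAIL", x$threshold))
  cat("  subtotals:",
      paste(sprintf("%s=%.2f", names(x$subtotals), x$subtotals),
            collapse = ", "), "\n")
  invisible(x)
}

#' Extract per-marker abundances for one sample from a feature table
#'
#' Matches annotated features to the marker panel by compound name and
#' assay mode, then averages the intensities over the selected injections
#' (all study injections of `sample_id`, or the given `injection_id`s).
#'
#' @param table a (normalized) [feature_table()] with annotated marker
#'   features.
#' @param markers a [load_marker_table()] panel.
#' @param sample_id a study `sample_id` present in the manifest.
#' @param injection_id alternatively, explicit injection ids.
#' @return data.frame with columns `assay_mode`, `name`, `nla` (matched
#'   markers only), suitable for [compute_quality_score()].
#' @export
marker_nlas_from_table <- function(table, markers, sample_id = NULL,
                                   injection_id = NULL) {
  inj <- table$injections
  if (is.null(injection_id)) {
    if (is.null(sample_id)) stop("give sample_id or injection_id")
    injection_id <- inj$injection_id[inj$role == "study" &
                                     !is.na(inj$sample_id) &
                                     inj$sample_id == sample_id]
    if (!length(injection_id)) stop("no study injection for sample ",
                                    sample_id)
  }
  jc <- match(injection_id, inj$injection_id)
  if (anyNA(jc)) stop("unknown injection_id")
  f <- table$features
  fkey <- paste(f$assay_mode, f$annotation, sep = ":")
  mkey <- paste(markers$assay_mode, markers$name, sep = ":")
  fi <- match(mkey, fkey)
  hit <- which(!is.na(fi))
  nla <- vapply(fi[hit], function(r) {
    v <- table$intensities[r, jc]
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1L))
  out <- data.frame(assay_mode = markers$assay_mode[hit],
                    name = markers$name[hit], nla = nla,
                    stringsAsFactors = FALSE)
  out[is.finite(out$nla), , drop = FALSE]
}

#' Score every study sample in a feature table
#'
#' @inheritParams marker_nlas_from_table
#' @inheritParams compute_quality_score
#' @return data.frame with one row per study sample: `sample_id`, `score`,
#'   `n_markers_used`, `pass`.
#' @export
score_samples <- function(table, markers = load_marker_table(),
                          mode = c("literal", "direction_aware"),
                          threshold = 85) {
  mode <- match.arg(mode)
  inj <- table$injections
  samples <- unique(inj$sample_id[inj$role == "study" & !is.na(inj$sample_id)])
  rows <- lapply(samples, function(s) {
    nlas <- marker_nlas_from_table(table, markers, sample_id = s)
    res <- compute_quality_score(nlas, markers, mode = mode,
                                 threshold = threshold)
    data.frame(sample_id = s, score = res$total,
               n_markers_used = res$n_markers_used, pass = res$pass,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
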