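# Feature selection with the QC injections: repeatability over the
# intercalated SQC injections, dilution-proportional response over the dQC
# series, and assay-specific m/z caps. Filters run on normalized
# intensities and are pure predicates, so their order does not matter.

#' Filtering configuration
#'
#' @param cv_threshold maximum tolerated coefficient of variation over the
#'   eligible SQC injections, as a fraction (default 0.30; a feature at
#'   exactly the threshold is retained — only CVs *over* it are eliminated).
#' @param dqc_cv_threshold maximum CV within each dilution level's replicate
#'   injections (default 0.30).
#' @param mz_cap_c18,mz_cap_hilic exclusive upper m/z bounds for C18 and
#'   HILIC features (defaults 950 and 700 Da); heavier features are treated
#'   as probable noise or column contaminants.
#' @param monotonicity_rule `"strict_means"` (mean intensity strictly
#'   decreasing over dilution folds 1, 2, 4, 8, 16) or `"spearman"`
#'   (Spearman correlation of mean intensity with fold equal to -1;
#'   equivalent on five complete levels).
#' @param skip_initial_sqc number of column-conditioning SQC injections at
#'   the head of the sequence to exclude from the repeatability CV
#'   (default 10).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(cv_threshold = 0.30, dqc_cv_threshold = 0.30,
                          mz_cap_c18 = 950, mz_cap_hilic = 700,
                          monotonicity_rule = c("strict_means", "spearman"),
                          skip_initial_sqc = 10L) {
  stopifnot(cv_threshold > 0, cv_threshold <= 1,
            dqc_cv_threshold > 0, dqc_cv_threshold <= 1,
            mz_cap_c18 > 0, mz_cap_hilic > 0, skip_initial_sqc >= 0)
  structure(list(cv_threshold = cv_threshold,
                 dqc_cv_threshold = dqc_cv_threshold,
                 mz_cap_c18 = mz_cap_c18, mz_cap_hilic = mz_cap_hilic,
                 monotonicity_rule = match.arg(monotonicity_rule),
                 skip_initial_sqc = as.integer(skip_initial_sqc)),
            class = "filter_config")
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean, over
#' the present (finite) values. Returns `NA` when fewer than two values are
#' present or the mean is not positive; callers treat `NA` as unevaluable.
#'
#' @param values numeric vector of intensities (NA = undetected).
#' @return CV as a fraction, or `NA`.
#' @export
coefficient_of_variation <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2L) return(NA_real_)
  m <- mean(v)
  if (m <= 0) return(NA_real_)
  stats::sd(v) / m
}

# Repeatability is defined on the SQCs intercalated with the study blocks:
# the conditioning SQCs at the head are excluded by count, and the closing
# SQCs of the dilution series (after the last RQC) are excluded because
# they lie outside the drift-corrected part of the sequence.
eligible_sqc_ids <- function(table, cfg) {
  inj <- table$injections
  keep <- inj$role == "SQC"
  if (any(inj$role == "RQC")) {
    keep <- keep & inj$run_index <= max(inj$run_index[inj$role == "RQC"])
  }
  sqc <- inj$injection_id[keep]  # already in run order
  if (cfg$skip_initial_sqc > 0L && length(sqc)) {
    sqc <- sqc[-seq_len(min(cfg$skip_initial_sqc, length(sqc)))]
  }
  sqc
}

#' SQC repeatability filter
#'
#' Fails every feature whose CV over the eligible SQC injections exceeds
#' `cfg$cv_threshold` (strictly), or that is unevaluable (< 2 present SQC
#' values or nonpositive mean). The first `cfg$skip_initial_sqc`
#' column-conditioning SQCs are excluded.
#'
#' @param table a [feature_table()] (normalized intensities).
#' @param cfg a [filter_config()].
#' @return Character vector of failing `feature_id`s.
#' @export
sqc_cv_filter <- function(table, cfg = filter_config()) {
  sqc <- eligible_sqc_ids(table, cfg)
  if (!length(sqc)) stop("no eligible SQC injections after excluding the ",
                         cfg$skip_initial_sqc, " conditioning injections")
  m <- table$intensities[, match(sqc, table$injections$injection_id),
                         drop = FALSE]
  cv <- apply(m, 1L, coefficient_of_variation)
  table$features$feature_id[is.na(cv) | cv > cfg$cv_threshold]
}

# Replicate injections per dilution level: folds 2/4/8/16 from the dQC
# injections, fold 1 from the closing SQC triplet (SQCs after the last dQC;
# if the sequence has none, the last eligible SQCs stand in).
dilution_level_ids <- function(table, cfg) {
  inj <- table$injections
  dqc <- inj[inj$role == "dQC", , drop = FALSE]
  if (!nrow(dqc)) stop("the sequence contains no dQC injections")
  levels <- split(dqc$injection_id, dqc$dilution_fold)
  sqc <- inj[inj$role == "SQC", , drop = FALSE]
  closing <- sqc$injection_id[sqc$run_index > max(dqc$run_index)]
  if (!length(closing)) {
    elig <- eligible_sqc_ids(table, cfg)
    closing <- utils::tail(elig, 3L)
  }
  levels[["1"]] <- closing
  need <- as.character(c(1, 2, 4, 8, 16))
  missing <- setdiff(need, names(levels))
  if (length(missing)) {
    stop("missing dilution level(s): fold ", paste(missing, collapse = ", "))
  }
  levels[need]
}

dqc_response_details <- function(table, cfg = filter_config()) {
  levels <- dilution_level_ids(table, cfg)
  folds <- as.numeric(names(levels))
  cols <- lapply(levels, function(ids) {
    match(ids, table$injections$injection_id)
  })
  nf <- n_features(table)
  cv_fail <- logical(nf)
  mono_fail <- logical(nf)
  for (f in seq_len(nf)) {
    vals <- lapply(cols, function(j) {
      v <- table$intensities[f, j]
      v[is.finite(v)]
    })
    if (any(vapply(vals, length, integer(1L)) < 2L)) {
      mono_fail[f] <- TRUE  # unevaluable dilution response
      next
    }
    cvs <- vapply(vals, function(v) coefficient_of_variation(v), numeric(1L))
    if (anyNA(cvs) || any(cvs > cfg$dqc_cv_threshold)) cv_fail[f] <- TRUE
    means <- vapply(vals, mean, numeric(1L))
    ok <- if (cfg$monotonicity_rule == "strict_means") {
      all(diff(means) < 0)
    } else {
      isTRUE(all.equal(
        stats::cor(means, folds, method = "spearman"), -1))
    }
    if (!ok) mono_fail[f] <- TRUE
  }
  data.frame(feature_id = table$features$feature_id,
             dqc_cv = cv_fail, dqc_monotonicity = mono_fail,
             stringsAsFactors = FALSE)
}

#' Dilution-series response filter
#'
#' A feature passes only if (a) its CV within each dilution level's
#' replicate injections (folds 1, 2, 4, 8, 16; fold 1 is the closing SQC
#' triplet) is at most `cfg$dqc_cv_threshold`, and (b) its mean intensity is
#' inversely related to the dilution fold under `cfg$monotonicity_rule` —
#' for instance a d8QC mean above the d4QC mean fails. A feature missing a
#' full dilution level is unevaluable and fails.
#'
#' @inheritParams sqc_cv_filter
#' @return Character vector of failing `feature_id`s.
#' @export
dqc_response_filter <- function(table, cfg = filter_config()) {
  d <- dqc_response_details(table, cfg)
  d$feature_id[d$dqc_cv | d$dqc_monotonicity]
}

#' Assay-specific m/z cap filter
#'
#' Fails C18 features above `cfg$mz_cap_c18` and HILIC features above
#' `cfg$mz_cap_hilic`; both caps are exclusive (a feature exactly at the
#' cap is retained).
#'
#' @inheritParams sqc_cv_filter
#' @return Character vector of failing `feature_id`s.
#' @export
mz_cap_filter <- function(table, cfg = filter_config()) {
  f <- table$features
  cap <- ifelse(startsWith(f$assay_mode, "C18"), cfg$mz_cap_c18,
                cfg$mz_cap_hilic)
  f$feature_id[f$mz > cap]
}

#' Apply all QC filters and account for every removal
#'
#' Composes [sqc_cv_filter()], [dqc_response_filter()] and
#' [mz_cap_filter()]; the filtered table contains exactly the features that
#' fail no rule, and the report assigns one or more reason codes
#' (`sqc_cv`, `dqc_cv`, `dqc_monotonicity`, `mz_cap`) to every removed
#' feature, so retained + removed always equals the feature total.
#'
#' @inheritParams sqc_cv_filter
#' @return A list with `table` (the filtered [feature_table()]) and
#'   `report` (class `filter_report`: per-feature decisions, per-reason
#'   counts, retained count).
#' @export
apply_all_filters <- function(table, cfg = filter_config()) {
  ids <- table$features$feature_id
  if (!length(ids)) {
    report <- structure(list(
      decisions = data.frame(feature_id = character(0),
                             retained = logical(0), reasons = character(0),
                             stringsAsFactors = FALSE),
      counts = c(sqc_cv = 0L, dqc_cv = 0L, dqc_monotonicity = 0L,
                 mz_cap = 0L),
      retained = 0L, total = 0L), class = "filter_report")
    return(list(table = table, report = report))
  }
  sqc_fail <- sqc_cv_filter(table, cfg)
  dqc <- dqc_response_details(table, cfg)
  mz_fail <- mz_cap_filter(table, cfg)

  reasons <- data.frame(
    sqc_cv = ids %in% sqc_fail,
    dqc_cv = dqc$dqc_cv[match(ids, dqc$feature_id)],
    dqc_monotonicity = dqc$dqc_monotonicity[match(ids, dqc$feature_id)],
    mz_cap = ids %in% mz_fail)
  retained <- !apply(reasons, 1L, any)
  reason_str <- apply(reasons, 1L, function(r) {
    paste(names(reasons)[r], collapse = ",")
  })
  decisions <- data.frame(feature_id = ids, retained = retained,
                          reasons = reason_str, stringsAsFactors = FALSE)
  report <- structure(list(
    decisions = decisions,
    counts = vapply(reasons, sum, integer(1L)),
    retained = sum(retained),
    total = length(ids)), class = "filter_report")
  list(table = subset_features(table, ids[retained]), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d of %d features retained\n", x$retained,
              x$total))
  cat("  removal reasons:",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "),
      "\n")
  invisible(x)
}
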