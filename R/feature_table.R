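# Feature-table data model: one row per (m/z, retention-time) feature, one
# column per injection, plus an injection manifest carrying the run order and
# QC roles. All downstream operations consume this container.

ASSAY_MODES <- c("C18pos", "C18neg", "HILICpos", "HILICneg")
INJECTION_ROLES <- c("study", "SQC", "dQC", "RQC", "blank")
DILUTION_FOLDS <- c(1L, 2L, 4L, 8L, 16L)

#' Construct a feature table
#'
#' A `feature_table` bundles feature metadata (m/z, retention time, assay
#' mode), an injection manifest (run order, plate, QC role) and a
#' features-by-injections intensity matrix. `NA` marks an undetected cell;
#' present intensities must be nonnegative. Injections are sorted by
#' `run_index` on construction, so column order always reflects the
#' analytical sequence.
#'
#' @param features data.frame with columns `feature_id`, `mz`, `rt`,
#'   `assay_mode` and optionally `annotation` (compound name, `NA` if
#'   unannotated).
#' @param injections data.frame with columns `injection_id`, `run_index`
#'   (0-based, unique, global across plates), `plate_id`, `role` (one of
#'   study/SQC/dQC/RQC/blank) and optionally `sample_id` (study injections)
#'   and `dilution_fold` (SQC/dQC; an SQC is dilution fold 1).
#' @param intensities numeric matrix, features x injections. If it carries
#'   column names they are matched against `injection_id`, otherwise columns
#'   are taken in the order of `injections` before sorting.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, injections, intensities) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  injections <- as.data.frame(injections, stringsAsFactors = FALSE)
  if (is.null(features$annotation)) features$annotation <- NA_character_
  if (is.null(injections$sample_id)) injections$sample_id <- NA_character_
  if (is.null(injections$dilution_fold)) {
    injections$dilution_fold <- NA_integer_
  }
  injections$run_index <- as.integer(injections$run_index)
  injections$dilution_fold <- as.integer(injections$dilution_fold)
  # an SQC is by definition the undiluted pool
  injections$dilution_fold[injections$role == "SQC" &
    is.na(injections$dilution_fold)] <- 1L

  intensities <- as.matrix(intensities)
  if (length(intensities) == 0L) {
    intensities <- matrix(numeric(0), nrow = nrow(features),
                          ncol = nrow(injections))
  }
  storage.mode(intensities) <- "double"
  if (!is.null(colnames(intensities)) && ncol(intensities) > 0L) {
    idx <- match(injections$injection_id, colnames(intensities))
    if (anyNA(idx)) {
      stop("intensity matrix is missing columns for injections: ",
           paste(injections$injection_id[is.na(idx)], collapse = ", "))
    }
    intensities <- intensities[, idx, drop = FALSE]
  }
  ord <- order(injections$run_index)
  injections <- injections[ord, , drop = FALSE]
  intensities <- intensities[, ord, drop = FALSE]
  rownames(features) <- NULL
  rownames(injections) <- NULL
  dimnames(intensities) <- list(features$feature_id, injections$injection_id)

  x <- structure(list(features = features, injections = injections,
                      intensities = intensities),
                 class = "feature_table")
  validate_feature_table(x)
  x
}

validate_feature_table <- function(x) {
  f <- x$features
  j <- x$injections
  m <- x$intensities
  need_f <- c("feature_id", "mz", "rt", "assay_mode")
  if (!all(need_f %in% names(f))) {
    stop("features must carry columns: ", paste(need_f, collapse = ", "))
  }
  need_j <- c("injection_id", "run_index", "plate_id", "role")
  if (!all(need_j %in% names(j))) {
    stop("injections must carry columns: ", paste(need_j, collapse = ", "))
  }
  if (nrow(m) != nrow(f) || ncol(m) != nrow(j)) {
    stop("intensity matrix dimensions do not match metadata")
  }
  if (anyDuplicated(f$feature_id)) {
    stop("duplicate feature_id: ",
         paste(unique(f$feature_id[duplicated(f$feature_id)]), collapse = ", "))
  }
  if (nrow(f) > 0L) {
    if (any(!is.finite(f$mz)) || any(f$mz <= 0)) stop("mz must be > 0")
    if (any(!is.finite(f$rt)) || any(f$rt < 0)) stop("rt must be >= 0")
    bad <- setdiff(unique(f$assay_mode), ASSAY_MODES)
    if (length(bad)) stop("unknown assay_mode: ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(j$injection_id)) {
    stop("duplicate injection_id: ",
         paste(unique(j$injection_id[duplicated(j$injection_id)]),
               collapse = ", "))
  }
  if (anyDuplicated(j$run_index)) {
    stop("duplicate run_index: ",
         paste(unique(j$run_index[duplicated(j$run_index)]), collapse = ", "))
  }
  if (nrow(j) > 0L) {
    if (any(j$run_index < 0L)) stop("run_index must be nonnegative")
    bad <- setdiff(unique(j$role), INJECTION_ROLES)
    if (length(bad)) stop("unknown injection role: ",
                          paste(bad, collapse = ", "))
    qc <- j$role %in% c("SQC", "dQC")
    if (any(qc & is.na(j$dilution_fold))) {
      stop("SQC/dQC injections must carry a dilution_fold")
    }
    if (any(!qc & !is.na(j$dilution_fold))) {
      stop("dilution_fold is only defined for SQC/dQC injections")
    }
    if (any(!j$dilution_fold[qc] %in% DILUTION_FOLDS)) {
      stop("dilution_fold must be one of ",
           paste(DILUTION_FOLDS, collapse = "/"))
    }
    if (any(j$dilution_fold[j$role == "SQC"] != 1L)) {
      stop("an SQC injection is dilution fold 1 by definition")
    }
  }
  if (any(m[is.finite(m)] < 0)) stop("present intensities must be >= 0")
  invisible(x)
}

#' @export
print.feature_table <- function(x, ...) {
  j <- x$injections
  cat(sprintf("feature_table: %d features x %d injections\n",
              nrow(x$features), nrow(j)))
  if (nrow(j)) {
    tab <- table(j$role)
    cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
    cat("  plates:", paste(unique(j$plate_id), collapse = ", "), "\n")
  }
  miss <- sum(is.na(x$intensities))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", miss,
              100 * miss / max(1L, length(x$intensities))))
  invisible(x)
}

n_features <- function(table) nrow(table$features)
n_injections <- function(table) nrow(table$injections)

injection_column <- function(table, injection) {
  jidx <- match(injection, table$injections$injection_id)
  if (is.na(jidx)) stop("unknown injection: ", injection)
  jidx
}

# Keep a subset of features (by id), preserving order of `ids`.
subset_features <- function(table, ids) {
  idx <- match(ids, table$features$feature_id)
  if (anyNA(idx)) stop("unknown feature_id: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  feature_table(table$features[idx, , drop = FALSE], table$injections,
                table$intensities[idx, , drop = FALSE])
}

# Keep a subset of injections (by id).
subset_injections <- function(table, ids) {
  idx <- match(ids, table$injections$injection_id)
  if (anyNA(idx)) stop("unknown injection_id: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  feature_table(table$features, table$injections[idx, , drop = FALSE],
                table$intensities[, idx, drop = FALSE])
}

FEATURE_META_COLS <- c("feature_id", "mz", "rt", "assay_mode", "annotation")
MANIFEST_COLS <- c("injection_id", "run_index", "plate_id", "role",
                   "sample_id", "dilution_fold")

#' Read a feature table and its injection manifest from CSV
#'
#' The table dialect is comma-separated UTF-8: first column `feature_id`,
#' metadata columns `mz`, `rt`, `assay_mode` (and optionally `annotation`),
#' then one intensity column per injection. The manifest is a separate CSV
#' keyed by `injection_id` that must cover every intensity column; a
#' repeated `run_index` is a hard error. Empty cells, the sentinel "NA" and
#' unparseable or negative values become the missing marker, the latter two
#' with a warning giving the count.
#'
#' @param path path to the feature-table CSV.
#' @param manifest_path path to the injection-manifest CSV.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, manifest_path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(manifest_path)) stop("no such file: ", manifest_path)
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character", stringsAsFactors = FALSE)
  if (!"feature_id" %in% names(raw)) stop("table lacks a feature_id column")
  man <- utils::read.csv(manifest_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!all(c("injection_id", "run_index", "plate_id", "role") %in% names(man))) {
    stop("manifest lacks required columns")
  }
  inj_cols <- setdiff(names(raw), FEATURE_META_COLS)
  missing_man <- setdiff(inj_cols, man$injection_id)
  if (length(missing_man)) {
    stop("manifest has no entry for intensity column(s): ",
         paste(missing_man, collapse = ", "))
  }
  man <- man[match(inj_cols, man$injection_id), , drop = FALSE]
  if (anyDuplicated(man$run_index)) {
    stop("duplicate run_index in manifest: ",
         paste(unique(man$run_index[duplicated(man$run_index)]),
               collapse = ", "))
  }
  if (!"sample_id" %in% names(man)) man$sample_id <- NA_character_
  if (!"dilution_fold" %in% names(man)) man$dilution_fold <- NA_integer_

  features <- data.frame(
    feature_id = raw$feature_id,
    mz = as.numeric(raw$mz),
    rt = as.numeric(raw$rt),
    assay_mode = raw$assay_mode,
    annotation = if ("annotation" %in% names(raw)) raw$annotation
                 else NA_character_,
    stringsAsFactors = FALSE
  )
  n_bad <- 0L
  m <- matrix(NA_real_, nrow = nrow(raw), ncol = length(inj_cols),
              dimnames = list(raw$feature_id, inj_cols))
  for (cn in inj_cols) {
    v <- raw[[cn]]
    num <- suppressWarnings(as.numeric(v))
    unparseable <- !is.na(v) & v != "" & is.na(num)
    negative <- !is.na(num) & num < 0
    n_bad <- n_bad + sum(unparseable) + sum(negative)
    num[negative] <- NA_real_
    m[, cn] <- num
  }
  if (n_bad > 0L) {
    warning(sprintf("%d unparseable or negative cell(s) set to missing",
                    n_bad))
  }
  feature_table(features, man, m)
}

default_manifest_path <- function(path) {
  sub("\\.csv$", "", path) |> paste0(".manifest.csv")
}

#' Write a feature table (and its manifest) to CSV
#'
#' Inverse of [read_feature_table()]: numeric values are serialized with 17
#' significant digits so that a read/write round trip is bit-exact for
#' finite values and preserves the missingness pattern.
#'
#' @param table a [feature_table()].
#' @param path output path for the feature-table CSV.
#' @param manifest_path output path for the manifest CSV; defaults to
#'   `<path minus .csv>.manifest.csv`.
#' @return Invisibly, the two paths written.
#' @export
write_feature_table <- function(table, path,
                                manifest_path = default_manifest_path(path)) {
  validate_feature_table(table)
  fmt <- function(v) ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  f <- table$features
  out <- data.frame(feature_id = f$feature_id, mz = fmt(f$mz), rt = fmt(f$rt),
                    assay_mode = f$assay_mode, annotation = f$annotation,
                    stringsAsFactors = FALSE, check.names = FALSE)
  m <- table$intensities
  for (k in seq_len(ncol(m))) out[[colnames(m)[k]]] <- fmt(m[, k])
  utils::write.csv(out, path, row.names = FALSE, na = "NA")
  utils::write.csv(table$injections[, MANIFEST_COLS], manifest_path,
                   row.names = FALSE, na = "NA")
  invisible(c(table = path, manifest = manifest_path))
}

#' Merge per-plate feature tables into one analytical sequence
#'
#' All tables must describe the identical ordered feature list; injections
#' must be disjoint and their run indices globally consistent (a single
#' total order across plates). The result concatenates the injections and
#' re-sorts them by run index.
#'
#' @param tables list of [feature_table()] objects.
#' @return A single merged [feature_table()].
#' @export
merge_plates <- function(tables) {
  if (!length(tables)) stop("no tables to merge")
  ref <- tables[[1L]]$features$feature_id
  for (k in seq_along(tables)[-1L]) {
    ids <- tables[[k]]$features$feature_id
    if (!identical(ids, ref)) {
      extra <- setdiff(ids, ref)
      lost <- setdiff(ref, ids)
      stop("feature lists differ between plates; only in table ", k, ": [",
           paste(extra, collapse = ", "), "]; missing from table ", k, ": [",
           paste(lost, collapse = ", "), "]")
    }
  }
  inj <- do.call(rbind, lapply(tables, `[[`, "injections"))
  m <- do.call(cbind, lapply(tables, `[[`, "intensities"))
  feature_table(tables[[1L]]$features, inj, m)
}

# Run `code` under `seed` without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
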