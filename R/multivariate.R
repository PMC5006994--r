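# Multivariate marker discovery: PCA for visualizing run structure,
# two-class OPLS-DA with the orthogonal-projection algorithm, S-plot
# covariance/correlation loadings with the |p(corr)| > 0.7 selection rule,
# and t-test / fold-change ranking of candidates. Matrices are samples x
# features throughout.

#' Impute missing values by half the feature minimum
#'
#' The conventional metabolomics stand-in for below-detection-limit cells:
#' each feature's missing entries are replaced by half its minimum observed
#' intensity (0 when a feature is entirely missing).
#'
#' @param matrix numeric matrix, samples x features.
#' @return The imputed matrix.
#' @export
impute_halfmin <- function(matrix) {
  for (j in seq_len(ncol(matrix))) {
    v <- matrix[, j]
    if (anyNA(v)) {
      fin <- v[is.finite(v)]
      matrix[!is.finite(v), j] <- if (length(fin)) min(fin) / 2 else 0
    }
  }
  matrix
}

# Center and scale samples-x-features data. Pareto scaling (divide by the
# square root of the standard deviation) is the default convention for
# MS metabolomics; constant features cannot be scaled and are dropped.
scale_features <- function(matrix, scaling = c("pareto", "unit_variance",
                                               "center_only")) {
  scaling <- match.arg(scaling)
  if (is.null(colnames(matrix))) {
    colnames(matrix) <- paste0("V", seq_len(ncol(matrix)))
  }
  ctr <- colMeans(matrix)
  sds <- apply(matrix, 2L, stats::sd)
  kept <- rep(TRUE, ncol(matrix))
  if (scaling != "center_only") {
    kept <- sds > 0
    if (any(!kept)) {
      warning(sprintf("%d constant feature(s) dropped before %s scaling",
                      sum(!kept), scaling))
    }
  }
  scl <- switch(scaling,
    center_only = rep(1, ncol(matrix)),
    unit_variance = sds,
    pareto = sqrt(sds))
  X <- sweep(matrix[, kept, drop = FALSE], 2L, ctr[kept], "-")
  X <- sweep(X, 2L, scl[kept], "/")
  list(X = X, center = ctr[kept], scale = scl[kept],
       features = colnames(matrix)[kept], scaling = scaling)
}

apply_scaling <- function(matrix, sc) {
  if (is.null(colnames(matrix))) {
    colnames(matrix) <- paste0("V", seq_len(ncol(matrix)))
  }
  X <- matrix[, sc$features, drop = FALSE]
  X <- sweep(X, 2L, sc$center, "-")
  sweep(X, 2L, sc$scale, "/")
}

latent_model <- function(method, scores, loadings, component_kinds,
                         explained_variation, sc, extra = list()) {
  structure(c(list(method = method, scores = scores, loadings = loadings,
                   component_kinds = component_kinds,
                   explained_variation = explained_variation,
                   center = sc$center, scale = sc$scale,
                   features = sc$features, scaling = sc$scaling), extra),
            class = "latent_model")
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("latent_model (%s): %d sample(s), %d feature(s), components: %s\n",
              x$method, nrow(x$scores), length(x$features),
              paste(x$component_kinds, collapse = ", ")))
  cat("  explained variation:",
      paste(sprintf("%.3f", x$explained_variation), collapse = ", "), "\n")
  invisible(x)
}

#' Principal component analysis of a sample-by-feature matrix
#'
#' Centering/scaling per `scaling` (Pareto by default), then singular value
#' decomposition via [stats::prcomp()]. Loadings are orthonormal and the
#' explained variation is non-increasing.
#'
#' @param matrix numeric matrix, samples x features, no missing values
#'   (impute upstream, e.g. [impute_halfmin()]).
#' @param n_components number of components to keep.
#' @param scaling `"pareto"`, `"unit_variance"` or `"center_only"`.
#' @return A `latent_model` with scores, loadings and per-component
#'   explained variation (fractions of total variance).
#' @export
pca <- function(matrix, n_components = 2L,
                scaling = c("pareto", "unit_variance", "center_only")) {
  sc <- scale_features(matrix, scaling)
  n_components <- min(n_components, dim(sc$X))
  pr <- stats::prcomp(sc$X, center = FALSE, scale. = FALSE)
  keep <- seq_len(n_components)
  ev <- pr$sdev^2 / sum(pr$sdev^2)
  latent_model("pca", pr$x[, keep, drop = FALSE],
               pr$rotation[, keep, drop = FALSE],
               rep("principal", n_components), ev[keep], sc)
}

#' Two-class OPLS-DA
#'
#' Orthogonal projections to latent structures discriminant analysis: the
#' class-predictive variation is concentrated in a single predictive
#' component after `n_orthogonal` components of y-orthogonal variation are
#' deflated from the data. With `n_orthogonal = 0` the model reduces
#' exactly to single-component PLS (PLS1).
#'
#' @param matrix numeric matrix, samples x features, no missing values.
#' @param labels two-class factor (or coercible), one entry per sample,
#'   each class with at least two samples.
#' @param n_orthogonal number of orthogonal components (default 1).
#' @param scaling `"pareto"`, `"unit_variance"` or `"center_only"`.
#' @return A `latent_model` whose first component is predictive and the
#'   rest orthogonal; `explained_variation` is the fraction of (scaled) X
#'   variance each component removes.
#' @export
opls_da <- function(matrix, labels, n_orthogonal = 1L,
                    scaling = c("pareto", "unit_variance", "center_only")) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) {
    stop("OPLS-DA requires exactly two classes, got ", nlevels(labels))
  }
  if (any(table(labels) < 2L)) stop("both classes need at least 2 samples")
  sc <- scale_features(matrix, scaling)
  X <- sc$X
  y <- ifelse(labels == levels(labels)[2L], 1, -1)
  yc <- y - mean(y)
  ssx <- sum(X^2)

  T_orth <- NULL; P_orth <- NULL; W_orth <- NULL
  for (j in seq_len(n_orthogonal)) {
    w <- drop(crossprod(X, yc))
    w <- w / sqrt(sum(w^2))
    t <- drop(X %*% w)
    p <- drop(crossprod(X, t)) / sum(t^2)
    wo <- p - sum(w * p) * w
    if (sum(wo^2) < 1e-12 * sum(p^2)) break  # no orthogonal variation left
    wo <- wo / sqrt(sum(wo^2))
    to <- drop(X %*% wo)
    po <- drop(crossprod(X, to)) / sum(to^2)
    X <- X - tcrossprod(to, po)
    T_orth <- cbind(T_orth, to)
    P_orth <- cbind(P_orth, po)
    W_orth <- cbind(W_orth, wo)
  }
  w <- drop(crossprod(X, yc))
  w <- w / sqrt(sum(w^2))
  t_pred <- drop(X %*% w)
  p_pred <- drop(crossprod(X, t_pred)) / sum(t_pred^2)

  scores <- cbind(predictive = t_pred, T_orth)
  loadings <- cbind(predictive = p_pred, P_orth)
  k_orth <- ncol(scores) - 1L
  if (k_orth > 0L) {
    colnames(scores)[-1L] <- paste0("orthogonal", seq_len(k_orth))
    colnames(loadings)[-1L] <- paste0("orthogonal", seq_len(k_orth))
  }
  rownames(loadings) <- sc$features
  kinds <- c("predictive", rep("orthogonal", k_orth))
  ev <- colSums(scores^2) * colSums(loadings^2) / ssx
  latent_model("opls-da", scores, loadings, kinds, unname(ev), sc,
               extra = list(weights = w, labels = labels,
                            deflated = X, y = y))
}

#' S-plot points from an OPLS-DA model
#'
#' For every feature, the covariance (`p1`) and Pearson correlation
#' (`pcorr1`) between the scaled, centered feature vector and the
#' predictive score. High |pcorr1| with high |p1| marks reliable,
#' high-magnitude discriminators; `|pcorr1| <= 1` always. Features with
#' zero variance are excluded with a warning.
#'
#' @param model an [opls_da()] model.
#' @param matrix the samples x features matrix the model was built from.
#' @return data.frame of class `s_plot_points`: `feature_id`, `p1`,
#'   `pcorr1`.
#' @export
s_plot <- function(model, matrix) {
  if (!"predictive" %in% model$component_kinds) {
    stop("model has no predictive component")
  }
  X <- apply_scaling(matrix, model)
  t <- model$scores[, which(model$component_kinds == "predictive")[1L]]
  n <- length(t)
  tc <- t - mean(t)
  Xc <- sweep(X, 2L, colMeans(X), "-")
  p1 <- drop(crossprod(Xc, tc)) / (n - 1)
  sdx <- apply(X, 2L, stats::sd)
  ok <- sdx > 0
  if (any(!ok)) {
    warning(sprintf("%d zero-variance feature(s) excluded from the S-plot",
                    sum(!ok)))
  }
  pcorr1 <- p1[ok] / (sdx[ok] * stats::sd(t))
  out <- data.frame(feature_id = colnames(X)[ok], p1 = p1[ok],
                    pcorr1 = pcorr1, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("s_plot_points", "data.frame")
  out
}

#' Select features by the S-plot correlation threshold
#'
#' Keeps features whose `pcorr1` is strictly greater than `threshold` or
#' strictly less than `-threshold` (default 0.7, the marker-selection
#' rule; 0.55 is the relaxed variant used for weaker contrasts).
#'
#' @param points an [s_plot()] data.frame.
#' @param threshold absolute p(corr) cut in (0, 1).
#' @return Character vector of selected `feature_id`s.
#' @export
select_by_pcorr <- function(points, threshold = 0.7) {
  stopifnot(threshold > 0, threshold < 1)
  points$feature_id[abs(points$pcorr1) > threshold]
}

#' Rank candidate markers by t-test p-value and fold change
#'
#' Two-sample t-test per feature between the two label classes (Welch by
#' default; set `var_equal = TRUE` for the classical pooled-variance
#' Student test), with candidates ordered lexicographically by ascending
#' p-value and then descending |log fold change|. The fold change is the
#' ratio of the second class's mean to the first's, and its side of 1
#' gives the direction. Features with zero variance in both groups are
#' skipped.
#'
#' @param matrix numeric matrix, samples x features.
#' @param labels two-class factor; the first level is the reference
#'   (control) group.
#' @param top_n number of candidates to return (default 40).
#' @param var_equal pooled-variance Student t-test instead of Welch?
#' @param points optional [s_plot()] data.frame; when given, each
#'   candidate's `pcorr1` is joined in.
#' @return data.frame of class `marker_candidates`: `feature_id`,
#'   `p_value`, `fold_change`, `direction`, `pcorr1`.
#' @export
rank_candidates <- function(matrix, labels, top_n = 40L, var_equal = FALSE,
                            points = NULL) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two classes")
  g1 <- labels == levels(labels)[1L]
  g2 <- labels == levels(labels)[2L]
  if (!any(g1) || !any(g2)) stop("both groups must be non-empty")
  if (is.null(colnames(matrix))) {
    colnames(matrix) <- paste0("V", seq_len(ncol(matrix)))
  }
  rows <- lapply(seq_len(ncol(matrix)), function(j) {
    x1 <- matrix[g1, j]; x1 <- x1[is.finite(x1)]
    x2 <- matrix[g2, j]; x2 <- x2[is.finite(x2)]
    if (length(x1) < 2L || length(x2) < 2L) return(NULL)
    if (stats::sd(x1) == 0 && stats::sd(x2) == 0) return(NULL)
    p <- tryCatch(
      stats::t.test(x1, x2, var.equal = var_equal)$p.value,
      error = function(e) NA_real_)
    if (!is.finite(p)) return(NULL)
    m1 <- mean(x1); m2 <- mean(x2)
    if (m1 <= 0 || m2 <= 0) return(NULL)  # fold change undefined
    data.frame(feature_id = colnames(matrix)[j], p_value = p,
               fold_change = m2 / m1,
               direction = if (m2 > m1) "increasing" else "decreasing",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable feature")
  out <- out[order(out$p_value, -abs(log(out$fold_change))), , drop = FALSE]
  out <- utils::head(out, top_n)
  out$pcorr1 <- if (!is.null(points)) {
    points$pcorr1[match(out$feature_id, points$feature_id)]
  } else NA_real_
  rownames(out) <- NULL
  class(out) <- c("marker_candidates", "data.frame")
  out
}
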