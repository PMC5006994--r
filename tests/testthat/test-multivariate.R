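# Shared synthetic two-class data: `n_true` discriminative features with a
# mean shift of `effect` standard deviations among nulls.
two_class_data <- function(n_per_class = 10, n_feat = 100, n_true = 10,
                           effect = 2, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(rnorm(n * n_feat), n, n_feat,
              dimnames = list(NULL, sprintf("V%03d", seq_len(n_feat))))
  labels <- factor(rep(c("a", "b"), each = n_per_class))
  X[labels == "b", seq_len(n_true)] <-
    X[labels == "b", seq_len(n_true)] + effect
  list(X = X, labels = labels, true = sprintf("V%03d", seq_len(n_true)))
}

test_that("half-minimum imputation fills missing cells", {
  m <- cbind(c(1, NA, 3), c(NA, NA, NA))
  out <- impute_halfmin(m)
  expect_equal(out[, 1], c(1, 0.5, 3))
  expect_equal(out[, 2], rep(0, 3))
})

test_that("PCA concentrates a rank-1 signal on the first component", {
  set.seed(11)
  t_true <- rnorm(30)
  X <- outer(t_true, rnorm(50)) + matrix(rnorm(30 * 50, 0, 0.01), 30, 50)
  model <- pca(X, n_components = 3, scaling = "center_only")
  expect_gt(model$explained_variation[1], 0.99)
  expect_true(all(diff(model$explained_variation) <= 0))
  # orthonormal loadings
  expect_equal(crossprod(model$loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  # duplicated samples land on the same score
  X2 <- rbind(X, X[1, ])
  s <- pca(X2, 2, scaling = "center_only")$scores
  expect_equal(s[31, ], s[1, ], tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("constant features are dropped with a warning under scaling", {
  X <- cbind(a = rnorm(10), b = rep(3, 10), c = rnorm(10))
  expect_warning(model <- pca(X, 2, scaling = "unit_variance"),
                 "constant feature")
  expect_setequal(model$features, c("a", "c"))
})

test_that("OPLS-DA separates classes and flags its components", {
  d <- two_class_data(effect = 3, seed = 21)
  model <- opls_da(d$X, d$labels, n_orthogonal = 1)
  expect_identical(model$component_kinds[1], "predictive")
  t_pred <- model$scores[, 1]
  expect_gt(abs(cor(t_pred, as.numeric(d$labels))), 0.9)
  expect_error(opls_da(d$X, factor(rep("a", 20))), "two classes")
})

test_that("with no orthogonal component OPLS-DA reduces to PLS1", {
  d <- two_class_data(seed = 31)
  mine <- opls_da(d$X, d$labels, n_orthogonal = 0,
                  scaling = "unit_variance")
  ref <- mixOmics::pls(d$X, as.numeric(d$labels), ncomp = 1,
                       scale = TRUE, mode = "regression")
  expect_gt(abs(cor(mine$scores[, 1], ref$variates$X[, 1])), 1 - 1e-8)
})

test_that("orthogonal removal never hurts training separation", {
  d <- two_class_data(effect = 1, seed = 41)
  sep <- function(t, y) {
    abs(mean(t[y == "b"]) - mean(t[y == "a"])) / sd(t)
  }
  pls1 <- opls_da(d$X, d$labels, n_orthogonal = 0)
  opls <- opls_da(d$X, d$labels, n_orthogonal = 1)
  expect_gte(sep(opls$scores[, 1], d$labels) + 1e-8,
             sep(pls1$scores[, 1], d$labels))
})

test_that("permuted labels separate no better than chance", {
  set.seed(51)
  X <- matrix(rnorm(12 * 80), 12, 80)
  labels <- factor(rep(c("a", "b"), each = 6))
  sep <- function(lab) {
    t <- opls_da(X, lab, n_orthogonal = 0)$scores[, 1]
    abs(mean(t[lab == "b"]) - mean(t[lab == "a"]))
  }
  obs <- sep(labels)
  perm <- replicate(100, sep(sample(labels)))
  expect_gt(mean(perm >= obs), 0.05)  # not beyond the permutation null
})

test_that("S-plot correlations are bounded and identify constructions", {
  d <- two_class_data(effect = 2, seed = 61)
  model <- opls_da(d$X, d$labels, n_orthogonal = 0,
                   scaling = "center_only")
  X2 <- cbind(d$X, spy = model$scores[, 1])
  model2 <- opls_da(X2, d$labels, n_orthogonal = 0,
                    scaling = "center_only")
  pts <- s_plot(model2, X2)
  expect_true(all(abs(pts$pcorr1) <= 1 + 1e-12))
  # a feature equal to the predictive score correlates perfectly
  expect_gt(pts$pcorr1[pts$feature_id == "spy"], 0.999)
  # engineered discriminators occupy the S-plot extremes
  ord <- pts$feature_id[order(-abs(pts$pcorr1))]
  expect_gt(length(intersect(ord[1:11], c(d$true, "spy"))), 9)
})

test_that("pure-noise features rarely reach high |pcorr|", {
  set.seed(71)
  X <- matrix(rnorm(60 * 200), 60, 200)
  labels <- factor(rep(c("a", "b"), each = 30))
  model <- opls_da(X, labels, n_orthogonal = 0)
  pts <- s_plot(model, X)
  expect_lt(mean(abs(pts$pcorr1) > 0.5), 0.01)
})

test_that("the p(corr) selection band is strict at the threshold", {
  pts <- data.frame(feature_id = c("a", "b", "c", "d", "e"),
                    p1 = 1, pcorr1 = c(0.71, 0.7, -0.69, -0.71, 0.0))
  expect_setequal(select_by_pcorr(pts, 0.7), c("a", "d"))
  expect_setequal(select_by_pcorr(pts, 0.55), c("a", "b", "c", "d"))
})

test_that("scaling invariance: per-feature affine rescaling keeps pcorr", {
  # autoscaling (unit variance) makes the scaled matrix, hence pcorr,
  # invariant to per-feature affine transforms with positive slope
  d <- two_class_data(seed = 81)
  model <- opls_da(d$X, d$labels, n_orthogonal = 0,
                   scaling = "unit_variance")
  pts <- s_plot(model, d$X)
  set.seed(82)
  Xr <- sweep(d$X, 2, runif(ncol(d$X), 0.5, 5), "*")
  Xr <- sweep(Xr, 2, rnorm(ncol(d$X)), "+")
  model_r <- opls_da(Xr, d$labels, n_orthogonal = 0,
                     scaling = "unit_variance")
  pts_r <- s_plot(model_r, Xr)
  expect_equal(pts$pcorr1, pts_r$pcorr1, tolerance = 1e-8)
  expect_setequal(select_by_pcorr(pts, 0.7), select_by_pcorr(pts_r, 0.7))
})

test_that("candidates rank by p-value then |log fold change|", {
  set.seed(91)
  n <- 12
  X <- matrix(rlnorm(n * 30, meanlog = 3, sdlog = 0.2), n, 30,
              dimnames = list(NULL, sprintf("V%02d", 1:30)))
  labels <- factor(rep(c("ctrl", "stored"), each = 6))
  X[labels == "stored", 1] <- X[labels == "stored", 1] * 10  # 10x shift
  X[, 2] <- rep(c(20, 20.0001), n / 2)                        # ~equal means
  out <- rank_candidates(X, labels, top_n = 30)
  expect_identical(out$feature_id[1], "V01")
  expect_identical(out$direction[1], "increasing")
  expect_gt(out$fold_change[1], 5)
  expect_identical(out$feature_id[nrow(out)], "V02")
  # a pooled-variance Student option exists and agrees on the top hit
  out_student <- rank_candidates(X, labels, top_n = 5, var_equal = TRUE)
  expect_identical(out_student$feature_id[1], "V01")
})
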