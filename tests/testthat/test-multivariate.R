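test_that("scaling centers, unit-scales and inverts exactly", {
  set.seed(1)
  x <- matrix(rnorm(40, 5, 2), 8, 5)
  rec <- scale_matrix(x)
  expect_equal(unname(colMeans(rec$x)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(rec$x, 2, var)), rep(1, 5), tolerance = 1e-12)
  expect_equal(unscale_matrix(rec), x, tolerance = 1e-10)
  # mode none with centering off is the identity
  plain <- scale_matrix(x, mode = "none", center = FALSE)
  expect_equal(plain$x, x)
  # zero-variance features are named
  xz <- x; xz[, 2] <- 3; colnames(xz) <- paste0("f", 1:5)
  expect_error(scale_matrix(xz), "f2")
})

test_that("NIPALS PCA agrees with a dense spectral-decomposition oracle", {
  set.seed(20)
  for (dims in list(c(6, 5), c(12, 9), c(20, 20))) {
    x <- scale_matrix(matrix(rnorm(prod(dims)), dims[1], dims[2]))$x
    a <- min(4L, dims[1] - 1L, dims[2])
    pca <- fit_pca(x, a)
    sv <- svd(x)
    for (k in seq_len(a)) {
      # agreement up to component sign
      s <- sign(sum(pca$loadings[, k] * sv$v[, k]))
      expect_equal(pca$loadings[, k], s * sv$v[, k], tolerance = 1e-8,
                   ignore_attr = TRUE)
      expect_equal(pca$scores[, k], s * sv$u[, k] * sv$d[k], tolerance = 1e-7,
                   ignore_attr = TRUE)
    }
    # R2X matches cumulative eigenvalue fractions
    expect_equal(pca$r2x_cum, cumsum(sv$d[1:a]^2) / sum(sv$d^2),
                 tolerance = 1e-8)
    # score orthogonality
    g <- crossprod(pca$scores)
    expect_lt(max(abs(g[upper.tri(g)])), 1e-6)
  }
})

test_that("a rank-one matrix is fully explained by one component", {
  t0 <- rnorm(10)
  p0 <- rnorm(6)
  x <- tcrossprod(t0, p0)
  pca <- fit_pca(x, 1)
  expect_equal(pca$r2x_cum[1], 1, tolerance = 1e-10)
})

test_that("PCA cross-validation separates structure from noise", {
  set.seed(31)
  noise <- scale_matrix(matrix(rnorm(30 * 40), 30, 40))$x
  expect_lte(q2_crossval(noise, n_components = 2, folds = 7, seed = 1), 0)
  structured <- tcrossprod(matrix(rnorm(60), 30, 2), matrix(rnorm(80), 40, 2)) +
    matrix(rnorm(30 * 40, 0, 0.05), 30, 40)
  expect_gt(q2_crossval(scale_matrix(structured)$x, n_components = 2,
                        folds = 7, seed = 1), 0.5)
  # leave-one-out runs and returns a finite value
  small <- scale_matrix(matrix(rnorm(8 * 5), 8, 5))$x
  q2_loo <- q2_crossval(small, n_components = 2, folds = 8, seed = 1)
  expect_true(is.finite(q2_loo))
})

test_that("OPLS-DA explains a class-aligned direction completely", {
  y <- rep(c("case", "control"), each = 6)
  t0 <- ifelse(y == "case", 1, -1) + 0 # scores proportional to class
  p0 <- c(2, -1, 0.5, 1, -2)
  x <- tcrossprod(t0, p0)
  fit <- fit_oplsda(x, y, n_orthogonal = 0, folds = 4, seed = 1)
  expect_equal(fit$metrics$r2y_cum, 1, tolerance = 1e-10)
  dir <- p0 / sqrt(sum(p0^2))
  got <- fit$loadings[, 1] / sqrt(sum(fit$loadings[, 1]^2))
  s <- sign(sum(got * dir))
  expect_equal(unname(got), s * dir, tolerance = 1e-8)
})

test_that("with no orthogonal components OPLS-DA reduces to single-component PLS", {
  set.seed(14)
  x <- scale_matrix(matrix(rnorm(16 * 7), 16, 7))$x
  y <- rep(c("case", "control"), each = 8)
  fit <- fit_oplsda(x, y, n_orthogonal = 0, folds = 4, seed = 1)
  # independent PLS oracle: w = X'y / ||X'y||, t = Xw, c = y't / t't
  yc <- ifelse(y == "case", 1, 0); yc <- yc - mean(yc)
  w <- drop(crossprod(x, yc)); w <- w / sqrt(sum(w^2))
  t_or <- drop(x %*% w)
  c_or <- sum(yc * t_or) / sum(t_or^2)
  s <- sign(sum(fit$scores[, 1] * t_or))
  expect_equal(unname(fit$scores[, 1]), s * t_or, tolerance = 1e-8)
  expect_equal(fit$metrics$r2y_cum,
               1 - sum((yc - t_or * c_or)^2) / sum(yc^2), tolerance = 1e-10)
})

test_that("single-component PLS matches the mixOmics implementation", {
  set.seed(77)
  x <- matrix(rnorm(20 * 6), 20, 6)
  y <- rep(c(1, 0), each = 10)
  fit <- fit_oplsda(scale_matrix(x)$x, factor(ifelse(y == 1, "case", "control")),
                    n_orthogonal = 0, folds = 4, seed = 1)
  ref <- mixOmics::pls(x, y, ncomp = 1, mode = "regression", scale = TRUE)
  t_ref <- ref$variates$X[, 1]
  s <- sign(sum(fit$scores[, 1] * t_ref))
  expect_gt(abs(cor(fit$scores[, 1], s * t_ref)), 1 - 1e-8)
})

test_that("orthogonal components are orthogonal to the predictive score", {
  set.seed(55)
  x <- scale_matrix(matrix(rnorm(24 * 10), 24, 10))$x
  y <- rep(c("case", "control"), each = 12)
  fit <- fit_oplsda(x, y, n_orthogonal = 2, folds = 4, seed = 1)
  for (k in seq_len(ncol(fit$scores_ortho))) {
    expect_lt(abs(sum(fit$scores[, 1] * fit$scores_ortho[, k])), 1e-8)
  }
  expect_lte(fit$metrics$r2x_cum, 1 + 1e-12)
  # requesting more orthogonal components than the residual rank fails
  expect_error(fit_oplsda(x, y, n_orthogonal = 50L), "rank")
})

test_that("cross-validated Q2 never beats the training fit and is deterministic", {
  set.seed(60)
  for (rep in 1:3) {
    co <- generate_cohort(small_design(seed = 100L + rep))
    pre <- suppressMessages(preprocess_table(co$table))
    xs <- scale_matrix(t(pre$intensity))$x
    fit <- fit_oplsda(xs, pre$samples$class, n_orthogonal = 0, folds = 7,
                      seed = 3)
    expect_lte(fit$metrics$q2_cum, fit$metrics$r2y_cum + 1e-10)
    again <- q2_crossval(xs, pre$samples$class, n_orthogonal = 0, folds = 7,
                         seed = 3)
    expect_identical(fit$metrics$q2_cum, again)
  }
})

test_that("label permutation destroys the cross-validated fit", {
  co <- generate_cohort(small_design(seed = 9L))
  pre <- suppressMessages(preprocess_table(co$table))
  planted <- !co$truth$is_noise[match(pre$features$feature_id,
                                      co$truth$feature_id)]
  xs <- scale_matrix(t(pre$intensity[planted, ]))$x
  true_q2 <- q2_crossval(xs, pre$samples$class, n_orthogonal = 0, folds = 7,
                         seed = 2)
  perm <- permutation_q2(xs, pre$samples$class, n_orthogonal = 0, folds = 7,
                         seed = 2, n_perm = 5)
  expect_gt(true_q2, 0.8)
  expect_true(all(perm < true_q2))
})

test_that("feature ranking is discriminant-based with stable tie-breaks", {
  co <- generate_cohort(small_design(seed = 4L))
  pre <- suppressMessages(preprocess_table(co$table))
  xs <- scale_matrix(t(pre$intensity))$x
  fit <- fit_oplsda(xs, pre$samples$class, n_orthogonal = 0, folds = 7, seed = 1)
  rk <- rank_features(fit)
  truth <- co$truth[match(rk$feature_id, co$truth$feature_id), ]
  strong <- !truth$is_noise & abs(truth$fold_change) >= 4
  noise_ranks <- rk$rank[truth$is_noise]
  # every strong planted feature outranks the median noise feature
  expect_true(all(rk$rank[strong] < stats::median(noise_ranks)))
  # PCA models are rejected
  expect_error(rank_features(fit_pca(xs, 2)), "OPLS-DA")
  # deterministic tie-break by feature id on duplicated columns
  xdup <- xs[, c(1, 1, 2)]
  colnames(xdup) <- c("b_feat", "a_feat", "c_feat")
  fit2 <- fit_oplsda(xdup, pre$samples$class, n_orthogonal = 0, folds = 7,
                     seed = 1)
  rk2 <- rank_features(fit2)
  tied <- rk2$feature_id[rk2$feature_id %in% c("a_feat", "b_feat")]
  expect_identical(tied, sort(tied))
})

test_that("single-feature data ranks that feature first", {
  x <- matrix(c(rnorm(6, 2), rnorm(6, -2)), ncol = 1,
              dimnames = list(NULL, "only"))
  y <- rep(c("case", "control"), each = 6)
  fit <- fit_oplsda(scale_matrix(x)$x, y, n_orthogonal = 0, folds = 3, seed = 1)
  rk <- rank_features(fit)
  expect_identical(rk$feature_id[1], "only")
  expect_equal(nrow(rk), 1L)
})
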