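#' Center and scale a data matrix
#'
#' Unit-variance scaling with centering (the convention of the multivariate
#' stage): each column is centered and divided by its standard deviation.
#' The returned record allows exact back-transformation.
#'
#' @param x Numeric samples-by-features matrix with no missing values.
#' @param mode `"unit-variance"` (default) or `"none"` (no division).
#' @param center Center columns first (default `TRUE`).
#' @return List of class `scaling_record` with elements `x` (the scaled
#'   matrix), `center`, `scale`, `mode`.
#' @export
scale_matrix <- function(x, mode = c("unit-variance", "none"), center = TRUE) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (anyNA(x)) stop("matrix has missing values; preprocess first", call. = FALSE)
  ctr <- if (center) colMeans(x) else rep(0, ncol(x))
  xs <- sweep(x, 2, ctr, "-")
  if (mode == "unit-variance") {
    sds <- apply(x, 2, stats::sd)
    zero <- sds <= .Machine$double.eps * 10
    if (any(zero)) {
      ids <- colnames(x)[zero] %||% which(zero)
      stop("zero-variance feature(s) cannot be unit-variance scaled: ",
           paste(utils::head(ids, 5), collapse = ", "), call. = FALSE)
    }
    xs <- sweep(xs, 2, sds, "/")
  } else {
    sds <- rep(1, ncol(x))
  }
  structure(list(x = xs, center = ctr, scale = sds, mode = mode),
            class = "scaling_record")
}

#' Invert a scaling record
#'
#' @param record A [scale_matrix()] result.
#' @return The original matrix.
#' @export
unscale_matrix <- function(record) {
  stopifnot(inherits(record, "scaling_record"))
  sweep(sweep(record$x, 2, record$scale, "*"), 2, record$center, "+")
}

# Sign convention: make the largest-|.| element of the loading positive.
fix_sign <- function(loading) {
  if (loading[which.max(abs(loading))] < 0) -1 else 1
}

#' Principal components analysis by NIPALS
#'
#' Iterative extraction of orthogonal components maximizing explained
#' variance from a centered (and typically unit-variance scaled) matrix.
#' Cumulative R2X after `a` components is
#' `1 - ||X - T_a P_a'||^2 / ||X||^2`. Each loading vector is signed so its
#' largest-magnitude element is positive.
#'
#' @param x Scaled samples-by-features matrix (use [scale_matrix()]).
#' @param n_components Number of components (`<= min(nrow - 1, ncol)`).
#' @param tol Convergence tolerance on the squared relative score change
#'   between sweeps. The default is far below the target accuracy because the
#'   power-iteration contraction slows when eigenvalues are close: the
#'   successive change understates the remaining error by the spectral-gap
#'   factor.
#' @param max_iter Iteration cap per component; exceeded is an error.
#' @return Object of class `latent_model` with `kind = "pca"`, `scores`
#'   (samples x components), `loadings` (features x components), `r2x`
#'   (per component) and `r2x_cum`.
#' @export
fit_pca <- function(x, n_components = 2L, tol = 1e-20, max_iter = 50000L) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("matrix has missing values", call. = FALSE)
  a_max <- min(nrow(x) - 1L, ncol(x))
  if (n_components < 1L || n_components > a_max) {
    stop("n_components must be in [1, ", a_max, "]", call. = FALSE)
  }
  ss_total <- sum(x^2)
  if (ss_total == 0) stop("matrix is identically zero", call. = FALSE)
  scores <- matrix(0, nrow(x), n_components)
  loadings <- matrix(0, ncol(x), n_components)
  r2x_cum <- numeric(n_components)
  res <- x
  for (a in seq_len(n_components)) {
    t_vec <- res[, which.max(apply(res, 2, stats::var))]
    if (sum(t_vec^2) == 0) t_vec <- res[, which.max(colSums(res^2))]
    for (iter in seq_len(max_iter)) {
      p_vec <- crossprod(res, t_vec) / sum(t_vec^2)
      p_vec <- p_vec / sqrt(sum(p_vec^2))
      t_new <- res %*% p_vec
      delta <- sum((t_new - t_vec)^2) / max(sum(t_new^2), .Machine$double.eps)
      t_vec <- drop(t_new)
      if (delta < tol) break
      if (iter == max_iter) {
        stop("NIPALS failed to converge for component ", a, " after ",
             max_iter, " iterations (last relative change ",
             signif(delta, 3), ")", call. = FALSE)
      }
    }
    s <- fix_sign(p_vec)
    scores[, a] <- s * t_vec
    loadings[, a] <- s * p_vec
    res <- res - tcrossprod(scores[, a], loadings[, a])
    r2x_cum[a] <- 1 - sum(res^2) / ss_total
  }
  rownames(scores) <- rownames(x)
  rownames(loadings) <- colnames(x)
  colnames(scores) <- colnames(loadings) <- sprintf("PC%d", seq_len(n_components))
  structure(
    list(kind = "pca", scores = scores, loadings = loadings,
         r2x = diff(c(0, r2x_cum)), r2x_cum = r2x_cum,
         n_components = n_components),
    class = "latent_model"
  )
}

# Stratified venetian-blind fold assignment after a seeded shuffle.
assign_folds <- function(n, folds, seed, strata = NULL) {
  if (folds < 2L || folds > n) stop("folds must be in [2, n]", call. = FALSE)
  set.seed(seed)
  fold_of <- integer(n)
  if (is.null(strata)) strata <- rep(1L, n)
  for (g in unique(strata)) {
    idx <- sample(which(strata == g))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_of
}

# Core O-PLS fitter on a scaled matrix and centered response.
# Removes n_ortho y-orthogonal components, then one predictive component.
opls_core <- function(x, yc, n_ortho) {
  w_o <- list(); p_o <- list(); t_o <- list()
  res <- x
  for (k in seq_len(n_ortho)) {
    w <- drop(crossprod(res, yc)) / sum(yc^2)
    w <- w / sqrt(sum(w^2))
    t_vec <- drop(res %*% w)
    p_vec <- drop(crossprod(res, t_vec)) / sum(t_vec^2)
    wo <- p_vec - sum(w * p_vec) * w
    nrm <- sqrt(sum(wo^2))
    if (nrm < 1e-10) {
      stop("n_orthogonal = ", n_ortho, " exceeds the y-orthogonal rank ",
           "(no orthogonal variation left at component ", k, ")", call. = FALSE)
    }
    wo <- wo / nrm
    to <- drop(res %*% wo)
    po <- drop(crossprod(res, to)) / sum(to^2)
    res <- res - tcrossprod(to, po)
    w_o[[k]] <- wo; p_o[[k]] <- po; t_o[[k]] <- to
  }
  w <- drop(crossprod(res, yc)) / sum(yc^2)
  w <- w / sqrt(sum(w^2))
  t_vec <- drop(res %*% w)
  p_vec <- drop(crossprod(res, t_vec)) / sum(t_vec^2)
  s <- fix_sign(p_vec)
  w <- s * w; t_vec <- s * t_vec; p_vec <- s * p_vec
  c_coef <- sum(yc * t_vec) / sum(t_vec^2)
  list(w = w, t = t_vec, p = p_vec, c = c_coef,
       w_ortho = w_o, p_ortho = p_o, t_ortho = t_o)
}

# Predict centered response for new scaled rows.
opls_predict <- function(fit, newx) {
  newx <- as.matrix(newx)
  for (k in seq_along(fit$w_ortho)) {
    to <- drop(newx %*% fit$w_ortho[[k]])
    newx <- newx - tcrossprod(to, fit$p_ortho[[k]])
  }
  drop(newx %*% fit$w) * fit$c
}

encode_response <- function(y) {
  if (is.numeric(y)) {
    lv <- sort(unique(y))
    if (length(lv) != 2L) stop("response must have exactly two classes", call. = FALSE)
    y01 <- as.numeric(y == lv[2])
    labels <- as.character(lv)
  } else {
    y <- as.factor(y)
    if (nlevels(y) != 2L) stop("response must have exactly two classes", call. = FALSE)
    labels <- levels(y)
    # convention: "case" (or the first level alphabetically) codes as 1
    pos <- if ("case" %in% labels) "case" else labels[1]
    y01 <- as.numeric(y == pos)
    labels <- c(setdiff(labels, pos), pos)
  }
  if (min(table(y01)) < 2L) stop("each class needs at least 2 samples", call. = FALSE)
  list(y01 = y01, labels = labels)
}

#' Cross-validated Q2 of a latent model
#'
#' `Q2 = 1 - PRESS/SS` accumulated over held-out folds (stratified
#' venetian-blind assignment after a seeded shuffle). For OPLS-DA (`y`
#' given), PRESS is the squared error of the predicted class response. For
#' PCA (`y = NULL`), each held-out element is predicted from the sample's
#' other variables through the training loadings (row-wise scheme with
#' per-variable exclusion), so an uninformative matrix yields `Q2 <= 0`.
#'
#' @param x Scaled samples-by-features matrix.
#' @param y Two-class response for OPLS-DA, or `NULL` for PCA.
#' @param n_components PCA components (PCA mode).
#' @param n_orthogonal Orthogonal components (OPLS-DA mode).
#' @param folds Number of folds (default 7; `folds = nrow(x)` is
#'   leave-one-out).
#' @param seed Seed for the fold shuffle.
#' @return Cumulative Q2 (scalar).
#' @export
q2_crossval <- function(x, y = NULL, n_components = 2L, n_orthogonal = 0L,
                        folds = 7L, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(y)) {
    fold_of <- assign_folds(n, folds, seed)
    press <- 0
    ss <- sum(x^2)
    for (f in unique(fold_of)) {
      test <- fold_of == f
      pca <- fit_pca(x[!test, , drop = FALSE], n_components)
      press <- press + pca_rowwise_press(pca$loadings, x[test, , drop = FALSE])
    }
    return(1 - press / ss)
  }
  enc <- encode_response(y)
  yc_all <- enc$y01 - mean(enc$y01)
  fold_of <- assign_folds(n, folds, seed, strata = enc$y01)
  press <- 0
  for (f in unique(fold_of)) {
    test <- fold_of == f
    if (length(unique(enc$y01[!test])) < 2L) {
      stop("training fold ", f, " contains a single class; reduce folds",
           call. = FALSE)
    }
    ytr <- enc$y01[!test]
    fit <- opls_core(x[!test, , drop = FALSE], ytr - mean(ytr), n_orthogonal)
    yhat <- opls_predict(fit, x[test, , drop = FALSE]) + mean(ytr)
    press <- press + sum((enc$y01[test] - yhat)^2)
  }
  1 - press / sum(yc_all^2)
}

# PRESS for held-out rows: each variable predicted from the others through
# the loadings (A x A normal equations with a rank-one downdate per variable).
pca_rowwise_press <- function(loadings, x_test) {
  ptp <- crossprod(loadings)
  b_full <- tcrossprod(t(loadings), x_test) # A x m
  press <- 0
  for (j in seq_len(nrow(loadings))) {
    p_j <- loadings[j, ]
    a_j <- ptp - tcrossprod(p_j)
    b_j <- b_full - outer(p_j, x_test[, j])
    t_hat <- tryCatch(solve(a_j, b_j), error = function(e) {
      solve(a_j + diag(1e-12, nrow(a_j)), b_j)
    })
    xhat_j <- drop(crossprod(p_j, t_hat))
    press <- press + sum((x_test[, j] - xhat_j)^2)
  }
  press
}

#' Fit an OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis: one
#' predictive component capturing class-correlated variation after `K`
#' orthogonal components of class-uncorrelated variation have been removed.
#' Reports cumulative R2X (data variance modeled by predictive plus
#' orthogonal components), R2Y (class-response variance explained) and
#' cross-validated Q2 ([q2_crossval()]). With `n_orthogonal = NULL` the
#' orthogonal component count is chosen by adding components while Q2
#' improves by at least `q2_gain`.
#'
#' @param x Scaled samples-by-features matrix.
#' @param y Two-class response (the `"case"` level codes as 1).
#' @param n_orthogonal Orthogonal component count, or `NULL` for the
#'   Q2-improvement rule.
#' @param folds,seed Cross-validation settings (see [q2_crossval()]).
#' @param q2_gain Minimum Q2 improvement to keep adding orthogonal
#'   components (default 0.01).
#' @param max_orthogonal Cap for the automatic rule.
#' @return Object of class `latent_model` with `kind = "oplsda"`: predictive
#'   `scores`/`loadings`/`weights`, orthogonal `scores_ortho` /
#'   `loadings_ortho` / `weights_ortho`, covariance loadings `cov_loadings`,
#'   and `metrics` (`r2x_cum`, `r2y_cum`, `q2_cum`, `n_orthogonal`).
#' @export
fit_oplsda <- function(x, y, n_orthogonal = 0L, folds = 7L, seed = 1L,
                       q2_gain = 0.01, max_orthogonal = 5L) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("matrix has missing values", call. = FALSE)
  enc <- encode_response(y)
  yc <- enc$y01 - mean(enc$y01)

  if (is.null(n_orthogonal)) {
    q2_prev <- q2_crossval(x, y, n_orthogonal = 0L, folds = folds, seed = seed)
    n_orthogonal <- 0L
    while (n_orthogonal < max_orthogonal) {
      q2_next <- tryCatch(
        q2_crossval(x, y, n_orthogonal = n_orthogonal + 1L, folds = folds,
                    seed = seed),
        error = function(e) -Inf
      )
      if (!is.finite(q2_next) || q2_next - q2_prev < q2_gain) break
      n_orthogonal <- n_orthogonal + 1L
      q2_prev <- q2_next
    }
  }

  fit <- opls_core(x, yc, n_orthogonal)
  yhat <- fit$t * fit$c
  r2y <- 1 - sum((yc - yhat)^2) / sum(yc^2)
  recon <- tcrossprod(fit$t, fit$p)
  for (k in seq_along(fit$t_ortho)) {
    recon <- recon + tcrossprod(fit$t_ortho[[k]], fit$p_ortho[[k]])
  }
  r2x_cum <- 1 - sum((x - recon)^2) / sum(x^2)
  q2 <- q2_crossval(x, y, n_orthogonal = n_orthogonal, folds = folds,
                    seed = seed)
  n <- nrow(x)
  cov_loadings <- drop(crossprod(x, fit$t)) / (n - 1)
  names(cov_loadings) <- colnames(x)

  t_o <- if (n_orthogonal > 0) do.call(cbind, fit$t_ortho) else
    matrix(0, n, 0)
  p_o <- if (n_orthogonal > 0) do.call(cbind, fit$p_ortho) else
    matrix(0, ncol(x), 0)
  structure(
    list(kind = "oplsda",
         scores = matrix(fit$t, ncol = 1,
                         dimnames = list(rownames(x), "predictive")),
         loadings = matrix(fit$p, ncol = 1,
                           dimnames = list(colnames(x), "predictive")),
         weights = fit$w, c_coef = fit$c,
         weights_ortho = fit$w_ortho,
         scores_ortho = t_o, loadings_ortho = p_o,
         cov_loadings = cov_loadings,
         y_mean = mean(enc$y01), labels = enc$labels,
         metrics = list(r2x_cum = r2x_cum, r2y_cum = r2y, q2_cum = q2,
                        n_orthogonal = n_orthogonal)),
    class = "latent_model"
  )
}

#' @export
print.latent_model <- function(x, ...) {
  if (x$kind == "pca") {
    cat(sprintf("<latent_model> PCA, %d component(s), R2X(cum) = %.3f\n",
                x$n_components, x$r2x_cum[x$n_components]))
  } else {
    m <- x$metrics
    cat(sprintf(paste0("<latent_model> OPLS-DA, 1 predictive + %d orthogonal ",
                       "component(s)\n  R2X(cum) = %.3f, R2Y(cum) = %.3f, ",
                       "Q2(cum) = %.3f\n"),
                m$n_orthogonal, m$r2x_cum, m$r2y_cum, m$q2_cum))
  }
  invisible(x)
}

#' Rank features by discriminant relevance
#'
#' Features ordered by the absolute covariance between the scaled data and
#' the OPLS-DA predictive score (descending); ties broken by feature id for
#' determinism. PCA models are rejected: ranking is discriminant-based.
#'
#' @param model A fitted OPLS-DA [fit_oplsda()] model.
#' @return Data frame with `feature_id`, `cov_loading`, `rank`.
#' @export
rank_features <- function(model) {
  stopifnot(inherits(model, "latent_model"))
  if (model$kind != "oplsda") {
    stop("feature ranking requires an OPLS-DA model, not ", model$kind,
         call. = FALSE)
  }
  cl <- model$cov_loadings
  ids <- names(cl) %||% as.character(seq_along(cl))
  ord <- order(-abs(cl), ids)
  data.frame(feature_id = ids[ord], cov_loading = unname(cl[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Q2 under label permutation
#'
#' Null distribution of the cross-validated Q2: the class labels are
#' permuted `n_perm` times (seeded) and the OPLS-DA Q2 recomputed for each
#' permutation. A sound model on structured data should have a true Q2 far
#' above this null.
#'
#' @inheritParams fit_oplsda
#' @param n_perm Number of permutations.
#' @return Numeric vector of permuted Q2 values.
#' @export
permutation_q2 <- function(x, y, n_orthogonal = 0L, folds = 7L, seed = 1L,
                           n_perm = 20L) {
  set.seed(seed)
  perms <- replicate(n_perm, sample(length(y)), simplify = FALSE)
  vapply(seq_len(n_perm), function(i) {
    q2_crossval(x, y[perms[[i]]], n_orthogonal = n_orthogonal, folds = folds,
                seed = seed + i)
  }, numeric(1))
}

#' Export a latent model's scores, loadings and metrics
#'
#' Scores and loadings as tab-separated text (plot-ready), metrics as JSON.
#'
#' @param model A `latent_model`.
#' @param prefix Output path prefix; files `<prefix>_scores.tsv`,
#'   `<prefix>_loadings.tsv`, `<prefix>_metrics.json` are written.
#' @return Invisibly, the written paths.
#' @export
export_latent_model <- function(model, prefix) {
  stopifnot(inherits(model, "latent_model"))
  sc <- data.frame(sample_id = rownames(model$scores) %||%
                     seq_len(nrow(model$scores)),
                   model$scores, check.names = FALSE)
  ld <- data.frame(feature_id = rownames(model$loadings) %||%
                     seq_len(nrow(model$loadings)),
                   model$loadings, check.names = FALSE)
  if (model$kind == "oplsda" && ncol(model$scores_ortho) > 0) {
    on <- sprintf("orthogonal%d", seq_len(ncol(model$scores_ortho)))
    sc[on] <- model$scores_ortho
    ld[on] <- model$loadings_ortho
  }
  paths <- paste0(prefix, c("_scores.tsv", "_loadings.tsv", "_metrics.json"))
  utils::write.table(sc, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ld, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  metrics <- if (model$kind == "pca") {
    list(r2x_cum = model$r2x_cum[model$n_components],
         components = model$n_components)
  } else {
    model$metrics
  }
  jsonlite::write_json(metrics, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
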