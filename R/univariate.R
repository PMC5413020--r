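#' Signed case/control fold change
#'
#' Ratio of group means `r = mean(case)/mean(control)`, reported as `r` when
#' `r >= 1` and `-1/r` otherwise, so a 36.9-fold reduction in cases prints as
#' -36.9. Antisymmetric under swapping the groups; equal means map to +1.
#'
#' @param case_values,control_values Numeric vectors of (non-negative)
#'   intensities with positive means.
#' @return Signed fold change with `|FC| >= 1`.
#' @export
signed_fold_change <- function(case_values, control_values) {
  if (length(case_values) < 1L || length(control_values) < 1L) {
    stop("need at least one value per group", call. = FALSE)
  }
  m1 <- mean(case_values)
  m0 <- mean(control_values)
  if (!is.finite(m1) || !is.finite(m0) || m1 <= 0 || m0 <= 0) {
    stop("group means must be positive and finite", call. = FALSE)
  }
  r <- m1 / m0
  if (r >= 1) r else -1 / r
}

# Solve trigamma(y) = x by Newton iteration (monotone decreasing trigamma).
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (iter in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Fit the empirical-Bayes variance prior
#'
#' Method-of-moments fit of a scaled inverse-chi-square prior
#' (parameters `s0^2`, `d0`) to per-feature sample variances, via the first
#' two moments of the log variances. When the observed spread of the log
#' variances does not exceed its expected chi-square sampling value, the
#' variances are consistent with a common value: `d0 = Inf` and `s0^2` is
#' their geometric mean.
#'
#' @param variances Per-feature pooled sample variances (>= 2 features).
#' @param df Residual degrees of freedom of each variance (scalar).
#' @return List of class `shrinkage_estimate` with elements `s0_sq`, `d0`,
#'   and `df_residual`.
#' @export
fit_variance_prior <- function(variances, df) {
  if (length(variances) < 2L) stop("need at least two variances", call. = FALSE)
  if (df < 1) stop("residual df must be >= 1", call. = FALSE)
  if (all(variances <= 0)) stop("all variances are zero", call. = FALSE)
  ok <- is.finite(variances) & variances > 0
  if (!all(ok)) {
    warning(sum(!ok), " non-positive variance(s) excluded from prior fit")
    variances <- variances[ok]
  }
  z <- log(variances)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(mean(z))
  }
  structure(list(s0_sq = s0_sq, d0 = d0, df_residual = df),
            class = "shrinkage_estimate")
}

#' @export
print.shrinkage_estimate <- function(x, ...) {
  cat(sprintf("<shrinkage_estimate> s0^2 = %.6g, d0 = %s (residual df %g)\n",
              x$s0_sq, format(x$d0), x$df_residual))
  invisible(x)
}

#' Moderated two-sample t-statistic
#'
#' Pooled two-sample t with the per-feature variance shrunk toward the prior:
#' `s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)` with residual df
#' `d = n1 + n2 - 2`; the statistic is referred to a t distribution on
#' `d0 + d` degrees of freedom. With `d0 = 0` this is exactly the classical
#' pooled t-test; with `d0 = Inf` the variance is fixed at `s0^2`.
#'
#' @param case_values,control_values Numeric vectors (>= 2 each).
#' @param prior A [fit_variance_prior()] result, or a list with `s0_sq`, `d0`.
#' @return List with `t` (case minus control), `df_total`, `p` (two-sided).
#' @export
moderated_t <- function(case_values, control_values, prior) {
  n1 <- length(case_values)
  n2 <- length(control_values)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 values per group", call. = FALSE)
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * stats::var(case_values) +
           (n2 - 1) * stats::var(control_values)) / d
  st <- shrink_variances(s2, prior, d)
  if (st$s_tilde_sq <= 0) stop("shrunk variance is zero", call. = FALSE)
  tval <- (mean(case_values) - mean(control_values)) /
    sqrt(st$s_tilde_sq * (1 / n1 + 1 / n2))
  list(t = tval, df_total = st$df_total,
       p = 2 * stats::pt(-abs(tval), df = st$df_total))
}

# Vectorized shrinkage shared by moderated_t and differential_analysis.
shrink_variances <- function(s2, prior, d) {
  d0 <- prior$d0
  s_tilde_sq <- if (is.infinite(d0)) {
    rep(prior$s0_sq, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * prior$s0_sq + d * s2) / (d0 + d)
  }
  list(s_tilde_sq = s_tilde_sq, df_total = d0 + d)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values controlling the false-discovery rate
#' (wraps `stats::p.adjust(method = "BH")` after range validation).
#'
#' @param p P-values in `[0, 1]`.
#' @return Q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Flag differential features
#'
#' The selection rule for the differential feature matrix: strict
#' `p < p_cut` and `|FC| > fc_cut` (up or down).
#'
#' @param results Data frame with columns `p` and `fold_change`
#'   (a [differential_analysis()] result works directly).
#' @param p_cut,fc_cut Strict thresholds (defaults 0.05 and 1.5).
#' @return `results` with a logical `selected` column; the count is messaged.
#' @export
select_features <- function(results, p_cut = 0.05, fc_cut = 1.5) {
  stopifnot(all(c("p", "fold_change") %in% names(results)))
  results$selected <- results$p < p_cut & abs(results$fold_change) > fc_cut
  message("select_features: ", sum(results$selected), " of ", nrow(results),
          " features with p < ", p_cut, " and |FC| > ", fc_cut)
  results
}

#' Combine per-family p-values (Fisher's method)
#'
#' For the family-wise meta-analysis: each patient family is contrasted
#' against the control cohort and the per-family p-values for a feature are
#' combined as `X = -2 sum(log p) ~ chi-square(2k)`. Zero p-values are
#' floored at the smallest positive double with a warning.
#'
#' @param p Per-family p-values (>= 2 families).
#' @return List with `statistic`, `df`, `p_combined`, `p_family`.
#' @export
combine_family_contrasts <- function(p) {
  if (length(p) < 2L) stop("need p-values from at least two families", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (any(p == 0)) {
    warning("zero p-value(s) floored at the smallest positive double")
    p <- pmax(p, .Machine$double.xmin)
  }
  x <- -2 * sum(log(p))
  k <- length(p)
  list(statistic = x, df = 2 * k,
       p_combined = stats::pchisq(x, df = 2 * k, lower.tail = FALSE),
       p_family = p)
}

#' Per-feature differential analysis of a pretreated cohort
#'
#' For every feature: signed fold change on the normalized intensity scale,
#' and a moderated t-statistic on log2 intensities with the variance prior
#' fitted across all features ([fit_variance_prior()]), two-sided p-value,
#' and Benjamini-Hochberg q-value; features are then flagged with the
#' `p < p_cut`, `|FC| > fc_cut` rule.
#'
#' @param x A pretreated [feature_table()] (complete, normalized, positive).
#' @param p_cut,fc_cut Selection thresholds passed to [select_features()].
#' @return Data frame of class `differential_result` (feature_id, mz,
#'   rt_seconds, fold_change, log2_fc, t, df, p, q, selected) with the fitted
#'   prior in attribute `prior`.
#' @export
differential_analysis <- function(x, p_cut = 0.05, fc_cut = 1.5) {
  stopifnot(inherits(x, "feature_table"))
  if (anyNA(x$intensity)) stop("impute missing values first", call. = FALSE)
  if (any(x$intensity <= 0)) {
    stop("differential analysis needs strictly positive intensities", call. = FALSE)
  }
  ci <- case_columns(x)
  ki <- control_columns(x)
  if (length(ci) < 2L || length(ki) < 2L) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  n1 <- length(ci)
  n2 <- length(ki)
  d <- n1 + n2 - 2

  lx <- log2(x$intensity)
  m1 <- rowMeans(lx[, ci, drop = FALSE])
  m2 <- rowMeans(lx[, ki, drop = FALSE])
  v1 <- apply(lx[, ci, drop = FALSE], 1, stats::var)
  v2 <- apply(lx[, ki, drop = FALSE], 1, stats::var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d

  prior <- fit_variance_prior(s2, d)
  st <- shrink_variances(s2, prior, d)
  tval <- (m1 - m2) / sqrt(st$s_tilde_sq * (1 / n1 + 1 / n2))
  pval <- 2 * stats::pt(-abs(tval), df = st$df_total)

  fc <- vapply(seq_len(nrow(x$intensity)), function(i) {
    signed_fold_change(x$intensity[i, ci], x$intensity[i, ki])
  }, numeric(1))

  out <- data.frame(
    feature_id = x$features$feature_id, mz = x$features$mz,
    rt_seconds = x$features$rt_seconds, polarity = x$features$polarity,
    fold_change = fc, log2_fc = m1 - m2, t = tval, df = st$df_total,
    p = pval, q = bh_fdr(pval), stringsAsFactors = FALSE
  )
  out <- select_features(out, p_cut = p_cut, fc_cut = fc_cut)
  attr(out, "prior") <- prior
  class(out) <- c("differential_result", class(out))
  out
}

#' Write a differential result table
#'
#' @param results A [differential_analysis()] result.
#' @param path File path (tab-separated).
#' @return The path, invisibly.
#' @export
write_differential_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
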