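#' Remove features by missingness
#'
#' Noise filtering: a feature is eliminated when its missing fraction across
#' all samples (cases and controls pooled) is at or above `threshold` —
#' features missing from at least 75% of the data are dropped under the
#' default. Feature order is preserved; the number removed is reported as a
#' message and stored in the `n_removed` attribute.
#'
#' @param x A [feature_table()].
#' @param threshold Missing-fraction cutoff in (0, 1]; features with missing
#'   fraction `>= threshold` are removed.
#' @return Filtered [feature_table()].
#' @export
filter_missing <- function(x, threshold = 0.75) {
  stopifnot(inherits(x, "feature_table"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  if (nrow(x$intensity) == 0L) stop("feature table is empty", call. = FALSE)
  miss_frac <- rowMeans(is.na(x$intensity))
  keep <- miss_frac < threshold
  message("filter_missing: removed ", sum(!keep), " of ", length(keep),
          " features (missing fraction >= ", threshold, ")")
  out <- feature_table(x$intensity[keep, , drop = FALSE],
                       x$features[keep, , drop = FALSE], x$samples)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Impute missing intensities by half the feature minimum
#'
#' Detection-limit surrogate: each missing cell is replaced by half the
#' feature's minimum present intensity. Present values are never altered.
#'
#' @param x A [feature_table()]; every feature must have at least one present
#'   value (guaranteed after [filter_missing()] at any threshold < 1).
#' @return Completed [feature_table()] with no missing values.
#' @export
impute_missing <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  mat <- x$intensity
  n_miss <- rowSums(is.na(mat))
  if (any(n_miss == ncol(mat))) {
    stop("feature(s) with no present values cannot be imputed: ",
         paste(utils::head(x$features$feature_id[n_miss == ncol(mat)], 5),
               collapse = ", "), call. = FALSE)
  }
  needs <- which(n_miss > 0L)
  for (i in needs) {
    fill <- min(mat[i, ], na.rm = TRUE) / 2
    mat[i, is.na(mat[i, ])] <- fill
  }
  message("impute_missing: filled ", sum(n_miss), " missing cells in ",
          length(needs), " features (half-minimum)")
  feature_table(mat, x$features, x$samples)
}

#' Total-sum (total-intensity) normalization
#'
#' Each sample's intensities are divided by the sample's total, so every
#' value becomes a fraction of the spectral sum and each sample sums to 1.
#' Within-sample ratios between features are unchanged. Idempotent.
#'
#' @param x A [feature_table()] with no missing values (impute first).
#' @return Normalized [feature_table()].
#' @export
sum_normalize <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  if (anyNA(x$intensity)) {
    stop("sum_normalize requires a complete matrix; impute missing values first",
         call. = FALSE)
  }
  totals <- colSums(x$intensity)
  if (any(totals <= 0)) {
    stop("zero-total sample(s): ",
         paste(x$samples$sample_id[totals <= 0], collapse = ", "), call. = FALSE)
  }
  feature_table(sweep(x$intensity, 2, totals, "/"), x$features, x$samples)
}

#' Full data pretreatment: filter, impute, normalize
#'
#' The pipeline's pretreatment in its fixed order: missingness filter at
#' `threshold`, half-minimum imputation, then total-sum normalization.
#' Running the composition on its own output changes nothing.
#'
#' @inheritParams filter_missing
#' @return Pretreated [feature_table()].
#' @export
preprocess_table <- function(x, threshold = 0.75) {
  sum_normalize(impute_missing(filter_missing(x, threshold)))
}
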