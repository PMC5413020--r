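#' Construct a feature table
#'
#' The central container of the pipeline: an LC-MS feature-by-sample intensity
#' matrix plus feature annotations (m/z, retention time, polarity) and sample
#' metadata (class, family). Missing intensities are `NA`; present values must
#' be non-negative.
#'
#' @param intensity Numeric matrix, features in rows, samples in columns.
#' @param features Data frame with columns `feature_id`, `mz`, `rt_seconds`,
#'   `polarity`; one row per intensity-matrix row.
#' @param samples Data frame with columns `sample_id`, `class` (values
#'   `"case"`/`"control"`), and optionally `family`, `age`, `sex`; one row per
#'   intensity-matrix column.
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(intensity, features, samples) {
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  stopifnot(is.data.frame(features), is.data.frame(samples))
  if (nrow(features) != nrow(intensity)) {
    stop("features has ", nrow(features), " rows but intensity has ",
         nrow(intensity), call. = FALSE)
  }
  if (nrow(samples) != ncol(intensity)) {
    stop("samples has ", nrow(samples), " rows but intensity has ",
         ncol(intensity), " columns", call. = FALSE)
  }
  for (col in c("feature_id", "mz", "rt_seconds", "polarity")) {
    if (!col %in% names(features)) stop("features lacks column '", col, "'", call. = FALSE)
  }
  for (col in c("sample_id", "class")) {
    if (!col %in% names(samples)) stop("samples lacks column '", col, "'", call. = FALSE)
  }
  if (anyDuplicated(features$feature_id)) stop("duplicate feature ids", call. = FALSE)
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids", call. = FALSE)
  bad <- !samples$class %in% c("case", "control")
  if (any(bad)) {
    stop("sample class must be 'case' or 'control' (offending: ",
         paste(samples$sample_id[bad], collapse = ", "), ")", call. = FALSE)
  }
  if (any(intensity < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative where present", call. = FALSE)
  }
  rownames(intensity) <- features$feature_id
  colnames(intensity) <- samples$sample_id
  rownames(features) <- NULL
  rownames(samples) <- NULL
  structure(list(intensity = intensity, features = features, samples = samples),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  n_missing <- sum(is.na(x$intensity))
  cat(sprintf(paste0(
    "<feature_table> %d features x %d samples (%d case / %d control), ",
    "%.1f%% missing\n"),
    nrow(x$intensity), ncol(x$intensity),
    sum(x$samples$class == "case"), sum(x$samples$class == "control"),
    100 * n_missing / length(x$intensity)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensity)

#' Write a feature table to delimited text
#'
#' Two tab-separated files: the intensity file has feature annotation columns
#' followed by one column per sample (empty cell = missing); the metadata file
#' has one row per sample.
#'
#' @param x A [feature_table()].
#' @param path Intensity file path.
#' @param metadata_path Sample metadata file path; default derives
#'   `<path>_samples.tsv` next to `path`.
#' @return Invisibly, the two paths.
#' @export
write_feature_table <- function(x, path,
                                metadata_path = default_metadata_path(path)) {
  stopifnot(inherits(x, "feature_table"))
  out <- cbind(x$features, as.data.frame(x$intensity, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  utils::write.table(x$samples, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(c(path, metadata_path))
}

default_metadata_path <- function(path) {
  paste0(sub("\\.[A-Za-z0-9]+$", "", path), "_samples.tsv")
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Intensity file path.
#' @param metadata_path Sample metadata file path.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path,
                               metadata_path = default_metadata_path(path)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (!file.exists(metadata_path)) {
    stop("no such metadata file: ", metadata_path, call. = FALSE)
  }
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = "")
  samples <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                               na.strings = "")
  meta_cols <- c("feature_id", "mz", "rt_seconds", "polarity")
  intensity <- as.matrix(raw[, setdiff(names(raw), meta_cols), drop = FALSE])
  feature_table(intensity, raw[, meta_cols], samples)
}

# Convenience accessors used across the statistical stages.
case_columns <- function(x) which(x$samples$class == "case")
control_columns <- function(x) which(x$samples$class == "control")
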