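#' Pipeline run configuration
#'
#' Collects every stage parameter with its documented default. A config
#' round-trips losslessly through its YAML file form
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param missing_threshold Missingness filter cutoff ([filter_missing()]).
#' @param p_cut,fc_cut Feature-selection thresholds ([select_features()]).
#' @param tolerance,rt_window Annotation settings ([match_features()]).
#' @param scaling_mode Scaling for the multivariate stage
#'   ([scale_matrix()]).
#' @param pca_components PCA component cap.
#' @param n_orthogonal OPLS-DA orthogonal components (`NULL` = automatic
#'   Q2-improvement rule).
#' @param folds Cross-validation folds.
#' @param seed Master seed for every stochastic step.
#' @param library_path,rules_path Optional overrides for the bundled
#'   metabolite library and adduct rule table.
#' @return List of class `run_config`.
#' @export
run_config <- function(missing_threshold = 0.75, p_cut = 0.05, fc_cut = 1.5,
                       tolerance = 0.003, rt_window = 10,
                       scaling_mode = "unit-variance", pca_components = 16L,
                       n_orthogonal = 0L, folds = 7L, seed = 1L,
                       library_path = NULL, rules_path = NULL) {
  cfg <- list(missing_threshold = missing_threshold, p_cut = p_cut,
              fc_cut = fc_cut, tolerance = tolerance, rt_window = rt_window,
              scaling_mode = scaling_mode,
              pca_components = as.integer(pca_components),
              n_orthogonal = if (is.null(n_orthogonal)) NULL
                             else as.integer(n_orthogonal),
              folds = as.integer(folds), seed = as.integer(seed),
              library_path = library_path, rules_path = rules_path)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$rt_window) && is.character(vals$rt_window)) {
    vals$rt_window <- as.numeric(vals$rt_window) # ".inf" round-trip
  }
  do.call(run_config, vals)
}

#' Simulate a cohort and write its files
#'
#' Wraps [generate_cohort()]: writes the feature table, sample metadata and
#' ground truth under `dir` and logs a design summary.
#'
#' @param design A [cohort_design()].
#' @param dir Output directory (created if needed).
#' @param force Overwrite existing outputs (default `FALSE`: refusal).
#' @return Invisibly, the [generate_cohort()] result.
#' @export
simulate_cohort <- function(design, dir, force = FALSE) {
  stopifnot(inherits(design, "cohort_design"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("features.tsv", "features_samples.tsv",
                            "ground_truth.tsv"))
  if (!force && any(file.exists(paths))) {
    stop("output exists (use force = TRUE): ",
         paste(paths[file.exists(paths)], collapse = ", "), call. = FALSE)
  }
  cohort <- generate_cohort(design)
  write_feature_table(cohort$table, paths[1], paths[2])
  write_ground_truth(cohort$truth, paths[3])
  message(sprintf(
    "simulate_cohort: %d cases / %d controls, %d features (%d noise), seed %d",
    design$n_cases, design$n_controls, nrow(cohort$table$intensity),
    sum(cohort$truth$is_noise), design$seed))
  invisible(cohort)
}

#' Run the full pipeline on a feature table
#'
#' Executes the stage sequence filter, impute, normalize, univariate
#' statistics, PCA and OPLS-DA, annotation, fingerprint report. When `dir`
#' is given, all artifacts plus a machine-readable run manifest (parameter
#' values, seed, per-stage counts) are written there.
#'
#' @param x A [feature_table()] (e.g. from [generate_cohort()] or
#'   [read_feature_table()]).
#' @param config A [run_config()].
#' @param dir Optional output directory.
#' @return List of class `pipeline_result` with elements `table`
#'   (pretreated), `differential`, `pca`, `oplsda`, `ranking`, `annotation`,
#'   `report`, `manifest`.
#' @export
run_pipeline <- function(x, config = run_config(), dir = NULL) {
  stopifnot(inherits(x, "feature_table"), inherits(config, "run_config"))
  library <- metabolite_library(config$library_path)
  rules <- adduct_rules(config$rules_path)

  n_in <- nrow(x$intensity)
  pre <- preprocess_table(x, threshold = config$missing_threshold)
  n_kept <- nrow(pre$intensity)

  diff <- differential_analysis(pre, p_cut = config$p_cut,
                                fc_cut = config$fc_cut)

  xs <- scale_matrix(t(pre$intensity), mode = config$scaling_mode)
  pca <- fit_pca(xs$x, n_components = min(config$pca_components,
                                          nrow(xs$x) - 1L, ncol(xs$x)))

  # OPLS-DA on the differential feature matrix, mirroring the study's use of
  # the selected-feature data matrix; falls back to all features when the
  # selection is degenerate.
  sel <- diff$selected
  if (sum(sel) < 2L) sel <- rep(TRUE, nrow(diff))
  xsel <- scale_matrix(t(pre$intensity[sel, , drop = FALSE]),
                       mode = config$scaling_mode)
  opls <- fit_oplsda(xsel$x, pre$samples$class,
                     n_orthogonal = config$n_orthogonal,
                     folds = config$folds, seed = config$seed)
  ranking <- rank_features(opls)

  annotation <- annotate_cohort(diff, library = library, rules = rules,
                                tolerance = config$tolerance,
                                rt_window = config$rt_window)
  report <- fingerprint_report(annotation, ordering = library$name)

  manifest <- list(
    package_version = as.character(utils::packageVersion("plasmafp")),
    seed = config$seed,
    parameters = unclass(config),
    counts = list(
      features_in = n_in, features_after_filter = n_kept,
      features_tested = nrow(diff), features_selected = sum(diff$selected),
      features_in_oplsda = sum(sel), metabolites_annotated =
        nrow(annotation$summary)),
    metrics = list(pca_r2x_cum = pca$r2x_cum[pca$n_components],
                   oplsda = opls$metrics,
                   variance_prior = list(
                     s0_sq = attr(diff, "prior")$s0_sq,
                     d0 = if (is.finite(attr(diff, "prior")$d0))
                       attr(diff, "prior")$d0 else "Inf"))
  )

  result <- structure(
    list(table = pre, differential = diff, pca = pca, oplsda = opls,
         ranking = ranking, annotation = annotation, report = report,
         manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_table(pre, file.path(dir, "pretreated.tsv"))
    write_differential_results(diff, file.path(dir, "differential.tsv"))
    export_latent_model(pca, file.path(dir, "pca"))
    export_latent_model(opls, file.path(dir, "oplsda"))
    utils::write.table(ranking, file.path(dir, "ranking.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(annotation$matches, file.path(dir, "annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    write_fingerprint_report(report, file.path(dir, "fingerprint_report.tsv"))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cnt <- x$manifest$counts
  cat("<pipeline_result>\n")
  cat(sprintf("  features: %d in -> %d after filter, %d selected\n",
              cnt$features_in, cnt$features_after_filter,
              cnt$features_selected))
  cat(sprintf("  OPLS-DA: R2X %.3f, R2Y %.3f, Q2 %.3f\n",
              x$oplsda$metrics$r2x_cum, x$oplsda$metrics$r2y_cum,
              x$oplsda$metrics$q2_cum))
  cat(sprintf("  metabolites annotated: %d\n", cnt$metabolites_annotated))
  invisible(x)
}
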