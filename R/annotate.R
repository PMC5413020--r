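#' Match observed features to library metabolites through the adduct grammar
#'
#' Every (metabolite, ion form) pair with matching polarity is compared to
#' each feature; features within the absolute mass tolerance are matched.
#' When a metabolite matches several features, the retained set must co-elute
#' within a retention-time window of width `rt_window`: the largest subset
#' whose retention times span at most `rt_window` is kept (earliest window on
#' ties). A feature matching more than one metabolite is flagged ambiguous on
#' all of them (isobaric collision, e.g. citrate vs isocitrate).
#'
#' @param features Data frame with columns `feature_id`, `mz`, `rt_seconds`,
#'   `polarity` — or a [feature_table()], whose feature axis is used.
#' @param library Metabolite library ([metabolite_library()]).
#' @param rules Adduct rule table ([adduct_rules()]).
#' @param tolerance Absolute match tolerance in Da (default 0.003).
#' @param rt_window Co-elution window in seconds (default 10; `Inf` disables
#'   the constraint). Features without a retention time are exempt.
#' @return Data frame of class `annotation_matches`: one row per
#'   (metabolite, form, feature) match with `observed_mz`, `theoretical_mz`,
#'   `delta_mz` (4 decimals), `rt_seconds` and an `ambiguous` flag.
#' @export
match_features <- function(features, library = metabolite_library(),
                           rules = adduct_rules(), tolerance = 0.003,
                           rt_window = 10) {
  if (inherits(features, "feature_table")) features <- features$features
  stopifnot(is.data.frame(features),
            all(c("feature_id", "mz", "polarity") %in% names(features)))
  if (!"rt_seconds" %in% names(features)) features$rt_seconds <- NA_real_
  if (nrow(library) == 0L) stop("metabolite library is empty", call. = FALSE)
  if (nrow(rules) == 0L) stop("adduct rule set is empty", call. = FALSE)
  if (!is.numeric(tolerance) || tolerance <= 0) {
    stop("tolerance must be positive", call. = FALSE)
  }

  ions <- theoretical_ion_table(library, rules)
  out <- list()
  for (i in seq_len(nrow(ions))) {
    ion <- ions[i, ]
    cand <- features$polarity == ion$polarity &
      abs(features$mz - ion$theoretical_mz) <= tolerance
    if (!any(cand)) next
    hit <- features[cand, , drop = FALSE]
    out[[length(out) + 1L]] <- data.frame(
      metabolite = ion$metabolite, kegg_id = ion$kegg_id,
      formula = ion$formula, form = ion$form,
      feature_id = hit$feature_id, observed_mz = hit$mz,
      theoretical_mz = ion$theoretical_mz,
      delta_mz = delta_mz(hit$mz, ion$theoretical_mz),
      rt_seconds = hit$rt_seconds, stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    matches <- data.frame(metabolite = character(), kegg_id = character(),
                          formula = character(), form = character(),
                          feature_id = character(), observed_mz = numeric(),
                          theoretical_mz = numeric(), delta_mz = numeric(),
                          rt_seconds = numeric(), ambiguous = logical(),
                          stringsAsFactors = FALSE)
    class(matches) <- c("annotation_matches", class(matches))
    return(matches)
  }
  matches <- do.call(rbind, out)

  # co-elution: per metabolite keep the largest subset spanning <= rt_window
  if (is.finite(rt_window)) {
    keep <- rep(TRUE, nrow(matches))
    for (met in unique(matches$metabolite)) {
      idx <- which(matches$metabolite == met)
      rt <- matches$rt_seconds[idx]
      usable <- is.finite(rt)
      if (sum(usable) < 2L) next
      ord <- order(rt[usable])
      rts <- rt[usable][ord]
      best_n <- 0L
      best_lo <- 1L
      for (lo in seq_along(rts)) {
        n_in <- sum(rts >= rts[lo] & rts <= rts[lo] + rt_window)
        if (n_in > best_n) {
          best_n <- n_in
          best_lo <- lo
        }
      }
      in_win <- rt >= rts[best_lo] & rt <= rts[best_lo] + rt_window
      in_win[!is.finite(rt)] <- TRUE
      keep[idx[!in_win]] <- FALSE
    }
    matches <- matches[keep, , drop = FALSE]
  }

  # isobaric collisions: same feature claimed by several metabolites
  n_mets <- tapply(matches$metabolite, matches$feature_id,
                   function(m) length(unique(m)))
  shared <- names(n_mets)[n_mets > 1L]
  flagged_mets <- unique(matches$metabolite[matches$feature_id %in% shared])
  matches$ambiguous <- matches$metabolite %in% flagged_mets
  rownames(matches) <- NULL
  class(matches) <- c("annotation_matches", class(matches))
  matches
}

#' Average signed fold change over matched ion forms
#'
#' Arithmetic mean of the signed per-feature fold changes of all forms
#' matched to one metabolite (no intensity weighting). Mixed signs trigger a
#' sign-inconsistency warning; an empty input is an error (the metabolite has
#' no result, not a zero).
#'
#' @param fold_changes Signed per-feature fold changes (>= 1 finite value).
#' @return Signed mean.
#' @examples
#' average_fold_change(c(-40.0, -35.0, -36.0, -36.6)) # -36.9
#' @export
average_fold_change <- function(fold_changes) {
  fold_changes <- fold_changes[is.finite(fold_changes)]
  if (length(fold_changes) == 0L) {
    stop("no matched forms with finite fold changes", call. = FALSE)
  }
  if (length(unique(sign(fold_changes))) > 1L) {
    warning("sign-inconsistent fold changes across matched forms")
  }
  mean(fold_changes)
}

#' Annotate a cohort: matches plus per-metabolite averaged fold changes
#'
#' Joins the feature-level differential results onto the adduct matches and
#' aggregates a signed average fold change per metabolite.
#'
#' @param results A [differential_analysis()] result (carries m/z, retention
#'   time, polarity and per-feature fold changes).
#' @inheritParams match_features
#' @return List of class `annotation_result` with `matches` (per-form rows
#'   including `fold_change`) and `summary` (one row per annotated
#'   metabolite: `avg_fold_change`, `n_forms`, `ambiguous`,
#'   `sign_consistent`).
#' @export
annotate_cohort <- function(results, library = metabolite_library(),
                            rules = adduct_rules(), tolerance = 0.003,
                            rt_window = 10) {
  stopifnot(is.data.frame(results),
            all(c("feature_id", "mz", "polarity", "fold_change") %in%
                  names(results)))
  matches <- match_features(
    results[, c("feature_id", "mz", "rt_seconds", "polarity")],
    library = library, rules = rules, tolerance = tolerance,
    rt_window = rt_window
  )
  matches$fold_change <-
    results$fold_change[match(matches$feature_id, results$feature_id)]

  mets <- unique(matches$metabolite)
  summary <- do.call(rbind, lapply(mets, function(met) {
    rows <- matches[matches$metabolite == met, ]
    fcs <- rows$fold_change[is.finite(rows$fold_change)]
    sign_ok <- length(unique(sign(fcs))) <= 1L
    avg <- withCallingHandlers(
      average_fold_change(rows$fold_change),
      warning = function(w) invokeRestart("muffleWarning")
    )
    data.frame(metabolite = met, kegg_id = rows$kegg_id[1],
               formula = rows$formula[1], n_forms = nrow(rows),
               avg_fold_change = avg, sign_consistent = sign_ok,
               ambiguous = any(rows$ambiguous), stringsAsFactors = FALSE)
  }))
  if (is.null(summary)) {
    summary <- data.frame(metabolite = character(), kegg_id = character(),
                          formula = character(), n_forms = integer(),
                          avg_fold_change = numeric(),
                          sign_consistent = logical(), ambiguous = logical(),
                          stringsAsFactors = FALSE)
  }
  structure(list(matches = matches, summary = summary),
            class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat(sprintf("<annotation_result> %d matched forms across %d metabolite(s)\n",
              nrow(x$matches), nrow(x$summary)))
  invisible(x)
}

#' Fingerprint report table
#'
#' Emits the per-form annotation report: metabolite, KEGG id, match form,
#' observed m/z, delta m/z (4 decimals) and the metabolite's averaged signed
#' fold change rounded to 1 decimal. Metabolite blocks follow library order
#' by default; per-feature rows are retained for box-plot rendering.
#'
#' @param annotation An [annotate_cohort()] result.
#' @param ordering Metabolite name ordering; defaults to the bundled library
#'   order, with unlisted metabolites appended.
#' @return Data frame, one row per matched form.
#' @export
fingerprint_report <- function(annotation,
                               ordering = metabolite_library()$name) {
  stopifnot(inherits(annotation, "annotation_result"))
  m <- annotation$matches
  if (nrow(m) == 0L) {
    return(data.frame(metabolite = character(), kegg_id = character(),
                      match_form = character(), mz = numeric(),
                      delta_mz = numeric(), fold_change = numeric(),
                      avg_fold_change = numeric(), feature_id = character(),
                      stringsAsFactors = FALSE))
  }
  avg <- annotation$summary$avg_fold_change[
    match(m$metabolite, annotation$summary$metabolite)]
  out <- data.frame(
    metabolite = m$metabolite, kegg_id = m$kegg_id, match_form = m$form,
    mz = m$observed_mz, delta_mz = m$delta_mz, fold_change = m$fold_change,
    avg_fold_change = round_half_away(avg, 1L), feature_id = m$feature_id,
    stringsAsFactors = FALSE
  )
  ord <- c(intersect(ordering, out$metabolite),
           setdiff(unique(out$metabolite), ordering))
  out <- out[order(match(out$metabolite, ord), out$match_form), ]
  rownames(out) <- NULL
  out
}

#' Write/read a fingerprint report
#'
#' Tab-separated; round-trips through its own reader.
#'
#' @param report A [fingerprint_report()] table.
#' @param path File path.
#' @return `write_fingerprint_report()` returns the path invisibly;
#'   `read_fingerprint_report()` returns the data frame.
#' @export
write_fingerprint_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_fingerprint_report
#' @export
read_fingerprint_report <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
}
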