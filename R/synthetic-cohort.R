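#' Default metabolite panel for the synthetic cohort
#'
#' The nine fingerprint metabolites with their bundled library entries, the
#' ion forms each emits, the planted signed case/control fold change, and a
#' plausible base plasma ion abundance. Planted fold-change defaults are the
#' per-metabolite averages reported for the ACO2-deficiency fingerprint
#' (e.g. cis-aconitate -36.9, isocitrate -17.7); they double as ground truth
#' for pipeline validation.
#'
#' @param library Metabolite library data frame ([metabolite_library()]).
#' @return Data frame with columns `name`, `kegg_id`, `formula`, `forms`
#'   (semicolon-separated rule names), `fold_change`, `base_abundance`.
#' @export
default_metabolite_panel <- function(library = metabolite_library()) {
  forms <- c(
    "cis-aconitate"       = "M-H[-];M(C13)-H[-];M+Cl[-];M+Cl37[-]",
    "isocitrate"          = "M-H[-];M+Cl[-];M+Cl37[-];M+ACN-H[-]",
    "alpha-ketoglutarate" = "M-H[-];M+CH3COO[-];M-CO2+H[1+]",
    "succinate"           = "M+Br[-];M+Br81[-]",
    "fumarate"            = "M+Cl37[-]",
    "malate"              = "M+ACN-H[-];M+CH3COO[-]",
    "phosphoenolpyruvate" = "M+CH3COO[-];M-HCOOK+H[1+];M-CO2+H[1+]",
    "glutamate"           = paste0("M-H[-];M+HCOO[-];M-C3H4O2+H[1+];M-HCOOH+H[1+];",
                                   "M-CO2+H[1+];M-CO+H[1+];M-H2O+H[1+];M+H[1+];",
                                   "M+H2O+H[1+]"),
    "hydroxybutyrate"     = "M-H[-];M+Na-2H[-];M+HCOO[-];M+CH3COO[-]"
  )
  fold_change <- c(
    "cis-aconitate" = -36.9, "isocitrate" = -17.7, "alpha-ketoglutarate" = -4.3,
    "succinate" = 1.1, "fumarate" = -1.4, "malate" = -1.1,
    "phosphoenolpyruvate" = -6.9, "glutamate" = 1.8, "hydroxybutyrate" = -21.8
  )
  base_abundance <- c(
    "cis-aconitate" = 2e5, "isocitrate" = 3e5, "alpha-ketoglutarate" = 5e5,
    "succinate" = 8e5, "fumarate" = 4e5, "malate" = 1e6,
    "phosphoenolpyruvate" = 1.5e5, "glutamate" = 5e6, "hydroxybutyrate" = 2e6
  )
  stopifnot(all(library$name %in% names(forms)))
  data.frame(
    name = library$name, kegg_id = library$kegg_id, formula = library$formula,
    forms = unname(forms[library$name]),
    fold_change = unname(fold_change[library$name]),
    base_abundance = unname(base_abundance[library$name]),
    stringsAsFactors = FALSE
  )
}

#' Specify a synthetic case/control cohort
#'
#' The study-design defaults emulate the fingerprint cohort: 8 patients in
#' 4 families (sizes 2, 3, 2 and 1) versus 30 controls, with the nine panel
#' metabolites planted at their reported average fold changes, Gaussian mass
#' error (sd 0.0005 Da), log-normal intensity noise (CV 0.2),
#' intensity-dependent missingness (baseline rate 0.1), and 1000 background
#' noise features spread over the 67-1000 m/z acquisition range.
#'
#' @param n_cases,n_controls Group sizes (each >= 2).
#' @param family_sizes Integer partition of the cases into families.
#' @param metabolite_panel Panel data frame; see [default_metabolite_panel()].
#' @param mass_error_sd Gaussian m/z error sd in Da.
#' @param rt_window Width (seconds) within which all ion forms of one
#'   metabolite co-elute.
#' @param intensity_cv Coefficient of variation of the log-normal intensity
#'   noise; 0 disables noise.
#' @param missing_rate Baseline missingness probability, inflated at low
#'   intensities; 0 disables missingness.
#' @param n_noise_features Number of background features with no class effect.
#' @param mz_range,rt_range Acquisition m/z and retention-time ranges.
#' @param seed Integer seed governing every stochastic draw.
#' @param rules Adduct rule table used to compute theoretical m/z values.
#' @return Object of class `cohort_design`.
#' @export
cohort_design <- function(n_cases = 8L, n_controls = 30L,
                          family_sizes = c(2L, 3L, 2L, 1L),
                          metabolite_panel = default_metabolite_panel(),
                          mass_error_sd = 0.0005, rt_window = 10,
                          intensity_cv = 0.2, missing_rate = 0.1,
                          n_noise_features = 1000L,
                          mz_range = c(67, 1000), rt_range = c(60, 840),
                          seed = 1L, rules = adduct_rules()) {
  if (n_cases < 2L || n_controls < 2L) {
    stop("need at least 2 cases and 2 controls", call. = FALSE)
  }
  if (sum(family_sizes) != n_cases) {
    stop("family sizes must sum to n_cases", call. = FALSE)
  }
  if (nrow(metabolite_panel) == 0L) stop("metabolite panel is empty", call. = FALSE)
  fc <- metabolite_panel$fold_change
  if (any(!is.finite(fc)) || any(fc == 0) || any(abs(fc) < 1)) {
    stop("planted fold changes must be finite, nonzero and have |FC| >= 1",
         call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  stopifnot(mass_error_sd >= 0, intensity_cv >= 0, n_noise_features >= 0)
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         family_sizes = as.integer(family_sizes),
         metabolite_panel = metabolite_panel, mass_error_sd = mass_error_sd,
         rt_window = rt_window, intensity_cv = intensity_cv,
         missing_rate = missing_rate,
         n_noise_features = as.integer(n_noise_features),
         mz_range = mz_range, rt_range = rt_range, seed = as.integer(seed),
         rules = rules),
    class = "cohort_design"
  )
}

#' Generate a synthetic cohort with known ground truth
#'
#' Deterministic given the design seed. Each panel metabolite emits one
#' feature per requested ion form at its theoretical m/z plus Gaussian mass
#' error; all forms of a metabolite share a retention-time window. Control
#' intensities are log-normal around the form's abundance; case intensities
#' are multiplied by the planted fold change (ratio `FC` when `FC >= 1`,
#' `1/|FC|` when negative, i.e. down in cases). The class effect is applied
#' before missingness, so strongly down-regulated metabolites can fall below
#' the effective detection limit in cases. Missingness is logistic in
#' log-intensity, calibrated so the expected overall rate equals
#' `missing_rate` and capped at twice the baseline for the lowest
#' intensities, emulating detection-limit censoring. Background noise
#' features carry no class effect.
#'
#' @param design A [cohort_design()].
#' @return List with elements `table` (a [feature_table()]) and `truth`
#'   (ground-truth data frame: one row per feature with source metabolite,
#'   form, theoretical m/z and planted fold change; noise rows have `NA`).
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  panel <- design$metabolite_panel

  samples <- data.frame(
    sample_id = c(sprintf("case_%02d", seq_len(design$n_cases)),
                  sprintf("ctrl_%02d", seq_len(design$n_controls))),
    class = rep(c("case", "control"), c(design$n_cases, design$n_controls)),
    family = c(rep(sprintf("F%d", seq_along(design$family_sizes)),
                   design$family_sizes),
               rep(NA_character_, design$n_controls)),
    stringsAsFactors = FALSE
  )
  samples$age <- round(stats::runif(nrow(samples), 1.8, 21), 1)
  samples$sex <- sample(c("F", "M"), nrow(samples), replace = TRUE)

  # Panel features: one per (metabolite, form), co-eluting per metabolite.
  feat <- list()
  for (i in seq_len(nrow(panel))) {
    met <- panel[i, ]
    form_names <- strsplit(met$forms, ";", fixed = TRUE)[[1]]
    rt_met <- stats::runif(1, design$rt_range[1] + design$rt_window,
                           design$rt_range[2] - design$rt_window)
    for (fn in form_names) {
      ion <- theoretical_mz(met$formula, fn, design$rules)
      feat[[length(feat) + 1L]] <- data.frame(
        metabolite = met$name, kegg_id = met$kegg_id, form = fn,
        polarity = ion$polarity, theoretical_mz = ion$mz,
        mz = ion$mz + stats::rnorm(1, 0, design$mass_error_sd),
        rt_seconds = rt_met + stats::runif(1, -0.45, 0.45) * design$rt_window,
        fold_change = met$fold_change,
        abundance = met$base_abundance * stats::runif(1, 0.05, 1),
        stringsAsFactors = FALSE
      )
    }
  }
  feat <- do.call(rbind, feat)

  if (design$n_noise_features > 0L) {
    noise <- data.frame(
      metabolite = NA_character_, kegg_id = NA_character_, form = NA_character_,
      polarity = sample(c("negative", "positive"), design$n_noise_features,
                        replace = TRUE),
      theoretical_mz = NA_real_,
      mz = stats::runif(design$n_noise_features, design$mz_range[1],
                        design$mz_range[2]),
      rt_seconds = stats::runif(design$n_noise_features, design$rt_range[1],
                                design$rt_range[2]),
      fold_change = NA_real_,
      abundance = 10^stats::runif(design$n_noise_features, 4.5, 6.5),
      stringsAsFactors = FALSE
    )
    feat <- rbind(feat, noise)
  }
  feat$feature_id <- sprintf("FT%04d", seq_len(nrow(feat)))

  n_feat <- nrow(feat)
  n_samp <- nrow(samples)
  is_case <- samples$class == "case"
  case_ratio <- ifelse(is.na(feat$fold_change), 1,
                       ifelse(feat$fold_change >= 1, feat$fold_change,
                              1 / abs(feat$fold_change)))
  mean_mat <- outer(feat$abundance, rep(1, n_samp))
  mean_mat[, is_case] <- mean_mat[, is_case] * case_ratio

  sdlog <- sqrt(log(1 + design$intensity_cv^2))
  noise_mat <- if (sdlog > 0) {
    exp(matrix(stats::rnorm(n_feat * n_samp, -sdlog^2 / 2, sdlog),
               n_feat, n_samp))
  } else {
    matrix(1, n_feat, n_samp)
  }
  intensity <- mean_mat * noise_mat

  if (design$missing_rate > 0) {
    # logistic detection-limit censoring in log intensity: the threshold is
    # solved so the expected overall rate equals missing_rate, and the
    # low-intensity inflation is capped at twice the baseline rate so even
    # strongly suppressed signals keep some observed values
    z <- log(intensity)
    t_star <- stats::uniroot(
      function(t) mean(stats::plogis((t - z) / 0.5)) - 0.5, range(z)
    )$root
    p_miss <- pmin(0.95, 2 * design$missing_rate *
                     stats::plogis((t_star - z) / 0.5))
    drop <- matrix(stats::runif(n_feat * n_samp), n_feat, n_samp) < p_miss
    intensity[drop] <- NA_real_
  }

  features <- feat[, c("feature_id", "mz", "rt_seconds", "polarity")]
  truth <- feat[, c("feature_id", "metabolite", "kegg_id", "form",
                    "theoretical_mz", "mz", "rt_seconds", "fold_change")]
  truth$is_noise <- is.na(truth$metabolite)
  rownames(truth) <- NULL

  list(table = feature_table(intensity, features, samples), truth = truth)
}

#' Write/read cohort ground truth
#'
#' Tab-separated, one row per feature; round-trips losslessly.
#'
#' @param truth Ground-truth data frame from [generate_cohort()].
#' @param path File path.
#' @return `write_ground_truth()` returns the path invisibly;
#'   `read_ground_truth()` returns the data frame.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  out <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  out$is_noise <- as.logical(out$is_noise)
  out
}
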