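neg_feature <- function(mz, id = "F001", rt = NA_real_, polarity = "negative") {
  data.frame(feature_id = id, mz = mz, rt_seconds = rt, polarity = polarity,
             stringsAsFactors = FALSE)
}

test_that("an observed negative-mode ion matches its library form", {
  m <- match_features(neg_feature(191.0184))
  iso <- m[m$metabolite == "isocitrate" & m$form == "M-H[-]", ]
  expect_equal(nrow(iso), 1L)
  expect_identical(iso$delta_mz, -0.0013)
  # a feature exactly at the theoretical mass matches with delta 0
  exact <- theoretical_mz("C4H6O4", "M+Br[-]")$mz
  m2 <- match_features(neg_feature(exact))
  expect_identical(m2$delta_mz[m2$metabolite == "succinate"], 0)
})

test_that("isobaric library entries are both matched and flagged ambiguous", {
  lib <- rbind(metabolite_library(),
               data.frame(name = "citrate", kegg_id = "C00158",
                          formula = "C6H8O7", stringsAsFactors = FALSE))
  m <- match_features(neg_feature(191.0184), library = lib)
  hit <- m[m$form == "M-H[-]" & m$metabolite %in% c("citrate", "isocitrate"), ]
  expect_setequal(hit$metabolite, c("citrate", "isocitrate"))
  expect_true(all(hit$ambiguous))
})

test_that("shrinking the tolerance never adds matches", {
  co <- generate_cohort(small_design(seed = 6L))
  key <- function(m) paste(m$metabolite, m$form, m$feature_id)
  prev <- NULL
  for (tol in c(0.003, 0.002, 0.001, 0.0005)) {
    m <- match_features(co$table$features, tolerance = tol, rt_window = Inf)
    if (!is.null(prev)) expect_true(all(key(m) %in% prev))
    prev <- key(m)
  }
})

test_that("noise-free features map one-to-one onto their sources", {
  d <- cohort_design(seed = 17L, mass_error_sd = 0, n_noise_features = 0L)
  co <- generate_cohort(d)
  m <- match_features(co$table$features, tolerance = 0.003, rt_window = 10)
  truth <- co$truth
  got <- paste(m$metabolite, m$form, m$feature_id)
  want <- paste(truth$metabolite, truth$form, truth$feature_id)
  expect_setequal(got, want)  # every planted ion found, zero false matches
  expect_equal(nrow(m), nrow(truth))
})

test_that("small mass errors rarely cost a match at the default tolerance", {
  hits <- 0L; total <- 0L
  for (sd_seed in 1:5) {
    co <- generate_cohort(cohort_design(seed = 300L + sd_seed,
                                        n_noise_features = 0L))
    m <- match_features(co$table$features, tolerance = 0.003, rt_window = 10)
    found <- paste(m$metabolite, m$form) %in%
      paste(co$truth$metabolite, co$truth$form)
    hits <- hits + sum(paste(co$truth$metabolite, co$truth$form) %in%
                         paste(m$metabolite, m$form))
    total <- total + nrow(co$truth)
  }
  expect_gte(hits / total, 0.99)
})

test_that("the co-elution window separates mass-coincident metabolites", {
  # isocitrate M+Cl and phosphoenolpyruvate M+CH3COO differ by < 0.3 mDa;
  # distinct retention times must keep them apart
  iso_mz <- theoretical_mz("C6H8O7", "M+Cl[-]")$mz
  pep_mz <- theoretical_mz("C3H5O6P", "M+CH3COO[-]")$mz
  expect_lt(abs(iso_mz - pep_mz), 0.003)
  feats <- rbind(
    neg_feature(theoretical_mz("C6H8O7", "M-H[-]")$mz, "iso1", rt = 100),
    neg_feature(iso_mz, "iso2", rt = 102),
    neg_feature(pep_mz, "pep1", rt = 400),
    neg_feature(theoretical_mz("C3H5O6P", "M-CO2+H[1+]")$mz, "pep2", rt = 401,
                polarity = "positive")
  )
  m <- match_features(feats, tolerance = 0.003, rt_window = 10)
  iso <- m[m$metabolite == "isocitrate", ]
  pep <- m[m$metabolite == "phosphoenolpyruvate", ]
  expect_setequal(iso$feature_id, c("iso1", "iso2"))
  expect_setequal(pep$feature_id, c("pep1", "pep2"))
})

test_that("fold-change averaging is a plain signed mean", {
  expect_equal(average_fold_change(c(-40.0, -35.0, -36.0, -36.6)), -36.9)
  expect_equal(average_fold_change(2.0), 2.0)
  expect_warning(avg <- average_fold_change(c(-2, 2)), "sign")
  expect_equal(avg, 0)
  expect_error(average_fold_change(numeric(0)), "no matched forms")
})

test_that("the fingerprint report mirrors the annotation in library order", {
  co <- generate_cohort(small_design(seed = 2L))
  pre <- suppressMessages(preprocess_table(co$table))
  res <- suppressMessages(differential_analysis(pre))
  ann <- annotate_cohort(res, rt_window = 10)
  rep_tbl <- fingerprint_report(ann)
  lib_order <- metabolite_library()$name
  expect_identical(unique(rep_tbl$metabolite),
                   lib_order[lib_order %in% rep_tbl$metabolite])
  expect_true(all(c("metabolite", "kegg_id", "match_form", "mz", "delta_mz",
                    "avg_fold_change") %in% names(rep_tbl)))
  # report round-trips through its own reader
  path <- tempfile(fileext = ".tsv")
  write_fingerprint_report(rep_tbl, path)
  expect_equal(read_fingerprint_report(path), rep_tbl, tolerance = 1e-9)
  # averaged fold change equals the mean of that metabolite's form rows
  for (met in unique(rep_tbl$metabolite)) {
    rows <- rep_tbl[rep_tbl$metabolite == met, ]
    expect_equal(rows$avg_fold_change[1], round(mean(rows$fold_change), 1),
                 tolerance = 0.051)
  }
})

test_that("empty inputs degrade gracefully", {
  none <- match_features(neg_feature(500.123))
  expect_equal(nrow(none), 0L)
  expect_error(match_features(neg_feature(100), library = metabolite_library()[0, ]),
               "empty")
  res <- data.frame(feature_id = "F001", mz = 500.123, rt_seconds = 1,
                    polarity = "negative", fold_change = 2)
  ann <- annotate_cohort(res)
  expect_equal(nrow(ann$summary), 0L)
  expect_equal(nrow(fingerprint_report(ann)), 0L)
})
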