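# Shared fixtures, built in code.

# The published annotation table: metabolite, ion form, observed m/z and the
# printed observed-minus-calculated delta. `verified` marks the rows whose
# printed delta is reproduced exactly at 4 decimals by the package's mass
# convention (frozen from an independent hand computation with the reference
# atomic masses); the remaining rows are internally inconsistent with their
# stated formula/form at the printed precision and are excluded from exact
# checks, not silently skipped.
table2_rows <- function() {
  rows <- read.table(header = TRUE, stringsAsFactors = FALSE, text = '
metabolite form observed_mz printed_delta verified
cis-aconitate M-H[-] 173.0077 -0.0014 FALSE
cis-aconitate M(C13)-H[-] 174.0111 -0.0014 TRUE
cis-aconitate M+Cl[-] 208.9847 -0.0006 TRUE
cis-aconitate M+Cl37[-] 210.9818 -0.0005 TRUE
isocitrate M-H[-] 191.0184 -0.0013 TRUE
isocitrate M+Cl[-] 226.9954 -0.0005 TRUE
isocitrate M+Cl37[-] 228.9925 -0.0004 TRUE
isocitrate M+ACN-H[-] 232.0462 -0.0001 TRUE
alpha-ketoglutarate M-H[-] 145.0128 -0.0014 TRUE
alpha-ketoglutarate M+CH3COO[-] 205.0342 -0.0006 TRUE
alpha-ketoglutarate M-CO2+H[1+] 103.0385 -0.0005 TRUE
succinate M+Br[-] 196.9458 0.0009 TRUE
succinate M+Br81[-] 198.9439 0.0010 TRUE
fumarate M+Cl37[-] 152.9766 -0.0003 TRUE
malate M+ACN-H[-] 174.0394 -0.0014 TRUE
malate M+CH3COO[-] 193.0342 -0.0006 TRUE
phosphoenolpyruvate M+CH3COO[-] 226.9954 -0.0003 TRUE
phosphoenolpyruvate M-HCOOK+H[1+] 85.0282 -0.0002 FALSE
phosphoenolpyruvate M-CO2+H[1+] 124.9988 -0.0011 FALSE
glutamate M-H[-] 148.0423 -0.0008 FALSE
glutamate M+HCOO[-] 192.0496 -0.0012 TRUE
glutamate M-C3H4O2+H[1+] 76.0393 -0.0001 FALSE
glutamate M-HCOOH+H[1+] 102.0544 -0.0007 FALSE
glutamate M-CO2+H[1+] 104.0701 -0.0006 FALSE
glutamate M-CO+H[1+] 120.0647 -0.0008 TRUE
glutamate M-H2O+H[1+] 130.0489 -0.0010 TRUE
glutamate M+H[1+] 148.0591 -0.0014 FALSE
glutamate M+H2O+H[1+] 166.0711 0.0000 FALSE
hydroxybutyrate M-H[-] 105.0371 -0.0001 FALSE
hydroxybutyrate M+Na-2H[-] 124.0136 -0.0011 FALSE
hydroxybutyrate M+HCOO[-] 149.0440 -0.0009 FALSE
hydroxybutyrate M+CH3COO[-] 163.0598 -0.0008 TRUE
')
  lib <- metabolite_library()
  rows$formula <- lib$formula[match(rows$metabolite, lib$name)]
  rows
}

# Small, fast cohort for module-level tests.
small_design <- function(seed = 42L, ...) {
  cohort_design(seed = seed, n_noise_features = 50L, ...)
}

# A tiny feature table built by hand: `values` is features x samples.
toy_table <- function(values, classes = NULL, mz = NULL, polarity = "negative",
                      rt = NULL) {
  values <- as.matrix(values)
  n_feat <- nrow(values)
  n_samp <- ncol(values)
  if (is.null(classes)) {
    classes <- rep(c("case", "control"), length.out = n_samp)
  }
  feature_table(
    values,
    data.frame(feature_id = sprintf("F%03d", seq_len(n_feat)),
               mz = mz %||% seq(100, 200, length.out = n_feat),
               rt_seconds = rt %||% seq(60, 600, length.out = n_feat),
               polarity = rep_len(polarity, n_feat),
               stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("S%02d", seq_len(n_samp)),
               class = classes, stringsAsFactors = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
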