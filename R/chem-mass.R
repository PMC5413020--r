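#' @keywords internal
"_PACKAGE"

# Monoisotopic masses (Da) of the supported elements and heavy isotopes.
# Carbon-12 is exact by definition; the remainder are standard reference values.
ELEMENT_MASSES <- c(
  C      = 12,
  H      = 1.0078250319,
  O      = 15.9949146221,
  N      = 14.0030740052,
  P      = 30.97376151,
  S      = 31.97207069,
  Na     = 22.98976928,
  K      = 38.96370649,
  Cl     = 34.96885268,
  Br     = 78.9183376,
  `13C`  = 13.00335484,
  `37Cl` = 36.96590259,
  `81Br` = 80.9162906
)

# Mass of a proton; the charge carrier for proton-transfer ion forms.
PROTON_MASS <- 1.007276

# Elements the neutral molecule itself donates when a rule removes atoms.
# Salt/adduct elements (Na, K, Cl, Br) may be removed by a rule without
# appearing in the neutral formula: they enter transiently in the ion source
# (e.g. the in-source potassium formate loss M-HCOOK+H).
ORGANIC_CORE_ELEMENTS <- c("C", "H", "N", "O", "P", "S")

#' Parse a molecular formula in Hill notation
#'
#' Converts a formula string such as `"C6H8O7"` or `"C3H5O6P"` into a named
#' count vector over element symbols. Counts of one may be implicit. Only the
#' element symbols in the package's monoisotopic mass table are accepted
#' (C, H, N, O, P, S, Na, K, Cl, Br).
#'
#' @param text Non-empty formula string.
#' @return Named integer vector of element counts (class
#'   `elemental_formula`); elements with zero count are absent.
#' @examples
#' parse_formula("C6H6O6")
#' parse_formula("C3H5O6P")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("formula must be a single non-empty string", call. = FALSE)
  }
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (paste(tokens, collapse = "") != text) {
    stop("cannot parse formula '", text, "': unrecognised characters", call. = FALSE)
  }
  syms <- sub("[0-9]+$", "", tokens)
  counts <- sub("^[A-Za-z]+", "", tokens)
  counts <- ifelse(counts == "", "1", counts)
  counts <- as.integer(counts)
  unknown <- setdiff(syms, names(ELEMENT_MASSES))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(counts < 1L)) {
    stop("element counts must be positive integers in '", text, "'", call. = FALSE)
  }
  comp <- tapply(counts, factor(syms, levels = unique(syms)), sum)
  out <- as.integer(comp)
  names(out) <- names(comp)
  class(out) <- "elemental_formula"
  out
}

#' Format an elemental composition back to Hill notation
#'
#' Carbon first, then hydrogen, then remaining elements alphabetically.
#' `format_formula(parse_formula(x))` round-trips any Hill-ordered input.
#'
#' @param composition Named count vector as returned by [parse_formula()].
#' @return Formula string.
#' @export
format_formula <- function(composition) {
  composition <- as_composition(composition)
  syms <- names(composition)
  rest <- sort(setdiff(syms, c("C", "H")))
  ord <- c(intersect(c("C", "H"), syms), rest)
  paste0(ord, ifelse(composition[ord] == 1L, "", composition[ord]), collapse = "")
}

# Accept either a formula string or a named count vector.
as_composition <- function(f) {
  if (is.character(f)) {
    return(parse_formula(f))
  }
  if (is.null(names(f)) || length(f) == 0L) {
    stop("composition must be a named count vector or formula string", call. = FALSE)
  }
  unknown <- setdiff(names(f), names(ELEMENT_MASSES))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  storage.mode(f) <- "integer"
  if (any(f < 1L)) stop("element counts must be >= 1", call. = FALSE)
  class(f) <- "elemental_formula"
  f
}

#' Monoisotopic mass of a composition
#'
#' Sum of count times monoisotopic atomic mass over all elements (and heavy
#' isotopes) in the composition.
#'
#' @param f Formula string or named count vector ([parse_formula()] output).
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C6H6O6") # cis-aconitate, 174.016438
#' @export
monoisotopic_mass <- function(f) {
  comp <- as_composition(f)
  sum(ELEMENT_MASSES[names(comp)] * as.numeric(comp))
}

# Elementwise combination of two compositions; negative results are the
# caller's applicability error.
combine_compositions <- function(f, add = NULL, remove = NULL) {
  tally <- stats::setNames(as.numeric(f), names(f))
  bump <- function(tally, comp, sign) {
    for (el in names(comp)) {
      tally[el] <- (if (el %in% names(tally)) tally[el] else 0) + sign * comp[[el]]
    }
    tally
  }
  if (!is.null(add)) tally <- bump(tally, add, +1)
  if (!is.null(remove)) tally <- bump(tally, remove, -1)
  tally
}

#' Read the bundled (or a user-supplied) adduct/fragment rule table
#'
#' Each rule names an ion form, its polarity, the atoms it adds/removes
#' relative to the neutral molecule, optional single-isotope substitutions
#' (e.g. `"C>13C:1"`), and its charge convention: `proton-transfer` forms
#' shift the mass by one proton mass (minus for negative mode, plus for
#' positive), while `species-attachment` forms add/remove the neutral
#' monoisotopic mass of the attached species with no further correction.
#'
#' @param path Optional path to an alternative tab-separated rule file with
#'   the same columns; defaults to the 18 bundled negative/positive forms.
#' @return Data frame with columns `name`, `polarity`, `atoms_added`,
#'   `atoms_removed`, `isotope_substitutions`, `charge_convention`.
#' @export
adduct_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "adduct_rules.tsv", package = "plasmafp",
                        mustWork = TRUE)
  }
  rules <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  needed <- c("name", "polarity", "atoms_added", "atoms_removed",
              "isotope_substitutions", "charge_convention")
  missing_cols <- setdiff(needed, names(rules))
  if (length(missing_cols) > 0L) {
    stop("adduct rule table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in needed) rules[[col]] <- trimws(rules[[col]])
  bad <- !rules$polarity %in% c("negative", "positive")
  if (any(bad)) stop("invalid polarity for rule(s): ",
                     paste(rules$name[bad], collapse = ", "), call. = FALSE)
  bad <- !rules$charge_convention %in% c("proton-transfer", "species-attachment")
  if (any(bad)) stop("invalid charge convention for rule(s): ",
                     paste(rules$name[bad], collapse = ", "), call. = FALSE)
  rules
}

#' Read the bundled (or a user-supplied) metabolite library
#'
#' The bundled library holds the nine TCA-cycle and associated plasma
#' metabolites of the fingerprint panel, with KEGG identifiers and neutral
#' molecular formulas.
#'
#' @param path Optional path to an alternative tab-separated library with
#'   columns `name`, `kegg_id`, `formula`.
#' @return Data frame with columns `name`, `kegg_id`, `formula`.
#' @export
metabolite_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "metabolite_library.tsv", package = "plasmafp",
                        mustWork = TRUE)
  }
  lib <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("name", "kegg_id", "formula")
  missing_cols <- setdiff(needed, names(lib))
  if (length(missing_cols) > 0L) {
    stop("metabolite library lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  invisible(lapply(lib$formula, parse_formula)) # validate early
  lib
}

# "C>13C:1;Cl>37Cl:1" -> list of list(light, heavy, count)
parse_isotope_substitutions <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(list())
  parts <- strsplit(trimws(text), ";", fixed = TRUE)[[1]]
  lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([A-Za-z]+)>([0-9]+[A-Za-z]+):([0-9]+)$", p))[[1]]
    if (length(m) != 4L) {
      stop("cannot parse isotope substitution '", p, "'", call. = FALSE)
    }
    sub <- list(light = m[2], heavy = m[3], count = as.integer(m[4]))
    if (!sub$light %in% names(ELEMENT_MASSES) || !sub$heavy %in% names(ELEMENT_MASSES)) {
      stop("unknown isotope symbol in substitution '", p, "'", call. = FALSE)
    }
    sub
  })
}

lookup_rule <- function(rule, rules) {
  if (is.character(rule) && length(rule) == 1L) {
    hit <- which(rules$name == rule)
    if (length(hit) != 1L) {
      stop("unknown adduct rule '", rule, "'", call. = FALSE)
    }
    return(as.list(rules[hit, , drop = FALSE]))
  }
  as.list(rule)
}

#' Theoretical m/z of a neutral formula under an adduct/fragment rule
#'
#' Applies the rule's atom additions/removals and isotope substitutions to
#' the neutral composition, then the charge convention: proton-transfer rules
#' subtract (negative mode) or add (positive mode) one proton mass
#' (1.007276 Da); species-attachment rules use the neutral attached-species
#' mass only. All supported forms are singly charged, so the mass equals the
#' m/z.
#'
#' Applicability: removals must not drive any organic-core element
#' (C, H, N, O, P, S) below zero; salt-adduct elements (Na, K, Cl, Br) may be
#' removed without appearing in the neutral formula because they enter
#' transiently in the ion source.
#'
#' @param f Formula string or composition vector for the neutral molecule.
#' @param rule Rule name (looked up in `rules`) or a single-row rule record.
#' @param rules Rule table, by default the bundled [adduct_rules()].
#' @return List of class `ion_mass` with elements `mz`, `rule_name`,
#'   `polarity`, `source_formula`.
#' @examples
#' theoretical_mz("C6H8O7", "M-H[-]")$mz # isocitrate [M-H]-
#' @export
theoretical_mz <- function(f, rule, rules = adduct_rules()) {
  comp <- as_composition(f)
  rule <- lookup_rule(rule, rules)
  added <- if (nzchar(rule$atoms_added %||% "")) parse_formula(rule$atoms_added) else NULL
  removed <- if (nzchar(rule$atoms_removed %||% "")) parse_formula(rule$atoms_removed) else NULL

  tally <- combine_compositions(comp, add = added, remove = removed)
  core <- intersect(names(tally), ORGANIC_CORE_ELEMENTS)
  if (any(tally[core] < 0)) {
    stop("rule '", rule$name, "' is not applicable to ", format_formula(comp),
         ": removal exceeds available atoms", call. = FALSE)
  }

  mass <- monoisotopic_mass(comp) +
    (if (is.null(added)) 0 else monoisotopic_mass(added)) -
    (if (is.null(removed)) 0 else monoisotopic_mass(removed))

  for (sub in parse_isotope_substitutions(rule$isotope_substitutions)) {
    n_light <- if (sub$light %in% names(tally)) tally[[sub$light]] else 0
    if (n_light < sub$count) {
      stop("rule '", rule$name, "' substitutes ", sub$count, " ", sub$light,
           " atom(s) but only ", n_light, " available", call. = FALSE)
    }
    mass <- mass + sub$count * (ELEMENT_MASSES[[sub$heavy]] - ELEMENT_MASSES[[sub$light]])
  }

  if (rule$charge_convention == "proton-transfer") {
    mass <- mass + if (rule$polarity == "negative") -PROTON_MASS else PROTON_MASS
  }
  if (mass <= 0) {
    stop("rule '", rule$name, "' yields non-positive m/z for ",
         format_formula(comp), call. = FALSE)
  }
  structure(
    list(mz = mass, rule_name = rule$name, polarity = rule$polarity,
         source_formula = comp),
    class = "ion_mass"
  )
}

#' @export
print.ion_mass <- function(x, ...) {
  cat(sprintf("<ion_mass> %s of %s: m/z %.6f (%s mode)\n",
              x$rule_name, format_formula(x$source_formula), x$mz, x$polarity))
  invisible(x)
}

# Round half away from zero (base round() is half-to-even).
round_half_away <- function(x, digits = 4L) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Observed-minus-calculated mass difference
#'
#' Signed difference between an observed and a theoretical m/z, computed at
#' full precision and then rounded half-away-from-zero to 4 decimals — the
#' convention used in annotation reports.
#'
#' @param observed Observed m/z (> 0).
#' @param theoretical Theoretical m/z (> 0), a number or an `ion_mass`.
#' @param digits Decimal places to keep (default 4).
#' @return Signed difference in Da, rounded.
#' @examples
#' delta_mz(191.0184, theoretical_mz("C6H8O7", "M-H[-]")) # -0.0013
#' @export
delta_mz <- function(observed, theoretical, digits = 4L) {
  if (inherits(theoretical, "ion_mass")) theoretical <- theoretical$mz
  if (any(observed <= 0) || any(theoretical <= 0)) {
    stop("observed and theoretical m/z must be positive", call. = FALSE)
  }
  round_half_away(observed - theoretical, digits)
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L || (length(a) == 1L && is.na(a))) b else a
}

# All (metabolite x rule) theoretical ions for a library; used by annotation
# and by the synthetic cohort generator.
theoretical_ion_table <- function(library = metabolite_library(),
                                  rules = adduct_rules()) {
  grid <- expand.grid(met = seq_len(nrow(library)), rule = seq_len(nrow(rules)))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    met <- library[grid$met[i], ]
    rule <- as.list(rules[grid$rule[i], ])
    ion <- tryCatch(theoretical_mz(met$formula, rule, rules), error = function(e) NULL)
    if (is.null(ion)) return(NULL)
    data.frame(metabolite = met$name, kegg_id = met$kegg_id, formula = met$formula,
               form = rule$name, polarity = rule$polarity, theoretical_mz = ion$mz,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
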