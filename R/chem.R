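# Accurate-mass arithmetic: molecular formulas, adduct shifts, ppm errors.

# Monoisotopic element masses (Da), CODATA/IUPAC values.
.element_masses <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100,
  Na = 22.9897692809,
  K = 38.96370668
)

#' Parse a molecular formula into element counts
#'
#' @param formula Character vector of Hill-style formulas, e.g. `"C42H80NO8P"`.
#' @return A list of named integer vectors (element -> count), one per input.
#' @examples
#' parse_formula("C42H80NO8P")
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula))
  lapply(formula, function(f) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f, perl = TRUE)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    toks <- toks[nzchar(toks)]
    if (!length(toks) || paste(toks, collapse = "") != f) {
      stop("cannot parse formula: ", f, call. = FALSE)
    }
    el <- sub("[0-9]*$", "", toks)
    ct <- as.integer(ifelse(grepl("[0-9]+$", toks),
      sub("^[A-Za-z]+", "", toks), "1"
    ))
    unknown <- setdiff(el, names(.element_masses))
    if (length(unknown)) {
      stop("unknown element(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    counts <- tapply(ct, el, sum)
    stats::setNames(as.integer(counts), names(counts))
  })
}

#' Monoisotopic mass of a molecular formula
#'
#' @inheritParams parse_formula
#' @return Numeric vector of monoisotopic masses (Da).
#' @examples
#' formula_mass("C42H80NO8P") # 757.5622
#' @export
formula_mass <- function(formula) {
  vapply(parse_formula(formula), function(counts) {
    sum(.element_masses[names(counts)] * counts)
  }, numeric(1))
}

#' Number of atoms of one element in a formula
#'
#' @inheritParams parse_formula
#' @param element Element symbol, default `"C"`.
#' @return Integer vector of counts.
#' @export
element_count <- function(formula, element = "C") {
  vapply(parse_formula(formula), function(counts) {
    n <- counts[element]
    if (is.na(n)) 0L else as.integer(n)
  }, integer(1))
}

#' Adduct rules used for accurate-mass matching
#'
#' The five singly charged adducts considered: `[M+H]+`, `[M+Na]+`,
#' `[M+NH4]+` and `[M+K]+` in positive mode and `[M-H]-` in negative mode.
#' Shifts are proton-bound values; the electron mass is neglected (under
#' 1 ppm at lipid masses).
#'
#' @return A tibble with columns `adduct`, `mode`, `mass_shift` (Da), `charge`.
#' @examples
#' adduct_rules()
#' @export
adduct_rules <- function() {
  tibble::tibble(
    adduct = c("[M+H]+", "[M+Na]+", "[M+NH4]+", "[M+K]+", "[M-H]-"),
    mode = c("positive", "positive", "positive", "positive", "negative"),
    mass_shift = c(1.007276, 22.989218, 18.033823, 38.963158, -1.007276),
    charge = 1L
  )
}

#' Theoretical m/z of a neutral mass under an adduct
#'
#' @param monoisotopic_mass Neutral monoisotopic mass (Da), positive.
#' @param adduct Adduct name matching [adduct_rules()], or a numeric mass
#'   shift in Da. Vectorised and recycled against `monoisotopic_mass`.
#' @return Theoretical m/z (Da) for singly charged ions.
#' @examples
#' theoretical_mz(757.5622, "[M+H]+") # 758.5694
#' @export
theoretical_mz <- function(monoisotopic_mass, adduct) {
  stopifnot(is.numeric(monoisotopic_mass), all(monoisotopic_mass > 0))
  if (is.numeric(adduct)) {
    shift <- adduct
  } else {
    rules <- adduct_rules()
    idx <- match(adduct, rules$adduct)
    if (anyNA(idx)) {
      stop("unknown adduct(s): ", paste(unique(adduct[is.na(idx)]), collapse = ", "),
        call. = FALSE
      )
    }
    shift <- rules$mass_shift[idx]
  }
  monoisotopic_mass + shift
}

#' Signed parts-per-million mass error
#'
#' @param observed Observed m/z (Da).
#' @param theoretical Theoretical m/z (Da), positive.
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @examples
#' ppm_error(758.5770, 758.5694)
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(is.numeric(observed), is.numeric(theoretical), all(theoretical > 0))
  (observed - theoretical) / theoretical * 1e6
}

# Mass of a 13C-for-12C substitution; used for the M+1 isotopologue.
.c13_delta <- 1.0033548378

# Natural 13C abundance ratio per carbon: expected (M+1)/M intensity.
.c13_ratio_per_c <- 0.0107
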