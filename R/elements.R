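#' Element reference table
#'
#' Standard relative atomic masses (IUPAC 2021 abridged) and single-bond
#' covalent radii (Cordero et al. 2008) for the elements commonly found in
#' organic molecular crystals. Masses are in amu, radii in Angstrom.
#'
#' @return A tibble with columns `element`, `mass`, `r_cov`.
#' @export
#' @examples
#' element_table()
element_table <- function() {
  tibble::tribble(
    ~element, ~mass,    ~r_cov,
    "H",       1.008,   0.31,
    "D",       2.014,   0.31,
    "He",      4.003,   0.28,
    "Li",      6.94,    1.28,
    "Be",      9.012,   0.96,
    "B",      10.81,    0.84,
    "C",      12.011,   0.76,
    "N",      14.007,   0.71,
    "O",      15.999,   0.66,
    "F",      18.998,   0.57,
    "Ne",     20.180,   0.58,
    "Na",     22.990,   1.66,
    "Mg",     24.305,   1.41,
    "Al",     26.982,   1.21,
    "Si",     28.085,   1.11,
    "P",      30.974,   1.07,
    "S",      32.06,    1.05,
    "Cl",     35.45,    1.02,
    "Ar",     39.95,    1.06,
    "K",      39.098,   2.03,
    "Ca",     40.078,   1.76,
    "Mn",     54.938,   1.39,
    "Fe",     55.845,   1.32,
    "Co",     58.933,   1.26,
    "Ni",     58.693,   1.24,
    "Cu",     63.546,   1.32,
    "Zn",     65.38,    1.22,
    "Se",     78.971,   1.20,
    "Br",     79.904,   1.20,
    "I",     126.904,   1.39
  )
}

# Lookup helpers; element symbols are matched case-sensitively after
# stripping oxidation-state/label suffixes (e.g. "O1", "N2-" -> "O", "N").
normalize_element <- function(symbol) {
  sym <- sub("[^A-Za-z].*$", "", symbol)
  # CIF labels are often like "C4" or "H5A"; two-letter symbols keep case
  ifelse(sym %in% element_table()$element, sym,
         paste0(toupper(substr(sym, 1, 1)), tolower(substr(sym, 2, nchar(sym)))))
}

element_property <- function(elements, what) {
  tab <- element_table()
  idx <- match(elements, tab$element)
  if (anyNA(idx)) {
    bad <- unique(elements[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tab[[what]][idx]
}

#' Atomic masses for element symbols
#'
#' @param elements Character vector of element symbols.
#' @return Numeric vector of relative atomic masses (amu).
#' @export
atomic_mass <- function(elements) element_property(elements, "mass")

#' Covalent radii for element symbols
#'
#' @param elements Character vector of element symbols.
#' @return Numeric vector of covalent radii (Angstrom).
#' @export
covalent_radius <- function(elements) element_property(elements, "r_cov")
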