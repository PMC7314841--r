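#' Bundled reference tables for the cytosine example
#'
#' Small plain-text tables shipped with the package for the worked example
#' of an anhydrous/monohydrate crystal pair: published lattice-constant
#' determinations of cytosine (C, orthorhombic P2(1)2(1)2(1)) and cytosine
#' monohydrate (C-MH, monoclinic P2(1)/c), and the room-temperature THz
#' absorption peaks of both forms.
#'
#' `reference_lattices()` returns one row per (form, determination) with
#' the six cell parameters and the printed cell volume;
#' `reference_peaks()` returns one row per absorption peak with its
#' frequency (THz) and absorption level (cm^-1).
#'
#' @return A tibble.
#' @export
#' @examples
#' reference_lattices()
#' reference_peaks()
reference_lattices <- function() {
  f <- system.file("extdata", "cytosine_lattice_constants.tsv",
                   package = "modechar", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(f, comment.char = "#"))
}

#' @rdname reference_lattices
#' @export
reference_peaks <- function() {
  f <- system.file("extdata", "cytosine_thz_peaks.tsv",
                   package = "modechar", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(f, comment.char = "#"))
}

#' Lattice object for one bundled determination
#'
#' @param form `"C"` (anhydrous) or `"C-MH"` (monohydrate).
#' @param determination `"reference"`, `"powder"` or `"dft"`.
#' @return A [lattice()].
#' @export
#' @examples
#' cell_volume(reference_lattice("C-MH", "powder"))
reference_lattice <- function(form = c("C", "C-MH"),
                              determination = c("powder", "reference",
                                                "dft")) {
  form <- match.arg(form)
  determination <- match.arg(determination)
  tab <- reference_lattices()
  row <- tab[tab$form == form & tab$determination == determination, ]
  if (nrow(row) != 1) stop("no such determination", call. = FALSE)
  lattice(row$a, row$b, row$c, row$alpha, row$beta, row$gamma)
}
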