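#' Read a crystal structure from CIF text
#'
#' Minimal CIF dialect: the six `_cell_length_*` / `_cell_angle_*` items, an
#' atom loop carrying `_atom_site_fract_x/y/z` together with
#' `_atom_site_label` and/or `_atom_site_type_symbol`, and an optional
#' symmetry loop (`_symmetry_equiv_pos_as_xyz` or
#' `_space_group_symop_operation_xyz`) whose operator strings are kept
#' verbatim for algebraic expansion. Numeric values may carry standard
#' uncertainties in parentheses, which are stripped. No space-group-number
#' lookup is performed.
#'
#' @param file Path to a CIF file, or a character vector of CIF lines via
#'   `text`.
#' @param text Optional character scalar/vector of CIF content (overrides
#'   `file`).
#' @param expand If `TRUE` (default) symmetry operators are expanded via
#'   [expand_symmetry()] so the result is a full P1 cell.
#' @return A [crystal_structure()].
#' @export
read_cif <- function(file = NULL, text = NULL, expand = TRUE) {
  if (is.null(text)) {
    stopifnot(!is.null(file))
    text <- readLines(file, warn = FALSE)
  }
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)

  cif_number <- function(x) as.numeric(sub("\\(.*\\)", "", x))
  get_item <- function(tag) {
    hit <- grep(paste0("^", tag, "\\b"), lines, value = TRUE)
    if (length(hit) == 0) {
      stop("CIF is missing required item ", tag, call. = FALSE)
    }
    strsplit(hit[1], "[[:space:]]+")[[1]][2]
  }

  lat <- lattice(
    a = cif_number(get_item("_cell_length_a")),
    b = cif_number(get_item("_cell_length_b")),
    c = cif_number(get_item("_cell_length_c")),
    alpha = cif_number(get_item("_cell_angle_alpha")),
    beta = cif_number(get_item("_cell_angle_beta")),
    gamma = cif_number(get_item("_cell_angle_gamma"))
  )

  # walk loop_ blocks
  loops <- list()
  i <- 1
  while (i <= length(lines)) {
    if (identical(lines[i], "loop_")) {
      j <- i + 1
      tags <- character()
      while (j <= length(lines) && grepl("^_", lines[j])) {
        tags <- c(tags, strsplit(lines[j], "[[:space:]]+")[[1]][1])
        j <- j + 1
      }
      rows <- list()
      while (j <= length(lines) && nzchar(lines[j]) &&
             !grepl("^(_|loop_|data_)", lines[j])) {
        # respect single-quoted fields (symmetry operators contain commas,
        # not spaces, so simple quote-aware splitting suffices)
        toks <- regmatches(lines[j],
                           gregexpr("'[^']*'|\"[^\"]*\"|[^[:space:]]+", lines[j]))[[1]]
        toks <- gsub("^['\"]|['\"]$", "", toks)
        rows[[length(rows) + 1]] <- toks
        j <- j + 1
      }
      loops[[length(loops) + 1]] <- list(tags = tags, rows = rows)
      i <- j
    } else {
      i <- i + 1
    }
  }

  symtags <- c("_symmetry_equiv_pos_as_xyz", "_space_group_symop_operation_xyz")
  symmetry <- character()
  atoms <- NULL
  for (lp in loops) {
    if (any(symtags %in% lp$tags)) {
      col <- which(lp$tags %in% symtags)[1]
      symmetry <- vapply(lp$rows, function(r) r[col], character(1))
    }
    if ("_atom_site_fract_x" %in% lp$tags) {
      need <- c("_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z")
      miss <- setdiff(need, lp$tags)
      if (length(miss)) {
        stop("CIF atom loop is missing ", paste(miss, collapse = ", "),
             call. = FALSE)
      }
      bad <- which(lengths(lp$rows) != length(lp$tags))
      if (length(bad)) {
        stop("CIF atom loop row ", bad[1], " has ", lengths(lp$rows)[bad[1]],
             " fields, expected ", length(lp$tags), call. = FALSE)
      }
      m <- do.call(rbind, lp$rows)
      colnames(m) <- lp$tags
      label <- if ("_atom_site_label" %in% lp$tags) m[, "_atom_site_label"] else NULL
      elem <- if ("_atom_site_type_symbol" %in% lp$tags) {
        m[, "_atom_site_type_symbol"]
      } else if (!is.null(label)) {
        label
      } else {
        stop("CIF atom loop has neither _atom_site_label nor _atom_site_type_symbol",
             call. = FALSE)
      }
      atoms <- tibble::tibble(
        label = if (is.null(label)) paste0(elem, seq_along(elem)) else label,
        element = normalize_element(elem),
        x = cif_number(m[, "_atom_site_fract_x"]),
        y = cif_number(m[, "_atom_site_fract_y"]),
        z = cif_number(m[, "_atom_site_fract_z"])
      )
    }
  }
  if (is.null(atoms)) {
    stop("CIF is missing an _atom_site_fract_* coordinate loop", call. = FALSE)
  }
  # validate operators early so a bad file fails at read time
  lapply(symmetry, parse_symop)
  s <- crystal_structure(lat, atoms, symmetry = symmetry)
  if (expand && length(symmetry)) expand_symmetry(s) else s
}

#' Write a crystal structure as CIF text
#'
#' Emits the minimal dialect read by [read_cif()]; the round trip preserves
#' the lattice to 1e-6 Angstrom and fractional coordinates to 1e-6.
#'
#' @param structure A [crystal_structure()].
#' @param file Optional path; when `NULL` the CIF text is returned as a
#'   character vector of lines.
#' @param data_name Block name after `data_`.
#' @return The lines, invisibly when written to a file.
#' @export
write_cif <- function(structure, file = NULL, data_name = "modechar") {
  stopifnot(is_crystal_structure(structure))
  lat <- structure$lattice
  out <- c(
    paste0("data_", data_name),
    sprintf("_cell_length_a    %.6f", lat$a),
    sprintf("_cell_length_b    %.6f", lat$b),
    sprintf("_cell_length_c    %.6f", lat$c),
    sprintf("_cell_angle_alpha %.6f", lat$alpha),
    sprintf("_cell_angle_beta  %.6f", lat$beta),
    sprintf("_cell_angle_gamma %.6f", lat$gamma)
  )
  if (length(structure$symmetry)) {
    out <- c(out, "loop_", "_symmetry_equiv_pos_as_xyz",
             sprintf("'%s'", structure$symmetry))
  }
  at <- structure$atoms
  out <- c(out,
           "loop_",
           "_atom_site_label",
           "_atom_site_type_symbol",
           "_atom_site_fract_x",
           "_atom_site_fract_y",
           "_atom_site_fract_z",
           sprintf("%s %s %.8f %.8f %.8f", at$label, at$element,
                   at$x, at$y, at$z))
  if (is.null(file)) return(out)
  writeLines(out, file)
  invisible(out)
}
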