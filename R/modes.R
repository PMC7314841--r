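#' Gamma-point normal mode set
#'
#' Container for a set of normal modes: frequency (THz), IR intensity
#' (arbitrary units) and per-atom real Cartesian displacement vectors
#' indexed in structure atom order. The displacement scale is arbitrary —
#' mode-character percentages are scale-invariant — so no re-normalisation
#' is imposed.
#'
#' @param frequency_thz Numeric vector of mode frequencies (THz), >= 0.
#' @param ir_intensity Numeric vector of IR intensities, >= 0 (recycled to
#'   length of `frequency_thz` when scalar).
#' @param displacements List of n_atoms x 3 numeric matrices, one per mode,
#'   each with at least one nonzero row.
#' @param source Optional provenance string (file of origin).
#' @return An object of class `mode_set`.
#' @export
mode_set <- function(frequency_thz, ir_intensity, displacements,
                     source = NULL) {
  stopifnot(is.numeric(frequency_thz), is.list(displacements),
            length(displacements) == length(frequency_thz))
  if (length(ir_intensity) == 1) {
    ir_intensity <- rep(ir_intensity, length(frequency_thz))
  }
  stopifnot(length(ir_intensity) == length(frequency_thz))
  if (any(frequency_thz < 0)) {
    stop("mode frequencies must be >= 0", call. = FALSE)
  }
  if (any(ir_intensity < 0)) stop("IR intensities must be >= 0", call. = FALSE)
  n <- unique(vapply(displacements, nrow, integer(1)))
  if (length(n) != 1) {
    stop("all modes must cover the same number of atoms", call. = FALSE)
  }
  for (d in displacements) {
    stopifnot(is.matrix(d), ncol(d) == 3)
    if (all(d == 0)) stop("a mode has an all-zero displacement field",
                          call. = FALSE)
  }
  structure(
    list(frequency_thz = frequency_thz,
         ir_intensity = ir_intensity,
         displacements = lapply(displacements, unname),
         n_atoms = n,
         provenance = list(source = source, scaling_factor = NULL)),
    class = "mode_set"
  )
}

#' @export
print.mode_set <- function(x, ...) {
  sf <- x$provenance$scaling_factor
  cat(sprintf("<mode_set> %d mode(s) over %d atoms; frequencies %.3f-%.3f THz%s\n",
              length(x$frequency_thz), x$n_atoms,
              min(x$frequency_thz), max(x$frequency_thz),
              if (is.null(sf)) "" else sprintf(" (scaled by %.3f)", sf)))
  invisible(x)
}

is_mode_set <- function(x) inherits(x, "mode_set")

#' @export
length.mode_set <- function(x) length(x$frequency_thz)

#' Named frequency-scaling presets
#'
#' Single linear scaling factors that map 0 K harmonic frequencies onto
#' room-temperature measured peaks: 0.88 for the anhydrous crystal preset
#' and 0.85 for the monohydrate preset (water-containing crystals need the
#' stronger correction because of vibrational anharmonicity).
#'
#' @return Named numeric vector of presets.
#' @export
scaling_presets <- function() c(anhydrous = 0.88, monohydrate = 0.85)

#' Scale mode frequencies by a single linear factor
#'
#' Multiplies every frequency by `factor`; intensities and displacements
#' are untouched. The factor is recorded in provenance exactly once:
#' scaling an already-scaled set is an error (double-scaling guard).
#'
#' @param modes A [mode_set()].
#' @param factor Positive scalar, or a preset name from
#'   [scaling_presets()] (`"anhydrous"` = 0.88, `"monohydrate"` = 0.85).
#' @return The scaled `mode_set`.
#' @export
#' @examples
#' m <- mode_set(2, 1, list(matrix(c(1, 0, 0), 1)))
#' scale_frequencies(m, "anhydrous")$frequency_thz  # 1.76
scale_frequencies <- function(modes, factor) {
  stopifnot(is_mode_set(modes))
  if (is.character(factor)) {
    presets <- scaling_presets()
    if (!factor %in% names(presets)) {
      stop("unknown scaling preset '", factor, "'; available: ",
           paste(names(presets), collapse = ", "), call. = FALSE)
    }
    factor <- presets[[factor]]
  }
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0) {
    stop("scaling factor must be a positive scalar", call. = FALSE)
  }
  if (!is.null(modes$provenance$scaling_factor)) {
    stop("mode set has already been scaled (factor ",
         modes$provenance$scaling_factor,
         "); refusing to scale twice", call. = FALSE)
  }
  modes$frequency_thz <- modes$frequency_thz * factor
  modes$provenance$scaling_factor <- factor
  modes
}

#' Stick spectrum of a mode set
#'
#' @param modes A [mode_set()].
#' @return A tibble with columns `frequency_thz`, `intensity`.
#' @export
stick_spectrum <- function(modes) {
  stopifnot(is_mode_set(modes))
  tibble::tibble(frequency_thz = modes$frequency_thz,
                 intensity = modes$ir_intensity)
}

#' Read and write mode files (JSON)
#'
#' The primary mode-file format is JSON with fields `n_atoms`,
#' `scaling_factor` (null when unscaled) and `modes`, a list of objects
#' `{frequency_thz, ir_intensity, displacements: [[dx,dy,dz], ...]}`.
#'
#' @param file Path to a mode JSON file.
#' @return For `read_modes`, a [mode_set()].
#' @export
read_modes <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (is.null(j$modes)) stop("mode file has no 'modes' field", call. = FALSE)
  md <- j$modes
  disp <- md$displacements
  # jsonlite simplification: a single mode becomes an n x 3 matrix, a
  # homogeneous multi-mode file a modes x n x 3 array
  if (is.array(disp) && length(dim(disp)) == 3) {
    disp <- lapply(seq_len(dim(disp)[1]), function(i) disp[i, , ])
  } else if (is.matrix(disp)) {
    disp <- list(disp)
  }
  disp <- lapply(disp, function(d) {
    if (!is.matrix(d)) d <- do.call(rbind, d)
    storage.mode(d) <- "double"
    d
  })
  ms <- mode_set(md$frequency_thz, md$ir_intensity, disp, source = file)
  if (!is.null(j$scaling_factor)) {
    ms$provenance$scaling_factor <- j$scaling_factor
  }
  ms
}

#' @rdname read_modes
#' @param modes A [mode_set()].
#' @return For `write_modes`, the path, invisibly.
#' @export
write_modes <- function(modes, file) {
  stopifnot(is_mode_set(modes))
  obj <- list(
    n_atoms = modes$n_atoms,
    scaling_factor = modes$provenance$scaling_factor,
    modes = list(
      frequency_thz = modes$frequency_thz,
      ir_intensity = modes$ir_intensity,
      displacements = modes$displacements
    )
  )
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(file)
}

#' Read a plain-text dynamical-matrix mode listing
#'
#' Parses the common text dialect in which each mode starts with a header
#' line `freq (  n) =  <value> [THz] ...` followed by one row per atom of
#' six reals (real/imaginary parts of the x, y, z displacement components,
#' optionally wrapped in parentheses). Imaginary parts larger than 1e-8 of
#' the mode norm are rejected: Gamma-point eigenvectors are real up to
#' phase convention.
#'
#' @param file Path to the text file.
#' @param n_atoms Number of atoms per mode (inferred from the first block
#'   when NULL).
#' @return A [mode_set()] with zero IR intensities (the dialect carries
#'   none).
#' @export
read_modes_text <- function(file, n_atoms = NULL) {
  lines <- readLines(file, warn = FALSE)
  hdr <- grep("freq\\s*\\(", lines)
  if (length(hdr) == 0) {
    stop("no 'freq (' mode headers found in ", file, call. = FALSE)
  }
  freq <- as.numeric(sub(".*=\\s*([-0-9.eE+]+)\\s*\\[THz\\].*", "\\1",
                         lines[hdr]))
  if (anyNA(freq)) stop("unparsable frequency header in ", file, call. = FALSE)
  if (is.null(n_atoms)) {
    end <- if (length(hdr) > 1) hdr[2] - 1 else length(lines)
    block <- lines[(hdr[1] + 1):end]
    n_atoms <- sum(grepl("[0-9]", block) & !grepl("freq", block))
  }
  disp <- vector("list", length(hdr))
  for (k in seq_along(hdr)) {
    block <- lines[(hdr[k] + 1):(hdr[k] + n_atoms)]
    vals <- lapply(block, function(l) {
      as.numeric(regmatches(l, gregexpr("[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?",
                                        l))[[1]])
    })
    if (any(lengths(vals) != 6)) {
      stop("mode ", k, ": expected 6 reals per atom row", call. = FALSE)
    }
    m <- do.call(rbind, vals)
    re <- m[, c(1, 3, 5), drop = FALSE]
    im <- m[, c(2, 4, 6), drop = FALSE]
    if (sqrt(sum(im^2)) > 1e-8 * max(sqrt(sum(re^2)), .Machine$double.eps)) {
      stop("mode ", k, " has a non-negligible imaginary part; ",
           "Gamma-point displacement fields must be real", call. = FALSE)
    }
    disp[[k]] <- re
  }
  mode_set(freq, rep(0, length(freq)), disp, source = file)
}

#' Export a mode displacement field as AXSF
#'
#' Writes an animated-XSF file (one animation step) with Cartesian atom
#' positions and the mode's displacement vectors in the force columns, for
#' arrow rendering in external structure viewers.
#'
#' @param structure A [crystal_structure()].
#' @param modes A [mode_set()] over the same atoms.
#' @param mode_index Which mode to export.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_axsf <- function(structure, modes, mode_index, file) {
  stopifnot(is_crystal_structure(structure), is_mode_set(modes))
  if (modes$n_atoms != n_atoms(structure)) {
    stop("mode set covers ", modes$n_atoms, " atoms but structure has ",
         n_atoms(structure), call. = FALSE)
  }
  at <- structure$atoms
  cart <- as.matrix(at[, c("x", "y", "z")]) %*% structure$lattice$matrix
  d <- modes$displacements[[mode_index]]
  out <- c(
    "ANIMSTEPS 1",
    "CRYSTAL",
    "PRIMVEC",
    apply(structure$lattice$matrix, 1,
          function(v) sprintf(" %14.8f %14.8f %14.8f", v[1], v[2], v[3])),
    "PRIMCOORD 1",
    sprintf("%d 1", nrow(at)),
    sprintf(" %-2s %14.8f %14.8f %14.8f %14.8f %14.8f %14.8f",
            at$element, cart[, 1], cart[, 2], cart[, 3],
            d[, 1], d[, 2], d[, 3])
  )
  writeLines(out, file)
  invisible(file)
}
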