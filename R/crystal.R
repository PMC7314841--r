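#' Crystal structure container
#'
#' A lattice plus an ordered table of atomic sites in fractional
#' coordinates. Site order is stable and is the order that mode files
#' index. Fractional coordinates are wrapped into [0, 1) on construction;
#' unwrapping into connected molecules happens only in
#' [partition_molecules()].
#'
#' @param lat A [lattice()].
#' @param atoms Data frame with columns `element`, `x`, `y`, `z`
#'   (fractional) and optionally `label`; a `mass` column is filled from
#'   the bundled element table when absent.
#' @param symmetry Optional character vector of symmetry operator strings
#'   (e.g. `"-x,y+1/2,-z+1/2"`); kept verbatim, expanded by
#'   [expand_symmetry()].
#' @return An object of class `crystal_structure`.
#' @export
crystal_structure <- function(lat, atoms, symmetry = character()) {
  stopifnot(is_lattice(lat))
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  atoms$element <- normalize_element(atoms$element)
  if (!"label" %in% names(atoms)) {
    atoms$label <- paste0(atoms$element, seq_len(nrow(atoms)))
  }
  if (!"mass" %in% names(atoms)) atoms$mass <- atomic_mass(atoms$element)
  if (any(atoms$mass <= 0)) stop("atomic masses must be positive", call. = FALSE)
  for (col in c("x", "y", "z")) atoms[[col]] <- atoms[[col]] %% 1
  structure(
    list(lattice = lat,
         atoms = atoms[, c("label", "element", "x", "y", "z", "mass")],
         symmetry = symmetry),
    class = "crystal_structure"
  )
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("<crystal_structure> %d sites, %d symmetry operator(s)\n",
              nrow(x$atoms), length(x$symmetry)))
  print(x$lattice)
  print(utils::head(x$atoms, 8))
  if (nrow(x$atoms) > 8) cat("...\n")
  invisible(x)
}

is_crystal_structure <- function(x) inherits(x, "crystal_structure")

#' Number of atomic sites
#' @param structure A [crystal_structure()].
#' @return Integer site count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

# Parse one symmetry operator string like "-x,y+1/2,-z+1/2" into a 3x3
# rotation matrix and length-3 translation (fractional).
parse_symop <- function(op) {
  comps <- strsplit(gsub("[[:space:]]", "", op), ",", fixed = TRUE)[[1]]
  if (length(comps) != 3) {
    stop("unparsable symmetry operator: '", op, "'", call. = FALSE)
  }
  rot <- matrix(0, 3, 3)
  trans <- numeric(3)
  for (i in 1:3) {
    terms <- regmatches(
      comps[i],
      gregexpr("[+-]?([0-9]+/[0-9]+|[0-9]*\\.?[0-9]+|[xyzXYZ])", comps[i])
    )[[1]]
    if (length(terms) == 0 ||
        nchar(paste(terms, collapse = "")) != nchar(comps[i])) {
      stop("unparsable symmetry operator component: '", comps[i],
           "' in '", op, "'", call. = FALSE)
    }
    for (term in terms) {
      sign <- if (startsWith(term, "-")) -1 else 1
      body <- sub("^[+-]", "", term)
      if (tolower(body) %in% c("x", "y", "z")) {
        j <- match(tolower(body), c("x", "y", "z"))
        rot[i, j] <- rot[i, j] + sign
      } else if (grepl("/", body)) {
        nd <- as.numeric(strsplit(body, "/", fixed = TRUE)[[1]])
        trans[i] <- trans[i] + sign * nd[1] / nd[2]
      } else {
        trans[i] <- trans[i] + sign * as.numeric(body)
      }
    }
  }
  list(rot = rot, trans = trans)
}

#' Expand symmetry operators into a P1 structure
#'
#' Applies every stored operator string to every site, wraps the images into
#' the unit cell and merges duplicates closer than `merge_tol` Angstrom
#' (minimum-image Cartesian distance). The identity operator need not be
#' listed; it is always applied first so the original site order is
#' preserved as a prefix.
#'
#' @param structure A [crystal_structure()].
#' @param merge_tol Duplicate-merging distance in Angstrom (default 0.1).
#' @return A `crystal_structure` with symmetry cleared and sites expanded.
#' @export
expand_symmetry <- function(structure, merge_tol = 0.1) {
  stopifnot(is_crystal_structure(structure))
  ops <- lapply(structure$symmetry, parse_symop)
  ident <- list(rot = diag(3), trans = numeric(3))
  is_ident <- vapply(ops, function(o) {
    all(o$rot == diag(3)) && all(abs(o$trans %% 1) < 1e-9)
  }, logical(1))
  ops <- c(list(ident), ops[!is_ident])

  at <- structure$atoms
  frac <- as.matrix(at[, c("x", "y", "z")])
  out <- list()
  for (op in ops) {
    img <- sweep(frac %*% t(op$rot), 2, op$trans, "+") %% 1
    new <- at
    new$x <- img[, 1]; new$y <- img[, 2]; new$z <- img[, 3]
    out[[length(out) + 1]] <- new
  }
  allat <- dplyr::bind_rows(out)

  # merge duplicates: keep the first occurrence in order
  fr <- as.matrix(allat[, c("x", "y", "z")])
  keep <- rep(TRUE, nrow(fr))
  for (i in seq_len(nrow(fr))) {
    if (!keep[i]) next
    if (i == nrow(fr)) break
    d <- mic_distance(structure$lattice, fr[i, ], fr[(i + 1):nrow(fr), , drop = FALSE])
    dup <- which(d < merge_tol) + i
    keep[dup] <- FALSE
  }
  crystal_structure(structure$lattice, allat[keep, ], symmetry = character())
}

# Minimum-image Cartesian distance between fractional point p (3-vector)
# and rows of fractional matrix q, scanning the 27 neighbour images so the
# result is correct for skewed cells.
mic_distance <- function(lat, p, q) {
  q <- rbind(q)
  df <- sweep(q, 2, p)
  df <- df - round(df)
  shifts <- as.matrix(expand.grid(s1 = -1:1, s2 = -1:1, s3 = -1:1))
  best <- rep(Inf, nrow(df))
  for (k in seq_len(nrow(shifts))) {
    cart <- sweep(df, 2, shifts[k, ], "+") %*% lat$matrix
    best <- pmin(best, sqrt(rowSums(cart^2)))
  }
  best
}

# Minimum-image fractional shift: integer vector n minimizing the Cartesian
# length of (q - p + n); returns list(shift, dist, cart).
mic_shift <- function(lat, p, q) {
  df <- q - p
  base <- -round(df)
  shifts <- as.matrix(expand.grid(s1 = -1:1, s2 = -1:1, s3 = -1:1))
  best_d <- Inf; best_s <- c(0, 0, 0)
  for (k in seq_len(nrow(shifts))) {
    s <- base + shifts[k, ]
    cart <- drop((df + s) %*% lat$matrix)
    d <- sqrt(sum(cart^2))
    if (d < best_d) { best_d <- d; best_s <- s }
  }
  list(shift = best_s, dist = best_d)
}
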