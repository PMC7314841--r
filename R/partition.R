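#' Partition a crystal into covalently bonded molecules
#'
#' Two atoms are bonded when their minimum-image distance does not exceed
#' `bond_scale` times the sum of their covalent radii. Hydrogen is capped at
#' a single covalent bond (to its nearest heavy neighbour within the cutoff)
#' so hydrogen bonds never merge molecules. Molecules are the connected
#' components of the bond graph; each component is unwrapped into one
#' periodic image so no intra-molecular bond spans more than half a cell
#' vector.
#'
#' Species tags are assigned from the molecular formula: `"water"` for H2O,
#' `"host"` otherwise.
#'
#' @param structure A [crystal_structure()].
#' @param bond_scale Dimensionless multiplier on the covalent-radius sum
#'   (default 1.2).
#' @return An object of class `molecule_partition`: list with `molecules`
#'   (each holding `indices`, `species`, `formula`, `coords` — unwrapped
#'   Cartesian O x 3 matrix in Angstrom — and `masses`), the bond table, and
#'   a `summary` tibble (one row per molecule).
#' @export
partition_molecules <- function(structure, bond_scale = 1.2) {
  stopifnot(is_crystal_structure(structure), bond_scale > 0)
  at <- structure$atoms
  n <- nrow(at)
  frac <- as.matrix(at[, c("x", "y", "z")])
  rcov <- covalent_radius(at$element)
  lat <- structure$lattice

  # candidate bonds from minimum-image distances
  bonds <- list()
  for (i in seq_len(n - 1L)) {
    d <- mic_distance(lat, frac[i, ], frac[(i + 1L):n, , drop = FALSE])
    cut <- bond_scale * (rcov[i] + rcov[(i + 1L):n])
    hits <- which(d <= cut)
    for (h in hits) {
      bonds[[length(bonds) + 1L]] <- c(i, i + h, d[h])
    }
  }
  if (length(bonds)) {
    bm <- do.call(rbind, bonds)
    bond_tbl <- tibble::tibble(i = as.integer(bm[, 1]), j = as.integer(bm[, 2]),
                               dist = bm[, 3])
  } else {
    bond_tbl <- tibble::tibble(i = integer(), j = integer(), dist = numeric())
  }

  # hydrogen cap: keep only the shortest bond to a heavy atom for each H
  is_h <- at$element %in% c("H", "D")
  keep <- rep(TRUE, nrow(bond_tbl))
  for (a in which(is_h)) {
    rows <- which(bond_tbl$i == a | bond_tbl$j == a)
    if (length(rows) <= 1) next
    partner <- ifelse(bond_tbl$i[rows] == a, bond_tbl$j[rows], bond_tbl$i[rows])
    heavy <- !is_h[partner]
    cand <- if (any(heavy)) rows[heavy] else rows
    best <- cand[which.min(bond_tbl$dist[cand])]
    keep[setdiff(rows, best)] <- FALSE
  }
  bond_tbl <- bond_tbl[keep, ]

  g <- igraph::graph_from_data_frame(
    data.frame(from = bond_tbl$i, to = bond_tbl$j),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  comp <- unname(igraph::components(g)$membership)

  molecules <- list()
  for (cid in sort(unique(comp))) {
    idx <- which(comp == cid)
    shift <- unwrap_component(lat, frac, bond_tbl, idx)
    coords <- (frac[idx, , drop = FALSE] + shift) %*% lat$matrix
    rownames(coords) <- NULL
    elems <- at$element[idx]
    molecules[[length(molecules) + 1L]] <- list(
      indices = idx,
      species = if (identical_formula(elems, c(H = 2, O = 1))) "water" else "host",
      formula = hill_formula(elems),
      coords = coords,
      masses = at$mass[idx]
    )
  }
  summary <- tibble::tibble(
    molecule = seq_along(molecules),
    species = vapply(molecules, `[[`, character(1), "species"),
    formula = vapply(molecules, `[[`, character(1), "formula"),
    n_atoms = vapply(molecules, function(m) length(m$indices), integer(1)),
    mass = vapply(molecules, function(m) sum(m$masses), numeric(1))
  )
  structure(list(structure = structure, molecules = molecules,
                 bonds = bond_tbl, summary = summary),
            class = "molecule_partition")
}

#' @export
print.molecule_partition <- function(x, ...) {
  cat(sprintf("<molecule_partition> %d molecule(s)\n", length(x$molecules)))
  print(x$summary)
  invisible(x)
}

is_molecule_partition <- function(x) inherits(x, "molecule_partition")

# BFS over the intra-component bonds assigning each atom a lattice image
# shift; an atom reachable with two inconsistent shifts means the component
# wraps around the cell (percolating network) and cannot be unwrapped.
unwrap_component <- function(lat, frac, bond_tbl, idx) {
  m <- length(idx)
  pos <- match(seq_len(nrow(frac)), idx)  # global -> local index or NA
  adj <- vector("list", m)
  in_comp <- bond_tbl$i %in% idx & bond_tbl$j %in% idx
  for (r in which(in_comp)) {
    li <- pos[bond_tbl$i[r]]; lj <- pos[bond_tbl$j[r]]
    adj[[li]] <- c(adj[[li]], lj)
    adj[[lj]] <- c(adj[[lj]], li)
  }
  shift <- matrix(NA_real_, m, 3)
  shift[1, ] <- 0
  queue <- 1L
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) {
      # image shift placing v nearest the already-placed parent u
      s <- mic_shift(lat,
                     frac[idx[u], ] + shift[u, ],
                     frac[idx[v], ])$shift
      if (any(is.na(shift[v, ]))) {
        shift[v, ] <- s
        queue <- c(queue, v)
      } else if (any(abs(shift[v, ] - s) > 1e-9)) {
        stop("cannot unwrap molecule: bonded network percolates through the cell",
             call. = FALSE)
      }
    }
  }
  if (anyNA(shift)) stop("internal error: disconnected component", call. = FALSE)
  shift
}

hill_formula <- function(elements) {
  cnt <- table(elements)
  ord <- c(intersect(c("C", "H"), names(cnt)),
           sort(setdiff(names(cnt), c("C", "H"))))
  paste0(ord, ifelse(cnt[ord] > 1, cnt[ord], ""), collapse = "")
}

identical_formula <- function(elements, target) {
  cnt <- table(elements)
  length(cnt) == length(target) &&
    all(sort(names(cnt)) == sort(names(target))) &&
    all(cnt[names(target)] == target)
}
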