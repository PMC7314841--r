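#' Find hydrogen bonds in a crystal
#'
#' Enumerates donor-hydrogen...acceptor triples: H covalently bonded to a
#' donor in `elements`, acceptor in `elements` with minimum-image H...A
#' distance at most `max_ha` Angstrom and D-H...A angle at least
#' `min_angle` degrees, where H and A belong to different molecules or to
#' different periodic images of the same molecule. Results are sorted by
#' H...A distance.
#'
#' The geometric criterion is a conventional one (distance + angle cutoff
#' over N/O donors and acceptors); crystallographic reports typically list
#' only the distances, so the thresholds are exposed as arguments.
#'
#' @param structure A [crystal_structure()].
#' @param partition Optional [partition_molecules()] result; computed when
#'   missing.
#' @param max_ha Maximum H...A distance in Angstrom (default 2.5).
#' @param min_angle Minimum D-H...A angle in degrees (default 120).
#' @param elements Allowed donor/acceptor elements (default N and O).
#' @return A tibble with one row per bond: donor/hydrogen/acceptor labels
#'   and indices, `distance_ha` (Angstrom), `angle_dha` (degrees), and the
#'   acceptor periodic image shift columns `shift_a`, `shift_b`, `shift_c`.
#' @export
find_hydrogen_bonds <- function(structure, partition = NULL,
                                max_ha = 2.5, min_angle = 120,
                                elements = c("N", "O")) {
  stopifnot(is_crystal_structure(structure))
  if (is.null(partition)) partition <- partition_molecules(structure)
  at <- structure$atoms
  lat <- structure$lattice
  frac <- as.matrix(at[, c("x", "y", "z")])

  empty <- tibble::tibble(
    donor = character(), hydrogen = character(), acceptor = character(),
    donor_idx = integer(), hydrogen_idx = integer(), acceptor_idx = integer(),
    distance_ha = numeric(), angle_dha = numeric(),
    shift_a = integer(), shift_b = integer(), shift_c = integer()
  )
  h_idx <- which(at$element %in% c("H", "D"))
  if (length(h_idx) == 0) {
    warning("structure contains no hydrogen atoms; no hydrogen bonds searched")
    return(empty)
  }

  mol_of <- integer(nrow(at))
  for (k in seq_along(partition$molecules)) {
    mol_of[partition$molecules[[k]]$indices] <- k
  }
  # covalent partner of each hydrogen from the bond table
  bt <- partition$bonds
  rows <- list()
  shifts <- as.matrix(expand.grid(sa = -1:1, sb = -1:1, sc = -1:1))
  acc_idx <- which(at$element %in% elements)
  for (h in h_idx) {
    prow <- which(bt$i == h | bt$j == h)
    if (length(prow) == 0) next
    d_idx <- ifelse(bt$i[prow[1]] == h, bt$j[prow[1]], bt$i[prow[1]])
    if (!(at$element[d_idx] %in% elements)) next
    # place D and H in the unwrapped frame of their molecule
    sh_h <- mic_shift(lat, frac[d_idx, ], frac[h, ])$shift
    d_cart <- drop(frac[d_idx, , drop = FALSE] %*% lat$matrix)
    h_cart <- drop((frac[h, ] + sh_h) %*% lat$matrix)
    for (a in acc_idx) {
      if (a == d_idx) next
      for (k in seq_len(nrow(shifts))) {
        a_cart <- drop((frac[a, ] + shifts[k, ]) %*% lat$matrix)
        v_ha <- a_cart - h_cart
        dist <- sqrt(sum(v_ha^2))
        if (dist < 1e-6 || dist > max_ha) next
        # same molecule, same image -> intramolecular contact, skip;
        # detected by comparing against the unwrapped intra-molecular vector
        if (mol_of[a] == mol_of[h]) {
          mol <- partition$molecules[[mol_of[h]]]
          intra <- mol$coords[match(a, mol$indices), ] -
            mol$coords[match(h, mol$indices), ]
          if (sqrt(sum((v_ha - intra)^2)) < 1e-6) next
        }
        v_hd <- d_cart - h_cart
        cosang <- sum(v_hd * v_ha) / (sqrt(sum(v_hd^2)) * dist)
        ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        if (ang < min_angle) next
        rows[[length(rows) + 1L]] <- tibble::tibble(
          donor = at$label[d_idx], hydrogen = at$label[h],
          acceptor = at$label[a],
          donor_idx = d_idx, hydrogen_idx = h, acceptor_idx = a,
          distance_ha = dist, angle_dha = ang,
          shift_a = as.integer(shifts[k, 1]),
          shift_b = as.integer(shifts[k, 2]),
          shift_c = as.integer(shifts[k, 3])
        )
      }
    }
  }
  if (length(rows) == 0) return(empty)
  dplyr::arrange(dplyr::bind_rows(rows), .data$distance_ha)
}
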