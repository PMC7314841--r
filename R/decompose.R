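#' Center-of-mass displacement of a molecule under a mode
#'
#' The mass-weighted mean displacement \eqn{(\sum_i m_i \delta_i)/\sum_i m_i}
#' of a molecule's atoms. Its three components, taken along the
#' crystallographic Cartesian axes, define the three intermolecular
#' translation fields: each is applied uniformly to every atom of the
#' molecule.
#'
#' @param group One molecule from [partition_molecules()] (`$molecules[[k]]`).
#' @param disp Displacement matrix of the full structure (n_atoms x 3) or of
#'   the group alone (O x 3).
#' @return Length-3 numeric vector (same units as `disp`).
#' @export
com_displacement <- function(group, disp) {
  d <- group_disp(group, disp)
  m <- group$masses
  if (sum(m) <= 0) stop("zero total mass", call. = FALSE)
  drop(crossprod(d, m) / sum(m))
}

group_disp <- function(group, disp) {
  stopifnot(is.matrix(disp), ncol(disp) == 3)
  if (nrow(disp) == length(group$indices)) return(disp)
  disp[group$indices, , drop = FALSE]
}

#' Rigid-body (principal-axis) frame of a molecule
#'
#' Center of mass, inertia tensor about it from point masses, and its
#' eigendecomposition. Principal moments are ordered descending
#' (I1 >= I2 >= I3); the sign of each of the first two axes is fixed so its
#' largest-magnitude component is positive, degenerate moments are
#' tie-broken by lexicographic comparison of axis components, and the third
#' axis is the cross product of the first two so the frame is always
#' right-handed.
#'
#' @param group One molecule from [partition_molecules()].
#' @param weights Optional per-atom weights for the moment computation;
#'   defaults to the atomic masses (the conventional inertia tensor).
#' @return Object of class `rigid_body_frame`: `com` (Angstrom), `inertia`
#'   (amu A^2), `moments` (descending), `axes` (3x3, columns = principal
#'   axes in the crystallographic Cartesian frame).
#' @export
rigid_body_frame <- function(group, weights = NULL) {
  r <- group$coords
  w <- if (is.null(weights)) group$masses else weights
  stopifnot(length(w) == nrow(r), all(w > 0))
  com <- drop(crossprod(r, w) / sum(w))
  s <- sweep(r, 2, com)
  inertia <- matrix(0, 3, 3)
  for (i in seq_len(nrow(s))) {
    si <- s[i, ]
    inertia <- inertia + w[i] * (sum(si^2) * diag(3) - tcrossprod(si))
  }
  e <- eigen(inertia, symmetric = TRUE)  # values decreasing
  vals <- e$values
  vecs <- e$vectors
  # deterministic signs: largest |component| positive
  fix_signs <- function(v) {
    for (k in 1:2) {
      j <- which.max(abs(v[, k]))
      if (v[j, k] < 0) v[, k] <- -v[, k]
    }
    v
  }
  vecs <- fix_signs(vecs)
  # lexicographic tie-break within degenerate pairs
  for (k in 1:2) {
    if (abs(vals[k] - vals[k + 1]) < 1e-12 * max(vals[1], 1)) {
      a <- vecs[, k]; b <- vecs[, k + 1]
      cmp <- sign(a - b); first <- cmp[cmp != 0][1]
      if (!is.na(first) && first < 0) {
        vecs[, c(k, k + 1)] <- vecs[, c(k + 1, k)]
        vals[c(k, k + 1)] <- vals[c(k + 1, k)]
      }
    }
  }
  vecs <- fix_signs(vecs)
  vecs[, 3] <- c(vecs[2, 1] * vecs[3, 2] - vecs[3, 1] * vecs[2, 2],
                 vecs[3, 1] * vecs[1, 2] - vecs[1, 1] * vecs[3, 2],
                 vecs[1, 1] * vecs[2, 2] - vecs[2, 1] * vecs[1, 2])
  structure(list(com = com, inertia = inertia, moments = vals, axes = vecs),
            class = "rigid_body_frame")
}

#' @export
print.rigid_body_frame <- function(x, ...) {
  cat(sprintf("<rigid_body_frame> moments (amu A^2): %.4g %.4g %.4g\n",
              x$moments[1], x$moments[2], x$moments[3]))
  invisible(x)
}

#' Libration angles of a molecule under a mode
#'
#' In the principal frame, the small-angle libration about principal axis k
#' is \eqn{\theta_k = [\sum_i m_i (r_i \times \delta_i)]_k / I_k}: the
#' mass-weighted angular momentum-like sum divided by the principal moment.
#' Positions are taken relative to the center of mass and the translational
#' (center-of-mass) displacement is removed first, so a pure translation
#' yields exactly zero angles and a rigid infinitesimal rotation is
#' recovered exactly. Principal moments below `eps` times the largest
#' moment (near-linear or single-atom molecules) give a zero angle.
#'
#' @param group One molecule from [partition_molecules()].
#' @param disp Displacement matrix (full structure or group rows).
#' @param frame A [rigid_body_frame()] for the group; computed when NULL.
#' @param mass_weighted Use masses in the numerator (and in the frame). The
#'   unweighted variant divides the plain cross-product sum by unweighted
#'   moments.
#' @param eps Relative moment threshold below which an axis is treated as
#'   librationally inert (default 1e-8).
#' @return Length-3 numeric vector of angles (radians), principal-axis
#'   order.
#' @export
libration_angles <- function(group, disp, frame = NULL,
                             mass_weighted = TRUE, eps = 1e-8) {
  w <- if (mass_weighted) group$masses else rep(1, length(group$masses))
  if (is.null(frame)) frame <- rigid_body_frame(group, weights = w)
  d <- group_disp(group, disp)
  if (nrow(group$coords) == 1) return(c(0, 0, 0))
  # remove the w-weighted mean displacement (translation part)
  d <- sweep(d, 2, drop(crossprod(d, w) / sum(w)))
  s <- sweep(group$coords, 2, frame$com)
  # rotate rows into the principal frame
  sp <- s %*% frame$axes
  dp <- d %*% frame$axes
  cr <- cbind(sp[, 2] * dp[, 3] - sp[, 3] * dp[, 2],
              sp[, 3] * dp[, 1] - sp[, 1] * dp[, 3],
              sp[, 1] * dp[, 2] - sp[, 2] * dp[, 1])
  num <- drop(crossprod(cr, w))
  theta <- numeric(3)
  ok <- frame$moments > eps * max(frame$moments)
  theta[ok] <- num[ok] / frame$moments[ok]
  theta
}

rodrigues_axis <- function(k, theta) {
  u <- c(0, 0, 0); u[k] <- 1
  ct <- cos(theta); st <- sin(theta)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  ct * diag(3) + st * ux + (1 - ct) * tcrossprod(u)
}

#' Librational displacement fields from finite rotations
#'
#' For each principal axis k the librational field is the finite-rotation
#' difference \eqn{R_k(\theta_k) r_i - r_i} evaluated in the principal
#' frame, then rotated back into the crystallographic Cartesian frame.
#'
#' @param group One molecule from [partition_molecules()].
#' @param frame A [rigid_body_frame()].
#' @param theta Length-3 libration angles (radians), principal-axis order.
#' @return List of three O x 3 matrices (crystallographic frame), one per
#'   principal axis.
#' @export
libration_displacements <- function(group, frame, theta) {
  s <- sweep(group$coords, 2, frame$com)
  sp <- s %*% frame$axes
  lapply(1:3, function(k) {
    fp <- sp %*% t(rodrigues_axis(k, theta[k])) - sp
    fp %*% t(frame$axes)
  })
}

# Bijective assignment of principal axes to crystal axes: the permutation
# maximizing the total squared projection, lexicographic tie-break.
axis_assignment <- function(axes) {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  score <- apply(perms, 1, function(p) sum(axes[cbind(p, 1:3)]^2))
  perms[which.max(score), ]  # crystal axis index for principal axes 1..3
}

#' Decompose one molecule's mode displacements
#'
#' Orchestrates the full per-molecule separation: center-of-mass
#' translation along each crystallographic axis, finite-rotation libration
#' about each principal axis (re-expressed in the crystallographic frame),
#' and the intramolecular residual defined by exact subtraction, so
#' translations + librations + intramolecular always reconstruct the input
#' field to machine precision.
#'
#' Librations are attributed to crystallographic axes X/Y/Z through a
#' bijective principal-to-crystal axis assignment (the permutation with the
#' largest total squared projection); set `principal_axes = TRUE` to keep
#' them keyed by principal axis instead.
#'
#' @param group One molecule from [partition_molecules()].
#' @param disp Displacement matrix (full structure or group rows).
#' @param mass_weighted Mass-weight the libration numerator and frame
#'   (default TRUE; see [libration_angles()]).
#' @param principal_axes Report librations in principal axes rather than
#'   crystal axes.
#' @return Object of class `decomposed_displacements`: `trans` (list X/Y/Z
#'   of O x 3 constant fields), `lib` (list of three O x 3 fields, named
#'   X/Y/Z or P1/P2/P3), `intra` (O x 3), `theta` (radians), `com_disp`,
#'   `frame`, `axis_map`, `masses` and the original field `total`.
#' @export
decompose_displacements <- function(group, disp, mass_weighted = TRUE,
                                    principal_axes = FALSE) {
  d <- group_disp(group, disp)
  w <- if (mass_weighted) group$masses else rep(1, length(group$masses))
  t_com <- com_displacement(group, d)
  O <- nrow(d)
  trans <- lapply(1:3, function(v) {
    f <- matrix(0, O, 3); f[, v] <- t_com[v]; f
  })
  names(trans) <- c("X", "Y", "Z")
  frame <- rigid_body_frame(group, weights = w)
  theta <- libration_angles(group, d, frame, mass_weighted = mass_weighted)
  lib_p <- libration_displacements(group, frame, theta)
  if (principal_axes) {
    lib <- lib_p
    names(lib) <- c("P1", "P2", "P3")
    axis_map <- 1:3
  } else {
    axis_map <- axis_assignment(frame$axes)
    lib <- vector("list", 3)
    names(lib) <- c("X", "Y", "Z")
    for (k in 1:3) lib[[axis_map[k]]] <- lib_p[[k]]
  }
  intra <- d - Reduce(`+`, trans) - Reduce(`+`, lib_p)
  structure(
    list(trans = trans, lib = lib, intra = intra, theta = theta,
         com_disp = t_com, frame = frame, axis_map = axis_map,
         masses = group$masses, total = d),
    class = "decomposed_displacements"
  )
}

#' @export
print.decomposed_displacements <- function(x, ...) {
  cat(sprintf(
    "<decomposed_displacements> O=%d  |t|=%.3g  theta=(%.3g, %.3g, %.3g) rad\n",
    nrow(x$intra), sqrt(sum(x$com_disp^2)),
    x$theta[1], x$theta[2], x$theta[3]))
  invisible(x)
}

mw_rms <- function(field, masses) {
  sqrt(sum(masses * rowSums(field^2)) / length(masses))
}

#' Percentage contributions of the seven mode components
#'
#' For each component c (translations along X/Y/Z, librations about X/Y/Z,
#' intramolecular) the mass-weighted RMS displacement is
#' \eqn{s_c = \sqrt{(1/O)\sum_i m_i \|\delta_{i,c}\|^2}} and its percentage
#' contribution is \eqn{P_c = 100\, s_c / \sum_{c'} s_{c'}}, the denominator
#' summing all seven RMS terms. The percentages are invariant to a common
#' rescaling of the displacement field or of the masses.
#'
#' @param decomp A [decompose_displacements()] result.
#' @param masses Optional masses (default: those stored in `decomp`).
#' @return One-row tibble with columns `p_trans_x/y/z`, `p_lib_x/y/z` (or
#'   `p_lib_p1/p2/p3` for principal-axis output), `p_intra`; values sum
#'   to 100.
#' @export
percentage_contributions <- function(decomp, masses = NULL) {
  stopifnot(inherits(decomp, "decomposed_displacements"))
  m <- if (is.null(masses)) decomp$masses else masses
  s <- c(vapply(decomp$trans, mw_rms, numeric(1), masses = m),
         vapply(decomp$lib, mw_rms, numeric(1), masses = m),
         intra = mw_rms(decomp$intra, m))
  if (sum(s) <= 0) {
    stop("all-zero decomposition: percentages are undefined", call. = FALSE)
  }
  p <- 100 * s / sum(s)
  lib_names <- if (identical(names(decomp$lib), c("P1", "P2", "P3"))) {
    c("p_lib_p1", "p_lib_p2", "p_lib_p3")
  } else {
    c("p_lib_x", "p_lib_y", "p_lib_z")
  }
  out <- as.list(p)
  names(out) <- c("p_trans_x", "p_trans_y", "p_trans_z", lib_names, "p_intra")
  tibble::as_tibble(out)
}

#' Mode-character table for a whole mode set
#'
#' Runs the per-molecule decomposition for every (mode, molecule) pair and
#' returns the percentage contributions as a tidy table, carrying the mode
#' frequency and IR intensity along.
#'
#' @param structure A [crystal_structure()].
#' @param modes A [mode_set()] indexed in the structure's atom order.
#' @param partition Optional [partition_molecules()] result.
#' @param mass_weighted,principal_axes Passed to
#'   [decompose_displacements()].
#' @return A tibble with one row per (mode, molecule): `mode`,
#'   `frequency_thz`, `ir_intensity`, `molecule`, `species`, and the seven
#'   percentage columns.
#' @export
#' @examples
#' xtal <- make_toy_crystal(toy_crystal_spec(seed = 1))
#' part <- partition_molecules(xtal)
#' mode <- make_mode_field(part, mixture_spec(seed = 1))
#' mode_character(xtal, mode, part)
mode_character <- function(structure, modes, partition = NULL,
                           mass_weighted = TRUE, principal_axes = FALSE) {
  stopifnot(is_crystal_structure(structure), is_mode_set(modes))
  if (modes$n_atoms != n_atoms(structure)) {
    stop("mode set covers ", modes$n_atoms, " atoms but structure has ",
         n_atoms(structure), call. = FALSE)
  }
  if (is.null(partition)) partition <- partition_molecules(structure)
  rows <- list()
  for (k in seq_along(modes$frequency_thz)) {
    d <- modes$displacements[[k]]
    for (j in seq_along(partition$molecules)) {
      g <- partition$molecules[[j]]
      dec <- decompose_displacements(g, d, mass_weighted = mass_weighted,
                                     principal_axes = principal_axes)
      pc <- percentage_contributions(dec)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(mode = k,
                       frequency_thz = modes$frequency_thz[k],
                       ir_intensity = modes$ir_intensity[k],
                       molecule = j, species = g$species),
        pc
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Species-averaged mode character over the unit cell
#'
#' Arithmetic mean of each molecule's percentage contributions within each
#' species tag (host molecules and water molecules averaged separately),
#' per mode. Averaging percentages (not pooled displacements) keeps every
#' row summing to 100.
#'
#' @param characters A [mode_character()] table.
#' @return A tibble with one row per (mode, species): frequency, intensity,
#'   `n_molecules` and the averaged percentage columns.
#' @export
summarize_unit_cell <- function(characters) {
  pcols <- grep("^p_", names(characters), value = TRUE)
  empty_species <- setdiff(unique(characters$species),
                           unique(characters$species[!is.na(characters$species)]))
  if (length(empty_species)) {
    warning("omitting empty species group(s): ",
            paste(empty_species, collapse = ", "))
  }
  characters |>
    dplyr::group_by(.data$mode, .data$frequency_thz, .data$ir_intensity,
                    .data$species) |>
    dplyr::summarise(n_molecules = dplyr::n(),
                     dplyr::across(dplyr::all_of(pcols), mean),
                     .groups = "drop")
}
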