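#' Specification for a toy hydrate crystal
#'
#' Describes a synthetic molecular crystal emulating the cell contents of a
#' small-molecule monohydrate: a rigid planar heterocyclic host (13 atoms,
#' C4H5N3O) plus water, four of each per cell by default. The default cell
#' is roomier than a real close-packed hydrate so that randomly oriented
#' molecules never clash; the generator emulates cell *contents* and
#' connectivity, not a realistic packing density.
#'
#' @param n_host,n_water Molecules per cell (defaults 4 + 4).
#' @param lat Cell as a [lattice()] (default monoclinic 12 x 14 x 12 A,
#'   beta = 99.5 deg).
#' @param jitter Gaussian placement jitter on molecular centers, Angstrom
#'   (default 0.15).
#' @param seed Integer random seed; generation is bit-reproducible.
#' @return A list of class `toy_crystal_spec`.
#' @export
toy_crystal_spec <- function(n_host = 4, n_water = 4,
                             lat = lattice(12, 14, 12, 90, 99.5, 90),
                             jitter = 0.15, seed = 1) {
  stopifnot(n_host >= 0, n_water >= 0, n_host + n_water >= 1,
            is_lattice(lat), jitter >= 0)
  structure(list(n_host = n_host, n_water = n_water, lat = lat,
                 jitter = jitter, seed = as.integer(seed)),
            class = "toy_crystal_spec")
}

# Idealized planar heterocycle, C4H5N3O (13 atoms): six-membered ring with
# a carbonyl O, an exocyclic amino group and ring hydrogens, all in the
# xy-plane. A generic rigid host body, not any specific compound geometry.
host_template <- function() {
  ring_r <- 1.39
  ang <- (c(90, 150, 210, 270, 330, 30)) * pi / 180
  ring_el <- c("N", "C", "N", "C", "C", "C")  # N1 C2 N3 C4 C5 C6
  ring <- cbind(ring_r * cos(ang), ring_r * sin(ang), 0)
  radial <- function(i, d) {
    u <- ring[i, 1:2] / sqrt(sum(ring[i, 1:2]^2))
    c(ring[i, 1:2] + d * u, 0)
  }
  amino_n <- radial(4, 1.35)
  amino_dir <- amino_n[1:2] / sqrt(sum(amino_n[1:2]^2))
  rot2 <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                           sin(a) * v[1] + cos(a) * v[2])
  coords <- rbind(
    ring,
    radial(2, 1.22),                       # carbonyl O on C2
    amino_n,                               # amino N on C4
    c(amino_n[1:2] + 1.01 * rot2(amino_dir,  pi / 3), 0),
    c(amino_n[1:2] + 1.01 * rot2(amino_dir, -pi / 3), 0),
    radial(1, 1.01),                       # H on N1
    radial(5, 1.08),                       # H on C5
    radial(6, 1.08)                        # H on C6
  )
  list(elements = c(ring_el, "O", "N", "H", "H", "H", "H", "H"),
       coords = coords)
}

water_template <- function() {
  a <- 104.5 / 2 * pi / 180
  list(elements = c("O", "H", "H"),
       coords = rbind(c(0, 0, 0),
                      c(0.9572 * sin(a),  0.9572 * cos(a), 0),
                      c(-0.9572 * sin(a), 0.9572 * cos(a), 0)))
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a toy molecular/hydrate crystal
#'
#' Places the requested numbers of rigid host and water molecules at
#' well-separated cell positions with seeded random orientations and
#' center jitter, retrying (bounded) until no interatomic contact is closer
#' than 2.0 Angstrom between molecules, so [partition_molecules()] always
#' recovers exactly the requested molecule counts and species tags.
#' Fractional coordinates are wrapped on construction, so molecules near
#' cell faces deliberately straddle the periodic boundary.
#'
#' @param spec A [toy_crystal_spec()].
#' @return A [crystal_structure()].
#' @export
#' @examples
#' xtal <- make_toy_crystal(toy_crystal_spec(seed = 7))
#' partition_molecules(xtal)$summary
make_toy_crystal <- function(spec = toy_crystal_spec()) {
  stopifnot(inherits(spec, "toy_crystal_spec"))
  lat <- spec$lat
  host_centers <- rbind(c(0.25, 0.25, 0.25), c(0.75, 0.25, 0.75),
                        c(0.25, 0.75, 0.75), c(0.75, 0.75, 0.25),
                        c(0.25, 0.25, 0.75), c(0.75, 0.75, 0.75))
  water_centers <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0, 0.5, 0.5),
                         c(0.5, 0, 0.5), c(0.5, 0.5, 0.5), c(0, 0, 0.5))
  if (spec$n_host > nrow(host_centers) ||
      spec$n_water > nrow(water_centers)) {
    stop("at most ", nrow(host_centers), " host and ", nrow(water_centers),
         " water molecules per cell are supported", call. = FALSE)
  }
  host <- host_template(); water <- water_template()
  set.seed(spec$seed)
  for (attempt in 1:50) {
    rows <- list()
    mol_id <- integer()
    place <- function(tmpl, center_frac, id) {
      rot <- random_rotation()
      ctr <- frac_to_cart(lat, center_frac) + spec$jitter * stats::rnorm(3)
      cart <- tmpl$coords %*% t(rot)
      cart <- sweep(cart, 2, ctr, "+")
      frac <- cart_to_frac(lat, cart)
      tibble::tibble(element = tmpl$elements,
                     x = frac[, 1], y = frac[, 2], z = frac[, 3])
    }
    k <- 0
    for (i in seq_len(spec$n_host)) {
      k <- k + 1
      rows[[k]] <- place(host, host_centers[i, ], k)
    }
    for (i in seq_len(spec$n_water)) {
      k <- k + 1
      rows[[k]] <- place(water, water_centers[i, ], k)
    }
    atoms <- dplyr::bind_rows(rows)
    mol_id <- rep(seq_len(k), times = vapply(rows, nrow, integer(1)))
    frac <- as.matrix(atoms[, c("x", "y", "z")]) %% 1
    ok <- TRUE
    for (i in seq_len(nrow(frac) - 1)) {
      rest <- (i + 1):nrow(frac)
      inter <- mol_id[rest] != mol_id[i]
      if (!any(inter)) next
      d <- mic_distance(lat, frac[i, ], frac[rest[inter], , drop = FALSE])
      if (any(d < 2.0)) { ok <- FALSE; break }
    }
    if (ok) {
      atoms$label <- paste0(atoms$element, seq_len(nrow(atoms)))
      return(crystal_structure(lat, atoms))
    }
  }
  stop("could not place molecules without clashes after 50 attempts; ",
       "use a larger cell", call. = FALSE)
}

#' Specification of a synthetic mode-component mixture
#'
#' Target mass-weighted RMS fractions for the seven mode components, in the
#' order translations X/Y/Z, librations X/Y/Z, intramolecular. The default
#' mixture resembles the mixed inter/intramolecular character typical of
#' low-frequency modes of hydrogen-bonded organic crystals (librations and
#' translations each contributing tens of percent, a substantial
#' intramolecular remainder).
#'
#' @param fractions Length-7 nonnegative vector summing to 1.
#' @param lib_cap Maximum libration angle in radians (default and cap
#'   0.05, keeping finite-rotation nonlinearity negligible).
#' @param noise Relative additive noise level (0 = none).
#' @param seed Integer random seed.
#' @return A list of class `mixture_spec`.
#' @export
mixture_spec <- function(fractions = c(0.12, 0.12, 0.12, 0.10, 0.10, 0.10, 0.34),
                         lib_cap = 0.05, noise = 0, seed = 1) {
  stopifnot(length(fractions) == 7, all(fractions >= 0),
            abs(sum(fractions) - 1) <= 1e-9,
            lib_cap > 0, lib_cap <= 0.05, noise >= 0)
  structure(list(fractions = fractions, lib_cap = lib_cap,
                 noise = noise, seed = as.integer(seed)),
            class = "mixture_spec")
}

#' Generate a displacement field with prescribed component fractions
#'
#' Builds, per molecule, the seven component fields — rigid translations
#' along the crystallographic axes, finite-rotation librations about the
#' principal axes (attributed to crystal axes by the same bijective
#' assignment the decomposition uses), and an intramolecular field
#' Gram-Schmidt-orthogonalised (mass-weighted) against all six rigid-body
#' basis vectors — each scaled so its mass-weighted RMS realises exactly
#' the requested fraction. Optional isotropic Gaussian noise is added to
#' the summed field afterwards.
#'
#' @param partition A [partition_molecules()] result.
#' @param spec A [mixture_spec()].
#' @param frequency_thz,ir_intensity Metadata for the generated mode.
#' @return A single-mode [mode_set()] over the partition's structure, with
#'   the target fractions stored in `$provenance$target_fractions`.
#' @export
make_mode_field <- function(partition, spec = mixture_spec(),
                            frequency_thz = 1.5, ir_intensity = 1) {
  stopifnot(is_molecule_partition(partition), inherits(spec, "mixture_spec"))
  set.seed(spec$seed)
  n <- n_atoms(partition$structure)
  d <- matrix(0, n, 3)
  S <- 0.01  # arbitrary overall amplitude (amu^1/2 Angstrom units)
  f <- spec$fractions
  for (g in partition$molecules) {
    O <- nrow(g$coords)
    m <- g$masses
    if (O < 3 && f[7] > 0) {
      stop("molecule with ", O, " atom(s) cannot host an intramolecular ",
           "component; set the intramolecular fraction to 0", call. = FALSE)
    }
    field <- matrix(0, O, 3)
    # translations: constant field along each crystal axis
    for (v in 1:3) {
      if (f[v] == 0) next
      t_field <- matrix(0, O, 3)
      t_field[, v] <- 1
      field <- field + t_field * (f[v] * S / mw_rms(t_field, m))
    }
    # librations: finite rotations about principal axes, scaled by angle
    frame <- rigid_body_frame(g)
    amap <- axis_assignment(frame$axes)   # principal k -> crystal axis
    s <- sweep(g$coords, 2, frame$com)
    sp <- s %*% frame$axes
    for (k in 1:3) {
      target <- f[3 + amap[k]] * S
      if (target == 0) next
      if (frame$moments[k] < 1e-8 * max(frame$moments)) {
        stop("molecule has a vanishing principal moment; cannot realise a ",
             "libration about that axis", call. = FALSE)
      }
      lib_field_p <- function(theta) sp %*% t(rodrigues_axis(k, theta)) - sp
      gfun <- function(theta) mw_rms(lib_field_p(theta), m) - target
      if (gfun(spec$lib_cap) < 0) {
        stop("libration fraction unreachable within the angle cap; ",
             "reduce the fraction or the overall amplitude", call. = FALSE)
      }
      theta <- stats::uniroot(gfun, c(0, spec$lib_cap), tol = 1e-14)$root
      field <- field + lib_field_p(theta) %*% t(frame$axes)
    }
    # intramolecular: orthogonal complement of the rigid-body space
    if (f[7] > 0) {
      basis <- rigid_basis(sp, m)           # principal frame, mass-weighted
      raw <- matrix(stats::rnorm(3 * O), O, 3)
      intra <- gram_schmidt_residual(raw, basis, m)
      nrm <- mw_rms(intra, m)
      if (nrm < 1e-12) {
        stop("degenerate intramolecular draw; change the seed", call. = FALSE)
      }
      intra <- intra * (f[7] * S / nrm)
      field <- field + intra %*% t(frame$axes)
    }
    d[g$indices, ] <- field
  }
  if (spec$noise > 0) {
    sdn <- spec$noise * sqrt(mean(d^2) * 3)  # relative to per-atom RMS norm
    d <- d + matrix(stats::rnorm(length(d), sd = sdn / sqrt(3)), nrow(d), 3)
  }
  ms <- mode_set(frequency_thz, ir_intensity, list(d),
                 source = "make_mode_field")
  ms$provenance$target_fractions <- f
  ms$provenance$seed <- spec$seed
  ms
}

# six rigid-body fields in the frame of sp (positions about the COM):
# three unit translations, three linearized rotations about the axes
rigid_basis <- function(sp, m) {
  O <- nrow(sp)
  basis <- vector("list", 6)
  for (v in 1:3) {
    b <- matrix(0, O, 3); b[, v] <- 1
    basis[[v]] <- b
  }
  for (k in 1:3) {
    u <- c(0, 0, 0); u[k] <- 1
    basis[[3 + k]] <- cbind(u[2] * sp[, 3] - u[3] * sp[, 2],
                            u[3] * sp[, 1] - u[1] * sp[, 3],
                            u[1] * sp[, 2] - u[2] * sp[, 1])
  }
  basis
}

# residual of field after mass-weighted Gram-Schmidt projection out of the
# (not necessarily orthogonal) basis fields
gram_schmidt_residual <- function(field, basis, m) {
  ip <- function(a, b) sum(m * rowSums(a * b))
  ortho <- list()
  for (b in basis) {
    for (o in ortho) b <- b - ip(b, o) * o
    nb <- sqrt(ip(b, b))
    if (nb > 1e-10) ortho[[length(ortho) + 1]] <- b / nb
  }
  for (o in ortho) field <- field - ip(field, o) * o
  field
}

#' Generate a reference/sample THz waveform pair
#'
#' The reference is a seeded band-limited single-cycle pulse (a Gaussian
#' derivative with spectral peak near `center_thz`, covering roughly
#' 0.1-3.5 THz); the sample is the reference propagated through the model
#' slab by [forward_waveform()], optionally with additive Gaussian noise
#' at a stated signal-to-noise ratio.
#'
#' @param n,alpha Slab refractive index and absorption (cm^-1): scalars,
#'   vectors on the positive FFT grid, or functions of frequency in THz.
#' @param thickness_cm Slab thickness in cm (default 0.055, i.e. 550
#'   micrometers, a typical pressed-pellet thickness).
#' @param dt_ps Time step (default 0.05 ps); an error is raised when the
#'   Nyquist frequency cannot contain the pulse band.
#' @param n_points Trace length (default 1024).
#' @param t0_ps Pulse arrival time (default 12 ps).
#' @param center_thz Spectral peak of the pulse (default 1.0 THz, slightly
#'   randomised by the seed).
#' @param snr_db Optional signal-to-noise ratio in dB for additive noise on
#'   the sample trace (NULL = noiseless).
#' @param seed Integer random seed.
#' @return List with elements `reference` and `sample`
#'   ([time_domain_trace()]s).
#' @export
make_waveform_pair <- function(n = 1.5, alpha = 20, thickness_cm = 0.055,
                               dt_ps = 0.05, n_points = 1024, t0_ps = 12,
                               center_thz = 1.0, snr_db = NULL, seed = 1) {
  set.seed(seed)
  nyquist <- 1 / (2 * dt_ps)
  band_edge <- 3.5 * center_thz
  if (nyquist < band_edge) {
    stop("time step ", dt_ps, " ps is too coarse for the pulse band (",
         "Nyquist ", nyquist, " THz < ", band_edge, " THz); reduce dt_ps",
         call. = FALSE)
  }
  nu_c <- center_thz * stats::runif(1, 0.95, 1.05)
  t0 <- t0_ps + stats::runif(1, -0.25, 0.25)
  sigma <- 1 / (2 * pi * nu_c)
  t <- seq(0, by = dt_ps, length.out = n_points)
  x <- -(t - t0) / sigma^2 * exp(-(t - t0)^2 / (2 * sigma^2))
  x <- x / max(abs(x))
  reference <- time_domain_trace(t, x, role = "reference")
  sample <- forward_waveform(reference, n, alpha, thickness_cm)
  if (!is.null(snr_db)) {
    rms <- sqrt(mean(sample$amplitude^2))
    sample$amplitude <- sample$amplitude +
      stats::rnorm(n_points, sd = rms / 10^(snr_db / 20))
  }
  list(reference = reference, sample = sample)
}
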