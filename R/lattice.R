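#' Crystal lattice
#'
#' Constructs a lattice from cell lengths (Angstrom) and angles (degrees).
#' The Cartesian cell matrix follows the crystallographic convention used
#' throughout the package: the first lattice vector lies along x, the second
#' in the xy-plane, and the matrix is right-handed. All Cartesian quantities
#' (molecule coordinates, displacement fields, mode-character axes) live in
#' this frame.
#'
#' @param a,b,c Cell lengths in Angstrom, positive.
#' @param alpha,beta,gamma Cell angles in degrees, in (0, 180).
#' @return An object of class `lattice`: a list with the six parameters and
#'   `matrix`, the 3x3 cell matrix whose rows are the lattice vectors in
#'   Angstrom.
#' @export
#' @examples
#' lat <- lattice(7.795, 9.838, 7.684, 90, 99.495, 90)
#' cell_volume(lat)
lattice <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (any(c(a, b, c) <= 0)) {
    stop("cell lengths must be positive", call. = FALSE)
  }
  ang <- c(alpha, beta, gamma)
  if (any(ang <= 0) || any(ang >= 180)) {
    stop("cell angles must lie strictly between 0 and 180 degrees",
         call. = FALSE)
  }
  ca <- cospi(alpha / 180); cb <- cospi(beta / 180); cg <- cospi(gamma / 180)
  sg <- sinpi(gamma / 180)
  vterm <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vterm <= 0) {
    stop("invalid lattice: angles do not define a positive cell volume",
         call. = FALSE)
  }
  m <- rbind(
    c(a, 0, 0),
    c(b * cg, b * sg, 0),
    c(c * cb, c * (ca - cb * cg) / sg, c * sqrt(vterm) / sg)
  )
  structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
         matrix = m),
    class = "lattice"
  )
}

#' @export
print.lattice <- function(x, ...) {
  cat(sprintf(
    "<lattice> a=%.4f b=%.4f c=%.4f A  alpha=%.3f beta=%.3f gamma=%.3f deg  V=%.2f A^3\n",
    x$a, x$b, x$c, x$alpha, x$beta, x$gamma, cell_volume(x)))
  invisible(x)
}

is_lattice <- function(x) inherits(x, "lattice")

#' Unit-cell volume
#'
#' Closed-form triclinic cell volume
#' \eqn{V = abc\sqrt{1-\cos^2\alpha-\cos^2\beta-\cos^2\gamma
#' + 2\cos\alpha\cos\beta\cos\gamma}}, identical to the determinant of the
#' cell matrix.
#'
#' @param lat A [lattice()].
#' @return Volume in cubic Angstrom.
#' @export
cell_volume <- function(lat) {
  stopifnot(is_lattice(lat))
  ca <- cospi(lat$alpha / 180); cb <- cospi(lat$beta / 180)
  cg <- cospi(lat$gamma / 180)
  vterm <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vterm <= 0) stop("invalid lattice", call. = FALSE)
  lat$a * lat$b * lat$c * sqrt(vterm)
}

#' Fractional to Cartesian coordinates and back
#'
#' Linear maps by the cell matrix (rows = lattice vectors): a fractional
#' row-vector f maps to Cartesian f %*% M.
#'
#' @param lat A [lattice()].
#' @param x Numeric 3-vector or n x 3 matrix of coordinates.
#' @return Matrix (or vector, matching the input shape) of mapped coordinates.
#' @export
frac_to_cart <- function(lat, x) {
  stopifnot(is_lattice(lat))
  drop_vec <- is.null(dim(x))
  m <- rbind(x) %*% lat$matrix
  if (drop_vec) drop(m) else m
}

#' @rdname frac_to_cart
#' @export
cart_to_frac <- function(lat, x) {
  stopifnot(is_lattice(lat))
  drop_vec <- is.null(dim(x))
  m <- rbind(x) %*% solve(lat$matrix)
  if (drop_vec) drop(m) else m
}

#' Bragg diffraction angle for a reflection
#'
#' d-spacing from the reciprocal metric tensor, then the Bragg condition
#' 2 d sin(theta) = lambda. Reflections with lambda > 2d are geometrically
#' inaccessible and reported as NA rather than an error.
#'
#' @param lat A [lattice()].
#' @param hkl Integer Miller-index triple, not (0,0,0); may also be an
#'   n x 3 matrix of triples.
#' @param wavelength X-ray wavelength in Angstrom (default Cu K-alpha,
#'   1.54 A).
#' @return A tibble with columns `h`, `k`, `l`, `d` (Angstrom) and
#'   `two_theta` (degrees; NA when inaccessible), sorted as given.
#' @export
#' @examples
#' lat <- lattice(13.044, 9.507, 3.820)
#' bragg_two_theta(lat, c(1, 0, 0))
bragg_two_theta <- function(lat, hkl, wavelength = 1.54) {
  stopifnot(is_lattice(lat))
  if (wavelength <= 0) stop("wavelength must be positive", call. = FALSE)
  hkl <- rbind(hkl)
  dimnames(hkl) <- NULL
  if (any(rowSums(abs(hkl)) == 0)) {
    stop("hkl must not be (0,0,0)", call. = FALSE)
  }
  gstar <- solve(lat$matrix %*% t(lat$matrix))  # reciprocal metric tensor
  inv_d2 <- rowSums((hkl %*% gstar) * hkl)
  d <- 1 / sqrt(inv_d2)
  s <- wavelength / (2 * d)
  two_theta <- ifelse(s <= 1, 2 * asin(pmin(s, 1)) * 180 / pi, NA_real_)
  tibble::tibble(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                 d = d, two_theta = two_theta)
}

#' Lattice-parameter agreement between two determinations
#'
#' For each free parameter of the reference lattice the agreement is
#' 100 * (1 - |p_test - p_ref| / p_ref). Cell lengths are always compared;
#' angles only when they differ from 90 degrees in the reference (fixed
#' right angles carry no information). The measure is asymmetric: the
#' reference supplies the denominator.
#'
#' @param reference,test [lattice()] objects.
#' @return A tibble with columns `parameter`, `reference`, `test`,
#'   `agreement_pct`, plus attribute `min_agreement` (also the last row
#'   under parameter "min").
#' @export
#' @examples
#' ref <- lattice(13.044, 9.496, 3.814)
#' new <- lattice(13.044, 9.507, 3.820)
#' lattice_agreement(ref, new)
lattice_agreement <- function(reference, test) {
  stopifnot(is_lattice(reference), is_lattice(test))
  pars <- c("a", "b", "c")
  for (ang in c("alpha", "beta", "gamma")) {
    if (abs(reference[[ang]] - 90) > 1e-8) pars <- c(pars, ang)
  }
  ref_v <- vapply(pars, function(p) reference[[p]], numeric(1))
  tst_v <- vapply(pars, function(p) test[[p]], numeric(1))
  agree <- 100 * (1 - abs(tst_v - ref_v) / ref_v)
  out <- tibble::tibble(parameter = pars, reference = ref_v, test = tst_v,
                        agreement_pct = agree)
  attr(out, "min_agreement") <- min(agree)
  out
}
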