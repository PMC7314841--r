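# Shared fixtures, all built in code at test time.

# one toy hydrate reused across tests (generation is deterministic)
toy_xtal <- function(seed = 11) make_toy_crystal(toy_crystal_spec(seed = seed))

toy_partition <- local({
  cache <- new.env()
  function(seed = 11) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- partition_molecules(toy_xtal(seed))
    }
    cache[[key]]
  }
})

# an ad-hoc "molecule" group for decomposition unit tests (no crystal needed)
fake_group <- function(coords, masses, species = "host") {
  list(indices = seq_len(nrow(coords)), species = species,
       formula = "X", coords = coords, masses = masses)
}

# a bent triatomic resembling water (Angstrom)
bent_molecule <- function() {
  a <- 104.5 / 2 * pi / 180
  fake_group(rbind(c(0, 0, 0),
                   c(0.9572 * sin(a), 0.9572 * cos(a), 0),
                   c(-0.9572 * sin(a), 0.9572 * cos(a), 0)),
             masses = c(15.999, 1.008, 1.008), species = "water")
}

# uniform random rotation matrix (det +1)
rand_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# finite rotation of a point set about unit axis u through the weighted COM
rotate_about <- function(coords, masses, u, theta) {
  com <- drop(crossprod(coords, masses) / sum(masses))
  s <- sweep(coords, 2, com)
  u <- u / sqrt(sum(u^2))
  ct <- cos(theta); st <- sin(theta)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  R <- ct * diag(3) + st * ux + (1 - ct) * tcrossprod(u)
  sweep(s %*% t(R), 2, com, "+")
}

# stick intensities that make the Lorentzian-broadened curve hit given peak
# heights at given positions (small linear system over the peak centers)
sticks_for_heights <- function(freqs, heights, fwhm = 0.1) {
  gam <- fwhm / 2
  L <- outer(freqs, freqs, function(a, b) (gam / pi) / ((a - b)^2 + gam^2))
  intens <- solve(L, heights)
  tibble::tibble(frequency_thz = freqs, intensity = intens)
}

# reported room-temperature absorption peaks (THz, cm^-1): anhydrous form
table1_c <- function() list(freqs = c(1.60, 2.76), heights = c(9.75, 93.56))
# monohydrate form, including the weak shoulder at 2.46 THz
table1_cmh <- function() list(freqs = c(2.18, 2.46, 2.76),
                              heights = c(24.86, 10.74, 29.83))

expect_frac_equal <- function(object, expected, tol) {
  expect_true(max(abs(object - expected)) <= tol,
              label = sprintf("max|diff| = %.3g <= %.3g",
                              max(abs(object - expected)), tol))
}

# mass-weighted RMS of a displacement field (independent of the package's
# internal helper)
mw_rms_test <- function(f, m) sqrt(sum(m * rowSums(f^2)) / length(m))
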