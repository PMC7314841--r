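#' Broaden a stick spectrum with Lorentzian lineshapes
#'
#' Each stick (frequency, intensity) becomes a unit-area Lorentzian of full
#' width at half maximum `fwhm`, scaled by the stick intensity, so the
#' integral of the continuous curve over an unbounded grid equals the total
#' stick intensity.
#'
#' @param sticks Data frame with columns `frequency_thz` and `intensity`
#'   (a [stick_spectrum()] works directly).
#' @param fwhm Lorentzian full width at half maximum in THz (default 0.1).
#' @param from,to,by Uniform frequency grid in THz.
#' @return A tibble of class `absorption_spectrum` with columns
#'   `frequency_thz`, `alpha`.
#' @export
#' @examples
#' broaden_spectrum(data.frame(frequency_thz = 2, intensity = 1))
broaden_spectrum <- function(sticks, fwhm = 0.1,
                             from = 0.2, to = 3.0, by = 0.002) {
  stopifnot(fwhm > 0, by > 0, to > from)
  nu <- seq(from, to, by = by)
  alpha <- numeric(length(nu))
  if (nrow(sticks) > 0) {
    gam <- fwhm / 2
    for (i in seq_len(nrow(sticks))) {
      alpha <- alpha + sticks$intensity[i] * (gam / pi) /
        ((nu - sticks$frequency_thz[i])^2 + gam^2)
    }
  }
  out <- tibble::tibble(frequency_thz = nu, alpha = alpha)
  class(out) <- c("absorption_spectrum", class(out))
  out
}

#' Fit and subtract an exponential scattering baseline
#'
#' Powder spectra in a scattering matrix ride on a smooth background well
#' described by \eqn{\alpha_b(\nu) = A e^{B\nu} + C}. The baseline is fitted
#' by nonlinear least squares with iterative peak rejection: points whose
#' residual exceeds `k_sigma` robust standard deviations above the current
#' fit are masked and the fit repeated until the mask stabilises.
#'
#' @param spec Data frame with `frequency_thz`, `alpha` (>= 10 points).
#' @param k_sigma Rejection threshold in robust sigmas (default 2).
#' @param max_iter Maximum masking iterations (default 20).
#' @return Object of class `baseline_fit`: `corrected` (tibble like the
#'   input, baseline removed), `baseline` (fitted values), `coefficients`
#'   (A, B, C), `mask` (logical, TRUE = used as baseline), `fit` (the nls
#'   object), `iterations`.
#' @export
subtract_baseline <- function(spec, k_sigma = 2, max_iter = 20) {
  stopifnot(all(c("frequency_thz", "alpha") %in% names(spec)))
  if (nrow(spec) < 10) stop("need at least 10 grid points", call. = FALSE)
  nu <- spec$frequency_thz
  y <- spec$alpha
  if (all(y == 0)) {
    corrected <- tibble::tibble(frequency_thz = nu, alpha = y)
    class(corrected) <- c("absorption_spectrum", class(corrected))
    return(structure(list(corrected = corrected, baseline = y,
                          coefficients = c(A = 0, B = 0, C = 0),
                          mask = rep(TRUE, length(y)), fit = NULL,
                          iterations = 0L),
                     class = "baseline_fit"))
  }
  mask <- rep(TRUE, length(y))
  fit <- NULL
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    df <- data.frame(nu = nu[mask], y = y[mask])
    start <- baseline_start(df$nu, df$y)
    fit_try <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(B * nu) + C, data = df, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e
    )
    if (inherits(fit_try, "error")) {
      if (is.null(fit)) {
        stop("baseline fit failed to converge: ",
             conditionMessage(fit_try), call. = FALSE)
      }
      break  # keep last successful iterate
    }
    fit <- fit_try
    co <- stats::coef(fit)
    base_all <- co[["A"]] * exp(co[["B"]] * nu) + co[["C"]]
    res <- y - base_all
    sigma <- stats::mad(res[mask], center = 0)
    if (sigma == 0) sigma <- stats::sd(res[mask])
    new_mask <- res <= k_sigma * max(sigma, 1e-12)
    if (sum(new_mask) < 10) break
    if (all(new_mask == mask)) break
    mask <- new_mask
  }
  co <- stats::coef(fit)
  baseline <- co[["A"]] * exp(co[["B"]] * nu) + co[["C"]]
  corrected <- tibble::tibble(frequency_thz = nu, alpha = y - baseline)
  class(corrected) <- c("absorption_spectrum", class(corrected))
  structure(list(corrected = corrected, baseline = baseline,
                 coefficients = c(A = co[["A"]], B = co[["B"]], C = co[["C"]]),
                 mask = mask, fit = fit, iterations = iterations),
            class = "baseline_fit")
}

# crude exponential-plus-offset starting values from the grid ends
baseline_start <- function(nu, y) {
  c0 <- min(y)
  y1 <- max(y[seq_len(max(3, length(y) %/% 10))]) - c0
  y2 <- max(y[seq(length(y) - max(3, length(y) %/% 10) + 1, length(y))]) - c0
  y1 <- max(y1, 1e-6); y2 <- max(y2, 1e-6)
  b0 <- log(y2 / y1) / (max(nu) - min(nu))
  a0 <- y2 / exp(b0 * max(nu))
  list(A = a0, B = b0, C = c0)
}

#' @export
print.baseline_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf(
    "<baseline_fit> alpha_b = %.4g * exp(%.4g nu) + %.4g  (%d iterations, %d/%d points)\n",
    co[["A"]], co[["B"]], co[["C"]], x$iterations, sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Locate peaks in an absorption spectrum
#'
#' Finds local maxima whose prominence — height above the higher of the two
#' flanking minima — exceeds `min_prominence`, at least `min_separation`
#' apart (keeping the taller of close pairs), and refines position and
#' height by 3-point parabolic interpolation.
#'
#' @param spec Data frame with `frequency_thz`, `alpha` on a uniform grid
#'   (baseline-corrected input recommended).
#' @param min_prominence Minimum prominence in the spectrum's intensity
#'   units (default 0).
#' @param min_separation Minimum peak separation in THz (default 0).
#' @return A tibble sorted by frequency: `frequency_thz`, `height`,
#'   `prominence`.
#' @export
find_peaks <- function(spec, min_prominence = 0, min_separation = 0) {
  nu <- spec$frequency_thz
  y <- spec$alpha
  n <- length(y)
  out <- tibble::tibble(frequency_thz = numeric(), height = numeric(),
                        prominence = numeric())
  if (n < 3) return(out)
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  # plateau maxima: first point of a flat top
  if (length(cand) == 0) return(out)
  rows <- list()
  for (i in cand) {
    # flanking minima: walk to the nearest strictly higher point on each
    # side (or the grid end), take the minimum in between
    l <- i; while (l > 1 && y[l - 1] <= y[i]) l <- l - 1
    left_base <- min(y[l:i])
    r <- i; while (r < n && y[r + 1] <= y[i]) r <- r + 1
    right_base <- min(y[i:r])
    prom <- y[i] - max(left_base, right_base)
    if (prom < min_prominence) next
    # parabolic refinement
    if (i > 1 && i < n) {
      d1 <- (y[i + 1] - y[i - 1]) / 2
      d2 <- y[i + 1] - 2 * y[i] + y[i - 1]
      off <- if (d2 < 0) -d1 / d2 else 0
      off <- max(min(off, 0.5), -0.5)
      freq <- nu[i] + off * (nu[2] - nu[1])
      height <- y[i] - d1^2 / (2 * d2) * (d2 < 0)
    } else {
      freq <- nu[i]; height <- y[i]
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      frequency_thz = freq, height = height, prominence = prom)
  }
  if (length(rows) == 0) return(out)
  pk <- dplyr::bind_rows(rows)
  if (min_separation > 0 && nrow(pk) > 1) {
    keep <- order(-pk$height)
    chosen <- integer()
    for (i in keep) {
      if (all(abs(pk$frequency_thz[i] - pk$frequency_thz[chosen]) >=
              min_separation)) {
        chosen <- c(chosen, i)
      }
    }
    pk <- pk[sort(chosen), ]
  }
  dplyr::arrange(pk, .data$frequency_thz)
}
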