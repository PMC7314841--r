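# speed of light in cm/ps: frequencies are THz (1/ps), thicknesses cm
C_CM_PER_PS <- 0.0299792458

#' Terahertz time-domain trace
#'
#' A sampled electric-field waveform: uniform time grid in picoseconds,
#' arbitrary amplitude units, tagged as the reference pulse or as a sample
#' (pellet) transmission with known thickness.
#'
#' @param time_ps Uniformly spaced sample times (ps), at least 64 points.
#' @param amplitude Field amplitudes, same length.
#' @param role `"reference"` or `"sample"`.
#' @param thickness_cm Pellet thickness in cm; required for sample traces.
#' @return Object of class `time_domain_trace`.
#' @export
time_domain_trace <- function(time_ps, amplitude,
                              role = c("reference", "sample"),
                              thickness_cm = NULL) {
  role <- match.arg(role)
  stopifnot(length(time_ps) == length(amplitude))
  if (length(time_ps) < 64) {
    stop("a trace needs at least 64 points", call. = FALSE)
  }
  dt <- diff(time_ps)
  if (max(abs(dt - dt[1])) > 1e-9 * abs(dt[1])) {
    stop("time grid must be uniform", call. = FALSE)
  }
  if (role == "sample") {
    if (is.null(thickness_cm) || thickness_cm <= 0) {
      stop("sample traces require a positive thickness_cm", call. = FALSE)
    }
  }
  structure(list(time_ps = as.numeric(time_ps),
                 amplitude = as.numeric(amplitude),
                 role = role, thickness_cm = thickness_cm,
                 dt_ps = dt[1]),
            class = "time_domain_trace")
}

#' @export
print.time_domain_trace <- function(x, ...) {
  cat(sprintf("<time_domain_trace> %s, %d points, dt = %.4g ps%s\n",
              x$role, length(x$time_ps), x$dt_ps,
              if (is.null(x$thickness_cm)) "" else
                sprintf(", d = %.4g cm", x$thickness_cm)))
  invisible(x)
}

is_trace <- function(x) inherits(x, "time_domain_trace")

#' Discrete Fourier spectrum of a time-domain trace
#'
#' Windowed, optionally zero-padded DFT. The frequency grid is in THz
#' (cycles per ps). With the rectangular window and no padding Parseval's
#' identity `sum(x^2) == sum(|X|^2)/N` holds to rounding error.
#'
#' @param trace A [time_domain_trace()].
#' @param window `"rectangular"` (default) or `"hann"`.
#' @param zero_pad Multiplicative padding factor (>= 1); the signal is
#'   padded with zeros to `zero_pad * N` samples.
#' @return A tibble with `frequency_thz` (the full DFT grid, 0 to
#'   (N-1)/(N dt)) and complex `amplitude`; attribute `nyquist_thz`.
#' @export
fft_spectrum <- function(trace, window = c("rectangular", "hann"),
                         zero_pad = 1) {
  stopifnot(is_trace(trace), zero_pad >= 1)
  window <- match.arg(window)
  x <- trace$amplitude
  n0 <- length(x)
  if (window == "hann") {
    x <- x * 0.5 * (1 - cos(2 * pi * seq(0, n0 - 1) / (n0 - 1)))
  }
  n <- ceiling(zero_pad * n0)
  if (n > n0) x <- c(x, numeric(n - n0))
  amp <- stats::fft(x)
  freq <- (seq_len(n) - 1) / (n * trace$dt_ps)
  out <- tibble::tibble(frequency_thz = freq, amplitude = amp)
  attr(out, "nyquist_thz") <- 1 / (2 * trace$dt_ps)
  out
}

#' Extract optical constants from a THz-TDS waveform pair
#'
#' Thick-slab, echo-free transfer-function analysis. The complex transfer
#' function is T(nu) = S(nu)/R(nu); with the pellet in the thick-sample
#' regime (echoes windowed out) the refractive index follows from the
#' unwrapped spectral phase, n = 1 + c phi/(2 pi nu d), and the absorption
#' coefficient from the magnitude after removing the Fresnel transmission
#' factor, alpha = -(2/d) ln(|T| (n+1)^2 / (4 n)). Phase unwrapping is
#' anchored at the low-frequency end: the branch offset is removed by
#' linearly extrapolating the phase to zero frequency and subtracting the
#' nearest multiple of 2 pi.
#'
#' @param reference,sample [time_domain_trace()]s on the same time grid.
#' @param thickness_cm Slab thickness in cm (defaults to the sample
#'   trace's).
#' @param floor Dynamic-range floor: frequencies where the reference
#'   magnitude falls below `floor` times its maximum are masked out
#'   (default 0.01).
#' @param window,zero_pad Passed to [fft_spectrum()].
#' @return A tibble of class `optical_constants`: `frequency_thz`, `n`,
#'   `alpha_cm` (cm^-1) and logical `valid`; rows cover the positive
#'   frequencies up to Nyquist.
#' @export
extract_optical_constants <- function(reference, sample,
                                      thickness_cm = NULL, floor = 0.01,
                                      window = "rectangular", zero_pad = 1) {
  stopifnot(is_trace(reference), is_trace(sample))
  if (is.null(thickness_cm)) thickness_cm <- sample$thickness_cm
  if (is.null(thickness_cm) || thickness_cm <= 0) {
    stop("thickness_cm must be positive", call. = FALSE)
  }
  if (length(reference$time_ps) != length(sample$time_ps) ||
      abs(reference$dt_ps - sample$dt_ps) > 1e-12) {
    stop("reference and sample must share one time grid", call. = FALSE)
  }
  rf <- fft_spectrum(reference, window = window, zero_pad = zero_pad)
  sf <- fft_spectrum(sample, window = window, zero_pad = zero_pad)
  nfft <- nrow(rf)
  pos <- 2:floor(nfft / 2)  # positive frequencies below Nyquist, nu > 0
  nu <- rf$frequency_thz[pos]
  R <- rf$amplitude[pos]
  S <- sf$amplitude[pos]
  valid <- Mod(R) >= floor * max(Mod(R)) & Mod(S) > 0
  Tf <- ifelse(Mod(R) > 0, S / R, NA_complex_)
  phi <- rep(NA_real_, length(nu))
  if (any(valid)) {
    ph <- -unwrap_phase(Arg(Tf[valid]))
    # anchor the 2*pi branch: extrapolate linearly through nu -> 0
    vnu <- nu[valid]
    nlow <- max(2L, min(10L, length(vnu)))
    fit <- stats::lm.fit(cbind(1, vnu[seq_len(nlow)]),
                         ph[seq_len(nlow)])
    ph <- ph - 2 * pi * round(fit$coefficients[1] / (2 * pi))
    phi[valid] <- ph
  }
  n <- 1 + C_CM_PER_PS * phi / (2 * pi * nu * thickness_cm)
  fres <- (n + 1)^2 / (4 * n)
  alpha <- -(2 / thickness_cm) * log(Mod(Tf) * fres)
  valid <- valid & is.finite(n) & n > 0 & is.finite(alpha)
  out <- tibble::tibble(frequency_thz = nu, n = n, alpha_cm = alpha,
                        valid = valid)
  class(out) <- c("optical_constants", class(out))
  attr(out, "thickness_cm") <- thickness_cm
  out
}

unwrap_phase <- function(p) {
  d <- diff(p)
  p - c(0, cumsum(round(d / (2 * pi)))) * 2 * pi
}

#' Propagate a reference pulse through a model slab
#'
#' Synthesizes the sample waveform a slab of refractive index n(nu) and
#' absorption alpha(nu) (cm^-1) would transmit, using the echo-free slab
#' transfer function 4n/(n+1)^2 * exp(-alpha d / 2) * exp(-i phi) with
#' phi = 2 pi nu (n-1) d / c. This is the exact inverse of
#' [extract_optical_constants()] in the thick-sample regime.
#'
#' @param reference A [time_domain_trace()].
#' @param n,alpha Scalars, vectors on the positive FFT grid, or functions
#'   of frequency (THz); alpha in cm^-1.
#' @param thickness_cm Slab thickness in cm.
#' @return A sample-role [time_domain_trace()] on the same grid.
#' @export
forward_waveform <- function(reference, n, alpha, thickness_cm) {
  stopifnot(is_trace(reference), thickness_cm > 0)
  x <- reference$amplitude
  nfft <- length(x)
  k <- seq_len(nfft) - 1
  signed <- ifelse(k <= nfft / 2, k, k - nfft) / (nfft * reference$dt_ps)
  absnu <- abs(signed)
  nv <- eval_profile(n, absnu, nfft)
  av <- eval_profile(alpha, absnu, nfft)
  if (any(nv <= 0)) stop("refractive index must be positive", call. = FALSE)
  amp <- 4 * nv / (nv + 1)^2 * exp(-av * thickness_cm / 2)
  delay <- (nv - 1) * thickness_cm / C_CM_PER_PS  # ps
  H <- amp * exp(-2i * pi * signed * delay)
  y <- Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / nfft
  time_domain_trace(reference$time_ps, y, role = "sample",
                    thickness_cm = thickness_cm)
}

eval_profile <- function(p, absnu, nfft) {
  if (is.function(p)) return(p(absnu))
  if (length(p) == 1) return(rep(p, nfft))
  if (length(p) == length(absnu)) return(p)
  # vector given on the positive grid nu = (1:(nfft/2 - 1))/(nfft dt)
  pos_len <- floor(nfft / 2) - 1
  if (length(p) == pos_len) {
    # map each |nu| bin to the nearest positive-grid entry
    j <- pmax(1L, pmin(pos_len, round(absnu / absnu[2])))
    return(p[j])
  }
  stop("n/alpha profile length matches neither 1, the FFT grid, ",
       "nor the positive-frequency grid", call. = FALSE)
}

#' Read and write two-column waveform text files
#'
#' Whitespace- or comma-separated `time_ps amplitude` rows; lines starting
#' with `#` are header comments and `# key=value` pairs (role,
#' thickness_cm) are honoured.
#'
#' @param file Path.
#' @param role,thickness_cm Override header values.
#' @return For `read_waveform`, a [time_domain_trace()].
#' @export
read_waveform <- function(file, role = NULL, thickness_cm = NULL) {
  lines <- readLines(file, warn = FALSE)
  hdr <- lines[startsWith(trimws(lines), "#")]
  kv <- regmatches(hdr,
                   regexec("#[[:space:]]*([A-Za-z_]+)[[:space:]]*=[[:space:]]*([^[:space:]]+)",
                           hdr))
  for (m in kv) {
    if (length(m) == 3) {
      if (m[2] == "role" && is.null(role)) role <- m[3]
      if (m[2] == "thickness_cm" && is.null(thickness_cm)) {
        thickness_cm <- as.numeric(m[3])
      }
    }
  }
  body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  vals <- lapply(strsplit(body, "[,[:space:]]+"), as.numeric)
  m <- do.call(rbind, vals)
  if (ncol(m) < 2) stop("waveform file needs two columns", call. = FALSE)
  time_domain_trace(m[, 1], m[, 2],
                    role = if (is.null(role)) "reference" else role,
                    thickness_cm = thickness_cm)
}

#' @rdname read_waveform
#' @param trace A [time_domain_trace()].
#' @param comments Extra `# key=value` provenance lines.
#' @export
write_waveform <- function(trace, file, comments = character()) {
  stopifnot(is_trace(trace))
  hdr <- c(sprintf("# role=%s", trace$role),
           if (!is.null(trace$thickness_cm))
             sprintf("# thickness_cm=%.8g", trace$thickness_cm),
           comments)
  writeLines(c(hdr, sprintf("%.10g %.10g", trace$time_ps, trace$amplitude)),
             file)
  invisible(file)
}
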