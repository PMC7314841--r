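#' Tidy the exponential baseline fit
#'
#' One row per coefficient of the scattering baseline model
#' A exp(B nu) + C, broom-style.
#'
#' @param x A `baseline_fit` from [subtract_baseline()].
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value` (standard errors NA for the degenerate all-zero input).
#' @method tidy baseline_fit
#' @export
tidy.baseline_fit <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(term = c("A", "B", "C"),
                          estimate = unname(x$coefficients),
                          std.error = NA_real_, statistic = NA_real_,
                          p.value = NA_real_))
  }
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' One-line summary of the baseline fit
#'
#' @param x A `baseline_fit` from [subtract_baseline()].
#' @param ... Unused.
#' @return A one-row tibble: `sigma` (residual sd over baseline points),
#'   `n_baseline`, `n_total`, `iterations`.
#' @method glance baseline_fit
#' @export
glance.baseline_fit <- function(x, ...) {
  res <- x$corrected$alpha[x$mask]
  tibble::tibble(sigma = stats::sd(res), n_baseline = sum(x$mask),
                 n_total = length(x$mask), iterations = x$iterations)
}

#' Tidy a per-molecule decomposition
#'
#' @param x A `decomposed_displacements` from
#'   [decompose_displacements()].
#' @param ... Unused.
#' @return A tibble with one row per component: `component`, `rms`
#'   (mass-weighted RMS displacement) and `percent`.
#' @method tidy decomposed_displacements
#' @export
tidy.decomposed_displacements <- function(x, ...) {
  pc <- percentage_contributions(x)
  fields <- c(x$trans, x$lib, list(intra = x$intra))
  tibble::tibble(
    component = names(pc),
    rms = vapply(fields, mw_rms, numeric(1), masses = x$masses),
    percent = as.numeric(pc[1, ])
  )
}

#' One-line summary of a per-molecule decomposition
#'
#' @param x A `decomposed_displacements`.
#' @param ... Unused.
#' @return A one-row tibble: translation magnitude, total libration angle,
#'   intramolecular share and the reconstruction residual (which is zero
#'   by construction).
#' @method glance decomposed_displacements
#' @export
glance.decomposed_displacements <- function(x, ...) {
  recon <- Reduce(`+`, x$trans) + Reduce(`+`, x$lib) + x$intra
  tibble::tibble(
    com_displacement = sqrt(sum(x$com_disp^2)),
    libration_norm_rad = sqrt(sum(x$theta^2)),
    p_intra = percentage_contributions(x)$p_intra,
    reconstruction_error = max(abs(recon - x$total))
  )
}
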