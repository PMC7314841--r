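test_that("trace construction enforces its invariants", {
  t <- seq(0, by = 0.05, length.out = 128)
  expect_error(time_domain_trace(t[1:32], rnorm(32)), "64")
  expect_error(time_domain_trace(c(t[-1], 99), rnorm(128)), "uniform")
  expect_error(time_domain_trace(t, rnorm(128), role = "sample"),
               "thickness")
  tr <- time_domain_trace(t, sin(t), role = "sample", thickness_cm = 0.05)
  expect_s3_class(tr, "time_domain_trace")
})

test_that("the DFT obeys Parseval and known phase shifts", {
  set.seed(13)
  t <- seq(0, by = 0.05, length.out = 256)
  x <- rnorm(256)
  tr <- time_domain_trace(t, x)
  sp <- fft_spectrum(tr)
  expect_equal(sum(x^2), sum(Mod(sp$amplitude)^2) / 256, tolerance = 1e-9)
  # conjugate symmetry of a real signal
  expect_equal(sp$amplitude[2], Conj(sp$amplitude[256]), tolerance = 1e-9)
  # pure delay: phase slope 2 pi nu dt, checked at three frequencies
  wf <- make_waveform_pair(n = 1, alpha = 0, seed = 2)
  shift_bins <- 8
  delayed <- time_domain_trace(
    wf$reference$time_ps,
    c(numeric(shift_bins),
      wf$reference$amplitude[1:(1024 - shift_bins)]))
  spr <- fft_spectrum(wf$reference)
  spd <- fft_spectrum(delayed)
  dt_shift <- shift_bins * 0.05
  for (k in c(20, 51, 103)) {
    nu <- spr$frequency_thz[k]
    ratio <- spd$amplitude[k] / spr$amplitude[k]
    expect_equal(Arg(ratio), Arg(exp(-2i * pi * nu * dt_shift)),
                 tolerance = 1e-6)
  }
  expect_error(fft_spectrum(tr, zero_pad = 0.5), "zero_pad")
})

test_that("the slab forward model delays and attenuates as Fresnel says", {
  wf0 <- make_waveform_pair(n = 1, alpha = 0, seed = 1)
  expect_equal(wf0$sample$amplitude, wf0$reference$amplitude,
               tolerance = 1e-10)
  # n = 1.5, 500 um: group delay (n-1) d / c = 0.834 ps
  ref <- make_waveform_pair(seed = 1)$reference
  smp <- forward_waveform(ref, 1.5, 0, 0.05)
  d_peak <- smp$time_ps[which.max(smp$amplitude)] -
    ref$time_ps[which.max(ref$amplitude)]
  expect_equal(d_peak, 0.834, tolerance = 0.05)
  # Fresnel amplitude factor 4n/(n+1)^2 = 0.96; the delay is unitary, so
  # the energy ratio carries the factor exactly (sampled peak heights shift
  # with the fractional-bin delay)
  expect_equal(sqrt(sum(smp$amplitude^2) / sum(ref$amplitude^2)), 0.96,
               tolerance = 1e-9)
})

test_that("identical waveforms extract to vacuum constants", {
  wf <- make_waveform_pair(n = 1, alpha = 0, seed = 4)
  oc <- extract_optical_constants(wf$reference, wf$sample)
  band <- oc$valid & oc$frequency_thz >= 0.3 & oc$frequency_thz <= 2.5
  expect_true(any(band))
  expect_frac_equal(oc$n[band], 1, 1e-9)
  expect_frac_equal(oc$alpha_cm[band], 0, 1e-9)
})

test_that("a pure magnitude drop maps to the closed-form absorption", {
  # |T| = 0.5 with zero phase: n = 1, alpha = 2 ln 2 / d
  ref <- make_waveform_pair(seed = 5)$reference
  smp <- time_domain_trace(ref$time_ps, 0.5 * ref$amplitude,
                           role = "sample", thickness_cm = 0.05)
  oc <- extract_optical_constants(ref, smp)
  band <- oc$valid & oc$frequency_thz >= 0.3 & oc$frequency_thz <= 2.5
  expect_frac_equal(oc$n[band], 1, 1e-8)
  expect_frac_equal(oc$alpha_cm[band], 2 * log(2) / 0.05, 1e-6)
  expect_equal(2 * log(2) / 0.05, 27.73, tolerance = 1e-3)
})

test_that("extraction inverts the forward model across random profiles", {
  set.seed(14)
  for (rep in 1:10) {
    n0 <- runif(1, 1.2, 2.2)
    a0 <- runif(1, 5, 60)
    d <- runif(1, 0.04, 0.06)
    wf <- make_waveform_pair(n = n0, alpha = a0, thickness_cm = d,
                             seed = 100 + rep)
    oc <- extract_optical_constants(wf$reference, wf$sample)
    band <- oc$valid & oc$frequency_thz >= 0.4 & oc$frequency_thz <= 2.5
    expect_frac_equal(oc$n[band] / n0, 1, 0.005)
    expect_frac_equal(oc$alpha_cm[band] / a0, 1, 0.01)
  }
})

test_that("a frequency-dependent profile round-trips", {
  nfun <- function(nu) 1.5 + 0.05 * nu
  afun <- function(nu) 10 + 15 * exp(-((nu - 2) / 0.2)^2)
  wf <- make_waveform_pair(n = nfun, alpha = afun, thickness_cm = 0.055,
                           seed = 6)
  oc <- extract_optical_constants(wf$reference, wf$sample)
  band <- oc$valid & oc$frequency_thz >= 0.4 & oc$frequency_thz <= 2.8
  expect_frac_equal(oc$n[band] / nfun(oc$frequency_thz[band]), 1, 0.005)
  expect_frac_equal(oc$alpha_cm[band] / afun(oc$frequency_thz[band]), 1, 0.01)
  # the absorption line center lands on the right grid point
  i <- which.max(oc$alpha_cm * band)
  expect_equal(oc$frequency_thz[i], 2.0, tolerance = 0.02)
})

test_that("extraction ignores a common amplitude rescaling", {
  wf <- make_waveform_pair(n = 1.7, alpha = 30, seed = 7)
  oc1 <- extract_optical_constants(wf$reference, wf$sample)
  r2 <- wf$reference; r2$amplitude <- 3.7 * r2$amplitude
  s2 <- wf$sample; s2$amplitude <- 3.7 * s2$amplitude
  oc2 <- extract_optical_constants(r2, s2)
  expect_equal(oc1$n, oc2$n, tolerance = 1e-12)
  expect_equal(oc1$alpha_cm, oc2$alpha_cm, tolerance = 1e-12)
})

test_that("grid mismatches and bad thickness are rejected", {
  wf <- make_waveform_pair(seed = 8)
  short <- time_domain_trace(wf$sample$time_ps[1:512],
                             wf$sample$amplitude[1:512],
                             role = "sample", thickness_cm = 0.05)
  expect_error(extract_optical_constants(wf$reference, short), "time grid")
  ref2 <- wf$reference; ref2$thickness_cm <- NULL
  smp2 <- wf$sample; smp2$thickness_cm <- NULL
  expect_error(extract_optical_constants(wf$reference, smp2), "thickness")
})

test_that("waveform text files round-trip with provenance", {
  wf <- make_waveform_pair(seed = 9)
  f <- withr::local_tempfile(fileext = ".txt")
  write_waveform(wf$sample, f, comments = "# note=test")
  back <- read_waveform(f)
  expect_equal(back$role, "sample")
  expect_equal(back$thickness_cm, wf$sample$thickness_cm)
  expect_equal(back$amplitude, wf$sample$amplitude, tolerance = 1e-9)
  expect_equal(back$time_ps, wf$sample$time_ps, tolerance = 1e-9)
})
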