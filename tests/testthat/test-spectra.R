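test_that("Lorentzian broadening preserves position and area", {
  one <- data.frame(frequency_thz = 2.00, intensity = 3)
  sp <- broaden_spectrum(one, fwhm = 0.1, from = 0.2, to = 3.8, by = 0.001)
  expect_equal(sp$frequency_thz[which.max(sp$alpha)], 2.00, tolerance = 1e-9)
  # numeric integral over +/- many FWHM recovers the stick intensity
  wide <- broaden_spectrum(one, fwhm = 0.1, from = 2 - 5, to = 2 + 5,
                           by = 0.0005)
  area <- sum(wide$alpha) * 0.0005
  expect_equal(area, 3, tolerance = 0.005 * 3)
  # empty stick list gives the zero spectrum
  z <- broaden_spectrum(data.frame(frequency_thz = numeric(),
                                   intensity = numeric()))
  expect_true(all(z$alpha == 0))
})

test_that("two sticks separated by a third of the width merge", {
  f0 <- 2.0; fwhm <- 0.12
  two <- data.frame(frequency_thz = c(f0, f0 + fwhm / 3),
                    intensity = c(1, 1))
  sp <- broaden_spectrum(two, fwhm = fwhm, from = 1.5, to = 2.6, by = 0.0005)
  pk <- find_peaks(sp, min_prominence = 1e-6)
  expect_equal(nrow(pk), 1)
  expect_gt(pk$frequency_thz, f0)
  expect_lt(pk$frequency_thz, f0 + fwhm / 3)
  # dense-grid oracle: direct evaluation finds the same argmax
  dense <- seq(1.9, 2.15, by = 1e-5)
  gam <- fwhm / 2
  curve <- rowSums(sapply(two$frequency_thz, function(c0) {
    (gam / pi) / ((dense - c0)^2 + gam^2)
  }))
  expect_equal(pk$frequency_thz, dense[which.max(curve)], tolerance = 1e-3)
})

test_that("peak heights scale linearly with stick intensities", {
  sticks <- data.frame(frequency_thz = c(1.2, 2.4), intensity = c(1, 2))
  sp1 <- broaden_spectrum(sticks)
  sticks$intensity <- sticks$intensity * 7
  sp7 <- broaden_spectrum(sticks)
  p1 <- find_peaks(sp1, 1e-6); p7 <- find_peaks(sp7, 1e-6)
  expect_equal(p7$height, 7 * p1$height, tolerance = 1e-9)
  expect_equal(p7$frequency_thz, p1$frequency_thz, tolerance = 1e-12)
})

test_that("an exponential baseline is removed to numerical precision", {
  nu <- seq(0.2, 3, by = 0.005)
  y <- 4 * exp(0.8 * nu) + 2
  fit <- subtract_baseline(tibble::tibble(frequency_thz = nu, alpha = y))
  expect_lt(max(abs(fit$corrected$alpha)), 1e-6 * max(y))
  expect_equal(unname(fit$coefficients["B"]), 0.8, tolerance = 1e-3)
  # all-zero input short-circuits
  fit0 <- subtract_baseline(tibble::tibble(frequency_thz = nu, alpha = 0))
  expect_true(all(fit0$corrected$alpha == 0))
  expect_error(subtract_baseline(tibble::tibble(frequency_thz = 1:5,
                                                alpha = 1:5)), "10")
})

test_that("a peak riding on an exponential baseline is recovered", {
  nu <- seq(0.2, 3, by = 0.002)
  gam <- 0.05
  peak_h <- 40
  truth <- peak_h * gam^2 / ((nu - 2.2)^2 + gam^2)
  y <- 10 * exp(0.6 * nu) + 5 + truth
  fit <- subtract_baseline(tibble::tibble(frequency_thz = nu, alpha = y))
  pk <- find_peaks(fit$corrected, min_prominence = 5)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$frequency_thz, 2.2, tolerance = 0.002)
  expect_equal(pk$height, peak_h, tolerance = 0.05 * peak_h)
  # broom-style accessors
  td <- tidy(fit)
  expect_equal(td$term, c("A", "B", "C"))
  expect_equal(glance(fit)$n_total, length(nu))
})

test_that("reported peaks of both crystal forms are recovered from
           spectra built on their printed values", {
  for (tab in list(table1_c(), table1_cmh())) {
    sticks <- sticks_for_heights(tab$freqs, tab$heights, fwhm = 0.1)
    sp <- broaden_spectrum(sticks, fwhm = 0.1, from = 0.2, to = 3.0,
                           by = 0.002)
    pk <- find_peaks(sp, min_prominence = 2)
    expect_equal(nrow(pk), length(tab$freqs))
    expect_frac_equal(pk$frequency_thz, tab$freqs, 0.002)
    expect_true(all(abs(pk$height - tab$heights) / tab$heights <= 0.02))
  }
})

test_that("the weak monohydrate shoulder drops out at high prominence", {
  tab <- table1_cmh()
  sticks <- sticks_for_heights(tab$freqs, tab$heights, fwhm = 0.1)
  sp <- broaden_spectrum(sticks, fwhm = 0.1, from = 0.2, to = 3.0, by = 0.002)
  expect_equal(nrow(find_peaks(sp, min_prominence = 2)), 3)
  expect_equal(nrow(find_peaks(sp, min_prominence = 15)), 2)
})

test_that("monotone curves contain no peaks", {
  sp <- tibble::tibble(frequency_thz = seq(0.2, 3, by = 0.01),
                       alpha = seq(0.2, 3, by = 0.01)^2)
  expect_equal(nrow(find_peaks(sp)), 0)
})

test_that("peak finding agrees with an independent implementation", {
  set.seed(12)
  sticks <- data.frame(frequency_thz = c(0.8, 1.7, 2.5),
                       intensity = c(2, 5, 3))
  sp <- broaden_spectrum(sticks, fwhm = 0.08, by = 0.001)
  pk <- find_peaks(sp, min_prominence = 1)
  pr <- pracma::findpeaks(sp$alpha, minpeakheight = 1)
  expect_equal(sort(pk$frequency_thz),
               sort(sp$frequency_thz[pr[, 2]]), tolerance = 0.002)
})
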