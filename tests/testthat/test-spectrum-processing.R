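# a clean Gaussian peak on a uniform axis
gaussian_spectrum <- function(center = 1500, sigma = 0.05, area = 1000,
                              mz_range = c(1490, 1510), delta = 0.01,
                              offset = 0) {
  mz <- seq(mz_range[1], mz_range[2], by = delta)
  y <- area / (sigma * sqrt(2 * pi)) * exp(-(mz - center)^2 / (2 * sigma^2))
  new_spectrum(mz, y + offset)
}

test_that("smoothing leaves constants alone and preserves ion current", {
  mz <- seq(1000, 1010, by = 0.01)
  flat <- new_spectrum(mz, rep(5, length(mz)))
  expect_equal(smooth_spectrum(flat)$intensity, flat$intensity,
               tolerance = 1e-10)

  g <- gaussian_spectrum()
  sm <- smooth_spectrum(g)
  expect_equal(sum(sm$intensity), sum(g$intensity), tolerance = 0.01)
  # apex stays put within one sample spacing
  expect_lt(abs(sm$mz[which.max(sm$intensity)] - 1500), 0.011)
})

test_that("smoothing contracts white noise", {
  set.seed(2)
  mz <- seq(1000, 1020, by = 0.01)
  noisy <- new_spectrum(mz, abs(rnorm(length(mz), 100, 10)))
  sm <- smooth_spectrum(noisy)
  expect_lt(var(sm$intensity), var(noisy$intensity))
})

test_that("smoothing rejects spectra shorter than the window", {
  s <- new_spectrum(seq(1000, 1000.03, by = 0.01), rep(1, 4))
  expect_error(smooth_spectrum(s), "fewer points")
})

test_that("tophat removes flat offsets and ramps but keeps peaks", {
  g <- gaussian_spectrum(offset = 50)
  bc <- baseline_correct(g, structuring_width_mz = 3)
  tail_region <- bc$mz < 1495
  expect_lt(max(bc$intensity[tail_region]), 1e-6)
  expect_equal(max(bc$intensity), max(g$intensity) - 50, tolerance = 0.01)

  # linear ramp baseline under two peaks
  mz <- seq(1000, 1040, by = 0.01)
  ramp <- 10 + (mz - 1000) * 2
  peaks <- 500 * exp(-(mz - 1010)^2 / (2 * 0.05^2)) +
    800 * exp(-(mz - 1030)^2 / (2 * 0.05^2))
  s <- new_spectrum(mz, ramp + peaks)
  bc2 <- baseline_correct(s, structuring_width_mz = 3)
  resid <- bc2$intensity - peaks
  flat_region <- abs(mz - 1010) > 1 & abs(mz - 1030) > 1
  expect_lt(max(abs(resid[flat_region])), 0.05 * max(ramp))

  z <- new_spectrum(mz, rep(0, length(mz)))
  expect_equal(baseline_correct(z)$intensity, z$intensity)
})

test_that("peak picking finds a lone peak at its true position", {
  set.seed(5)
  g <- gaussian_spectrum(center = 1500.123, area = 100)
  noise <- rnorm(nrow(g), 0, max(g$intensity) / 10)
  s <- new_spectrum(g$mz, pmax(g$intensity + noise, 0))
  s <- smooth_spectrum(s)
  pk <- pick_peaks(s, sn_cutoff = 3)
  top <- pk[which.max(pk$intensity), ]
  expect_lt(abs(top$mz - 1500.123), 0.01)
  expect_gt(top$sn, 3)
})

test_that("a resolved doublet yields two peaks", {
  mz <- seq(1490, 1510, by = 0.01)
  y <- 1000 * exp(-(mz - 1498)^2 / (2 * 0.05^2)) +
    800 * exp(-(mz - 1503)^2 / (2 * 0.05^2)) +
    abs(rnorm(length(mz), 2, 0.5))
  pk <- pick_peaks(new_spectrum(mz, y), sn_cutoff = 10)
  expect_equal(nrow(pk), 2)
  expect_equal(sort(pk$mz), c(1498, 1503), tolerance = 0.01)
})

# noiseless spectrum containing every calibrant at equal area, optionally
# distorted by a known polynomial
calibrant_spectrum <- function(distort = c(0, 0, 0, 0)) {
  prof <- tibble::tibble(composition = glyco_calibrants()$composition,
                         rel_abundance = 100 / 19)
  render_spectrum(prof,
                  render_params(mz_range = c(1100, 3800), delta_mz = 0.01,
                                baseline_amplitude = 0, noise_sd = 0,
                                miscalibration = distort,
                                intensity_scale = 1e6))
}

test_that("recalibration of clean peaks is the identity", {
  s <- calibrant_spectrum()
  pk <- pick_peaks(s, sn_cutoff = 3)
  cal <- recalibrate(s, pk)
  expect_lt(max(abs(cal$residuals$residual_ppm)), 0.5)
})

test_that("recalibration inverts a known cubic distortion", {
  s <- calibrant_spectrum(distort = c(0.08, 2e-5, 4e-9, -4e-13))
  pk <- pick_peaks(s, sn_cutoff = 3)
  cal <- recalibrate(s, pk)
  expect_equal(cal$n_calibrants, 19)
  expect_lt(max(abs(cal$residuals$residual_ppm)), 1)
})

test_that("fewer than five matched calibrants is a hard error", {
  s <- calibrant_spectrum()
  pk <- pick_peaks(s, sn_cutoff = 3)
  few <- glyco_calibrants()[1:4, ]
  expect_error(recalibrate(s, pk, calibrants = few), "4 calibrant")
})

test_that("extraction conserves the rendered analyte area", {
  prof <- tibble::tibble(composition = "H5N4F1", rel_abundance = 100)
  s <- render_spectrum(prof, render_params(
    mz_range = c(1750, 1900), delta_mz = 0.005, baseline_amplitude = 0,
    noise_sd = 0, miscalibration = c(0, 0, 0, 0), intensity_scale = 5e5))
  ext <- extract_analytes(s, tibble::tibble(composition = "H5N4F1"))
  expect_equal(ext$corrected_area, 5e5, tolerance = 0.01)
  expect_lt(abs(ext$ppm_error), 1)
  expect_lt(ext$qs, 0.01)
})

test_that("an absent analyte extracts to nothing and fails S/N", {
  prof <- tibble::tibble(composition = "H5N4F1", rel_abundance = 100)
  s <- render_spectrum(prof, render_params(
    mz_range = c(1750, 2000), delta_mz = 0.005, baseline_amplitude = 10,
    noise_sd = 2, miscalibration = c(0, 0, 0, 0), intensity_scale = 5e5),
    seed = 8)
  ext <- extract_analytes(s, tibble::tibble(composition = "H5N4E1"))
  expect_lt(ext$corrected_area / 5e5, 0.01)
  qc <- qc_analyte(ext)
  expect_false(qc$passes_analyte)
  # a window outside the spectrum is absent, not an error
  out <- extract_analytes(s, tibble::tibble(composition = "H9N8"))
  expect_true(out$absent)
  expect_equal(out$corrected_area, 0)
})

test_that("three-isotope truncation shields against a heavier neighbour", {
  # H5N4F2 sits ~146 Da above H5N4F1; instead craft a neighbour whose
  # envelope tail reaches into the 4th+ isotope region only
  prof1 <- tibble::tibble(composition = "H5N4F1", rel_abundance = 100)
  par <- render_params(mz_range = c(1750, 1900), delta_mz = 0.005,
                       baseline_amplitude = 0, noise_sd = 0,
                       miscalibration = c(0, 0, 0, 0),
                       intensity_scale = 5e5, n_isotopes = 6)
  s1 <- render_spectrum(prof1, par)
  # add a second component 4 isotopologue spacings up
  mz_shift <- 4 * 1.00235
  s2 <- new_spectrum(s1$mz, s1$intensity +
                       approx(s1$mz + mz_shift, s1$intensity * 2,
                              xout = s1$mz, rule = 2)$y)
  e1 <- extract_analytes(s1, tibble::tibble(composition = "H5N4F1"))
  e2 <- extract_analytes(s2, tibble::tibble(composition = "H5N4F1"))
  expect_equal(e2$corrected_area, e1$corrected_area, tolerance = 0.02)
})

test_that("spectrum QC applies the stated strict inequalities", {
  base <- tibble::tibble(composition = c("a", "b"), sn = c(20, 20),
                         raw_area = c(5e4, 5e4))
  expect_true(qc_spectrum(dplyr::mutate(base, raw_area = c(5e5, 5e5)))$pass)
  # total exactly at / below the threshold fails
  expect_false(qc_spectrum(dplyr::mutate(base, raw_area = c(2.5e4, 2.5e4)))$pass)
  expect_false(qc_spectrum(dplyr::mutate(base, raw_area = c(5e4, 5e4)))$pass)
  # exactly half the area from high-S/N analytes fails ("more than 50%")
  half <- tibble::tibble(composition = c("a", "b"), sn = c(20, 3),
                         raw_area = c(1e5, 1e5))
  expect_false(qc_spectrum(half)$pass)
  over_half <- tibble::tibble(composition = c("a", "b"), sn = c(20, 3),
                              raw_area = c(1.01e5, 0.99e5))
  expect_true(qc_spectrum(over_half)$pass)
})

test_that("analyte QC applies the stated strict inequalities", {
  mk <- function(sn, ppm, qs) tibble::tibble(sn = sn, ppm_error = ppm, qs = qs)
  expect_true(qc_analyte(mk(10, 5, 0.02))$passes_analyte)
  expect_false(qc_analyte(mk(5.9, 5, 0.02))$passes_analyte)
  expect_false(qc_analyte(mk(6, 5, 0.02))$passes_analyte)   # strict >
  expect_false(qc_analyte(mk(10, 20, 0.02))$passes_analyte) # strict <
  expect_false(qc_analyte(mk(10, -25, 0.02))$passes_analyte) # absolute ppm
  expect_false(qc_analyte(mk(10, 5, 0.2))$passes_analyte)
  # printed-direction variant is available
  expect_true(qc_analyte(mk(10, 5, 0.2),
                         qs_direction = "above")$passes_analyte)

  toy <- tibble::tibble(
    sn = c(10, 5.9, 10, 10, 30, 7),
    ppm_error = c(5, 5, 25, -3, 19.9, 21),
    qs = c(0.02, 0.02, 0.02, 0.15, 0.099, 0.02))
  expect_equal(sum(qc_analyte(toy)$passes_analyte), 2)
})

test_that("profiles rescale passing analytes to 100%", {
  ext <- tibble::tibble(composition = c("a", "b", "c"),
                        corrected_area = c(2, 3, 5),
                        passes_analyte = TRUE)
  prof <- build_profile(ext)
  expect_equal(prof$rel_abundance, c(20, 30, 50))
  ext$passes_analyte <- FALSE
  expect_error(build_profile(ext), "no analytes passed")
})

test_that("identical replicates give the single-replicate profile", {
  prof <- tibble::tibble(composition = c("H5N2", "H5N4F1"),
                         rel_abundance = c(60, 40))
  par <- render_params(mz_range = c(1100, 1900), delta_mz = 0.01,
                       baseline_amplitude = 0, noise_sd = 0,
                       miscalibration = c(0, 0, 0, 0), intensity_scale = 1e6)
  s <- render_spectrum(prof, par)
  targets <- tibble::tibble(composition = prof$composition)
  one <- extract_analytes(s, targets)
  three <- extract_analytes(combine_replicates(list(s, s, s)), targets)
  p1 <- build_profile(dplyr::mutate(one, passes_analyte = TRUE))
  p3 <- build_profile(dplyr::mutate(three, passes_analyte = TRUE))
  expect_equal(p1$rel_abundance, p3$rel_abundance, tolerance = 1e-9)
})
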