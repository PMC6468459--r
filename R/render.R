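#' Spectrum rendering / acquisition parameters
#'
#' Controls how a glycan profile is rendered into a synthetic MALDI-TOF
#' spectrum: the m/z axis, peak shape, baseline, additive noise, the mass
#' miscalibration polynomial the recalibration stage must undo, and the
#' total analyte intensity.
#'
#' @param mz_range numeric length-2, acquisition window in Da.
#' @param delta_mz sampling interval of the m/z axis (Da).
#' @param peak_sigma Gaussian peak width (sigma, Da); reflectron-mode
#'   MALDI-TOF resolution at these masses corresponds to a few hundredths
#'   of a Dalton.
#' @param baseline_amplitude amplitude of the smooth decaying baseline
#'   (intensity units) at the low-mass end.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param miscalibration polynomial coefficients `c(a0, a1, a2, a3)`; the
#'   rendered position of a peak at true m/z `m` is
#'   `m + a0 + a1 m + a2 m^2 + a3 m^3` (tens of ppm by default).
#' @param intensity_scale total area shared by all analyte envelopes.
#' @param n_isotopes isotopologue peaks rendered per analyte.
#' @return A list of class `render_params`.
#' @export
render_params <- function(mz_range = c(1000, 5000), delta_mz = 0.01,
                          peak_sigma = 0.05, baseline_amplitude = 800,
                          noise_sd = 120,
                          miscalibration = c(0.05, 1e-5, 3e-9, -2e-13),
                          intensity_scale = 2e6, n_isotopes = 5) {
  stopifnot(length(mz_range) == 2, mz_range[1] < mz_range[2],
            delta_mz > 0, peak_sigma > 0, n_isotopes >= 1,
            length(miscalibration) <= 4)
  p <- c(miscalibration, rep(0, 4 - length(miscalibration)))
  structure(list(mz_range = mz_range, delta_mz = delta_mz,
                 peak_sigma = peak_sigma,
                 baseline_amplitude = baseline_amplitude,
                 noise_sd = noise_sd, miscalibration = p,
                 intensity_scale = intensity_scale,
                 n_isotopes = as.integer(n_isotopes)),
            class = "render_params")
}

.apply_miscalibration <- function(mz, coef) {
  mz + coef[1] + coef[2] * mz + coef[3] * mz^2 + coef[4] * mz^3
}

#' Render a glycan profile as a synthetic MALDI-TOF spectrum
#'
#' Places, for every composition in the profile, Gaussian peaks at its
#' first few isotopologue m/z values (shifted by the miscalibration
#' polynomial), with areas proportional to relative abundance times the
#' theoretical isotopic fractions, on top of a smooth decaying baseline and
#' additive Gaussian noise.  Compositions whose envelope falls outside the
#' acquisition window are dropped with a warning.
#'
#' @param profile tibble with columns `composition` and `rel_abundance`
#'   (one sample).
#' @param params a [render_params()] object.
#' @param seed optional integer seed for the noise; `NULL` uses the current
#'   RNG state.
#' @return A spectrum tibble (`mz`, `intensity`) of class `glyco_spectrum`;
#'   the rendered per-composition areas are attached as attribute
#'   `"rendered_truth"`.
#' @export
render_spectrum <- function(profile, params = render_params(), seed = NULL) {
  stopifnot(all(c("composition", "rel_abundance") %in% names(profile)))
  if (!is.null(seed)) set.seed(seed)
  mz <- seq(params$mz_range[1], params$mz_range[2], by = params$delta_mz)
  intensity <- numeric(length(mz))

  canon <- render_composition(parse_composition(profile$composition))
  pat <- isotopic_pattern(canon, k = params$n_isotopes)
  total_ab <- sum(profile$rel_abundance)
  truth <- tibble::tibble(composition = profile$composition,
                          area = if (total_ab > 0) {
                            params$intensity_scale *
                              profile$rel_abundance / total_ab
                          } else 0,
                          rendered = total_ab > 0)
  sig <- params$peak_sigma
  half <- 6 * sig
  for (i in seq_len(if (total_ab > 0) nrow(profile) else 0)) {
    comp <- profile$composition[[i]]
    pp <- pat[pat$composition == canon[[i]], ]
    centers <- .apply_miscalibration(pp$mz, params$miscalibration)
    if (min(centers) - half < params$mz_range[1] ||
        max(centers) + half > params$mz_range[2]) {
      warning("composition ", comp, " falls outside the m/z range; omitted")
      truth$rendered[[i]] <- FALSE
      next
    }
    for (j in seq_along(centers)) {
      a <- truth$area[[i]] * pp$fraction[[j]]
      lo <- max(1L, ceiling((centers[[j]] - half - mz[1]) / params$delta_mz) + 1L)
      hi <- min(length(mz), floor((centers[[j]] + half - mz[1]) / params$delta_mz) + 1L)
      idx <- lo:hi
      intensity[idx] <- intensity[idx] +
        a / (sig * sqrt(2 * pi)) * exp(-(mz[idx] - centers[[j]])^2 / (2 * sig^2))
    }
  }

  baseline <- params$baseline_amplitude * exp(-(mz - mz[1]) / 900) +
    0.05 * params$baseline_amplitude
  noise <- stats::rnorm(length(mz), 0, params$noise_sd)
  out <- new_spectrum(mz, pmax(intensity + baseline + noise, 0))
  attr(out, "rendered_truth") <- truth
  out
}

#' Construct a spectrum object
#'
#' @param mz strictly increasing numeric vector of m/z values (Da).
#' @param intensity non-negative intensities, same length.
#' @return A tibble (`mz`, `intensity`) with class `glyco_spectrum`.
#' @export
new_spectrum <- function(mz, intensity) {
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have the same length")
  }
  if (is.unsorted(mz, strictly = TRUE)) {
    stop("mz must be strictly increasing")
  }
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(tibble::tibble(mz = mz, intensity = intensity),
            class = c("glyco_spectrum", class(tibble::tibble())))
}

#' Combine technical-replicate spectra into one spectrum
#'
#' Replicate spectra acquired on a shared m/z axis are combined point-wise
#' before extraction; summing (the default) matches the convention of
#' averaging raster acquisitions per replicate and then summing replicates
#' into one spectrum per sample.
#'
#' @param spectra list of spectrum tibbles with identical `mz` axes.
#' @param method `"sum"` or `"mean"`.
#' @return A single `glyco_spectrum`.
#' @export
combine_replicates <- function(spectra, method = c("sum", "mean")) {
  method <- match.arg(method)
  stopifnot(length(spectra) >= 1)
  mz <- spectra[[1]]$mz
  for (s in spectra[-1]) {
    if (length(s$mz) != length(mz) || any(abs(s$mz - mz) > 1e-9)) {
      stop("replicate spectra must share the same m/z axis")
    }
  }
  total <- Reduce(`+`, lapply(spectra, function(s) s$intensity))
  if (method == "mean") total <- total / length(spectra)
  new_spectrum(mz, total)
}
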