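#' Internal mass recalibration against known glycan peaks
#'
#' Matches picked peaks to the theoretical m/z of known calibrant
#' compositions (nearest peak within `tol_ppm`), fits a polynomial of the
#' given degree mapping observed to theoretical m/z by least squares, and
#' applies the fitted transform to the whole spectrum and peak list.  At
#' least five calibrants must match or the spectrum is rejected with an
#' error.
#'
#' @param spectrum a spectrum tibble.
#' @param peaks picked peaks, as from [pick_peaks()].
#' @param calibrants tibble with columns `composition` and
#'   `theoretical_mz`; defaults to the 19 reference glycans of
#'   [glyco_calibrants()].
#' @param tol_ppm initial match tolerance in ppm.
#' @param degree polynomial degree of the calibration function (<= 3).
#' @param min_calibrants minimum number of matched calibrants.
#' @param min_sn minimum signal-to-noise ratio a picked peak needs to serve
#'   as a calibrant match; keeps calibrants that happen to be absent from a
#'   sample from latching onto noise peaks.
#' @return A list of class `glyco_calibration` with elements `spectrum`
#'   (calibrated), `peaks` (calibrated), `coefficients`, and `residuals`
#'   (tibble: `composition`, `theoretical_mz`, `observed_mz`,
#'   `residual_ppm` after calibration).
#' @export
recalibrate <- function(spectrum, peaks, calibrants = glyco_calibrants(),
                        tol_ppm = 100, degree = 3, min_calibrants = 5,
                        min_sn = 9) {
  stopifnot(degree >= 1, degree <= 3,
            all(c("composition", "theoretical_mz") %in% names(calibrants)))
  if ("sn" %in% names(peaks)) peaks <- peaks[peaks$sn >= min_sn, ]
  if (!nrow(peaks)) stop("no peaks supplied for recalibration")

  # nearest picked peak for each calibrant, within tolerance
  obs <- vapply(calibrants$theoretical_mz, function(theo) {
    d <- abs(peaks$mz - theo)
    j <- which.min(d)
    if (d[j] / theo * 1e6 <= tol_ppm) peaks$mz[j] else NA_real_
  }, numeric(1))
  matched <- !is.na(obs)
  # a peak may only serve one calibrant: keep the closer assignment
  if (any(duplicated(obs[matched]))) {
    for (v in unique(obs[matched][duplicated(obs[matched])])) {
      idx <- which(obs == v)
      best <- idx[which.min(abs(calibrants$theoretical_mz[idx] - v))]
      obs[setdiff(idx, best)] <- NA_real_
    }
    matched <- !is.na(obs)
  }
  n_matched <- sum(matched)
  if (n_matched < min_calibrants) {
    stop("only ", n_matched, " calibrant(s) matched within ", tol_ppm,
         " ppm; at least ", min_calibrants, " required")
  }

  deg <- min(degree, n_matched - 1)
  fit_data <- data.frame(theo = calibrants$theoretical_mz[matched],
                         obs = obs[matched])
  fit <- stats::lm(theo ~ stats::poly(obs, degree = deg, raw = TRUE),
                   data = fit_data)
  # one trimming pass: a calibrant that latched onto the wrong peak shows a
  # residual far outside the bulk; drop such matches and refit
  res_ppm <- stats::residuals(fit) / fit_data$theo * 1e6
  cut <- max(3 * 1.4826 * stats::mad(res_ppm, constant = 1), 2)
  keep_fit <- abs(res_ppm) <= cut
  if (any(!keep_fit) && sum(keep_fit) >= min_calibrants) {
    idx <- which(matched)
    matched[idx[!keep_fit]] <- FALSE
    obs[idx[!keep_fit]] <- NA_real_
    n_matched <- sum(matched)
    deg <- min(degree, n_matched - 1)
    fit_data <- fit_data[keep_fit, ]
    fit <- stats::lm(theo ~ stats::poly(obs, degree = deg, raw = TRUE),
                     data = fit_data)
  }
  transform <- function(mz) {
    stats::predict(fit, newdata = data.frame(obs = mz))
  }

  cal_spectrum <- new_spectrum(unname(transform(spectrum$mz)),
                               spectrum$intensity)
  cal_peaks <- peaks
  cal_peaks$mz <- unname(transform(peaks$mz))

  resid <- tibble::tibble(
    composition = calibrants$composition[matched],
    theoretical_mz = calibrants$theoretical_mz[matched],
    observed_mz = obs[matched],
    residual_ppm = (unname(transform(obs[matched])) -
                      calibrants$theoretical_mz[matched]) /
      calibrants$theoretical_mz[matched] * 1e6
  )

  structure(list(spectrum = cal_spectrum, peaks = cal_peaks,
                 coefficients = stats::coef(fit), degree = deg,
                 n_calibrants = n_matched, residuals = resid),
            class = "glyco_calibration")
}

#' @export
print.glyco_calibration <- function(x, ...) {
  cat("Internal recalibration: degree", x$degree, "polynomial,",
      x$n_calibrants, "calibrants matched\n")
  cat("max |residual|:", format(max(abs(x$residuals$residual_ppm)),
                                digits = 3), "ppm\n")
  invisible(x)
}
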