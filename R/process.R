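#' Savitzky-Golay smoothing
#'
#' Applies a quadratic Savitzky-Golay filter repeatedly.  The window is the
#' nearest odd number of points spanning `width_mz` at the spectrum's
#' median sampling interval (at least 5 points so the quadratic fit is not
#' an identity).  Total ion current is preserved to well within 1%.
#'
#' @param spectrum a spectrum tibble (`mz`, `intensity`).
#' @param width_mz smoothing peak width in Da.
#' @param cycles number of filter passes.
#' @param order polynomial order of the filter.
#' @return The smoothed spectrum.
#' @export
smooth_spectrum <- function(spectrum, width_mz = 0.06, cycles = 4, order = 2) {
  dm <- stats::median(diff(spectrum$mz))
  w <- max(round(width_mz / dm), order + 3)
  if (w %% 2 == 0) w <- w + 1
  if (nrow(spectrum) < w) {
    stop("spectrum has fewer points (", nrow(spectrum),
         ") than the smoothing window (", w, ")")
  }
  y <- spectrum$intensity
  for (k in seq_len(cycles)) y <- signal::sgolayfilt(y, p = order, n = w)
  new_spectrum(spectrum$mz, pmax(y, 0))
}

# running minimum / maximum over a centred window of 2k+1 points
# (van Herk block algorithm; edges use the truncated window)
.running_extreme <- function(x, k, fun = pmin) {
  if (k <= 0) return(x)
  w <- 2L * k + 1L
  n <- length(x)
  pad_val <- if (identical(fun, pmin)) Inf else -Inf
  nb <- ceiling((n + 2L * k) / w)
  xp <- c(rep(pad_val, k), x, rep(pad_val, nb * w - n - k))
  m <- matrix(xp, nrow = w)
  cum <- if (identical(fun, pmin)) cummin else cummax
  g <- as.vector(apply(m, 2, cum))                      # left-to-right in block
  h <- as.vector(apply(m[w:1, , drop = FALSE], 2, cum)[w:1, , drop = FALSE])
  i <- seq_len(n) + k                                   # centre index in padded
  fun(h[i - k], g[i + k])
}

#' Tophat baseline correction
#'
#' Subtracts the morphological opening (erosion followed by dilation) of
#' the intensity trace with a flat structuring element of width
#' `structuring_width_mz`, which must be wider than the peaks so that peak
#' area is preserved while smooth baseline components are removed.
#'
#' @param spectrum a spectrum tibble.
#' @param structuring_width_mz width of the structuring element (Da).
#' @return The baseline-corrected spectrum.
#' @export
baseline_correct <- function(spectrum, structuring_width_mz = 3) {
  dm <- stats::median(diff(spectrum$mz))
  k <- max(1L, round(structuring_width_mz / dm / 2))
  eroded <- .running_extreme(spectrum$intensity, k, pmin)
  opened <- .running_extreme(eroded, k, pmax)
  new_spectrum(spectrum$mz, pmax(spectrum$intensity - opened, 0))
}

#' Local noise estimate
#'
#' Robust noise level as 1.4826 times the median absolute deviation of the
#' intensity in a sliding window, evaluated on a coarse grid and linearly
#' interpolated.  Peaks occupy a tiny fraction of each window, so the MAD
#' is insensitive to them.
#'
#' @param spectrum a spectrum tibble (smoothed, baseline-corrected).
#' @param window_mz sliding-window width (Da).
#' @param grid_mz spacing of evaluation points (Da).
#' @return A function mapping m/z to the local noise level.
#' @export
estimate_noise <- function(spectrum, window_mz = 20, grid_mz = 5) {
  mz <- spectrum$mz
  span <- mz[length(mz)] - mz[1]
  if (span <= window_mz) {
    level <- 1.4826 * stats::mad(spectrum$intensity, constant = 1)
    if (level <= 0) level <- 1e-6
    return(function(x) rep(level, length(x)))
  }
  centers <- seq(mz[1] + window_mz / 2, mz[length(mz)] - window_mz / 2,
                 by = grid_mz)
  noise <- vapply(centers, function(cm) {
    sel <- findInterval(c(cm - window_mz / 2, cm + window_mz / 2), mz)
    y <- spectrum$intensity[(sel[1] + 1):sel[2]]
    1.4826 * stats::mad(y, constant = 1)
  }, numeric(1))
  if (all(noise <= 0)) noise[] <- 1e-6
  noise[noise <= 0] <- min(noise[noise > 0])
  if (length(centers) < 2) {
    level <- noise[[1]]
    return(function(x) rep(level, length(x)))
  }
  stats::approxfun(centers, noise, rule = 2)
}

#' Peak picking
#'
#' Finds local intensity maxima, refines each apex by parabolic
#' interpolation of the top three points, and keeps peaks whose
#' signal-to-noise ratio (apex height over the local MAD-based noise) is at
#' least `sn_cutoff`.
#'
#' @param spectrum a smoothed, baseline-corrected spectrum tibble.
#' @param sn_cutoff minimum signal-to-noise ratio.
#' @param noise_window_mz window for the local noise estimate (Da).
#' @return A tibble with columns `mz` (interpolated apex), `intensity`
#'   (interpolated apex height), `area` (trapezoidal area within +/- 0.15
#'   Da), `noise`, `sn`.
#' @export
pick_peaks <- function(spectrum, sn_cutoff = 3, noise_window_mz = 20) {
  y <- spectrum$intensity
  n <- length(y)
  if (n < 3) return(tibble::tibble(mz = numeric(), intensity = numeric(),
                                   area = numeric(), noise = numeric(),
                                   sn = numeric()))
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  idx <- idx[y[idx] > 0]
  if (!length(idx)) {
    return(tibble::tibble(mz = numeric(), intensity = numeric(),
                          area = numeric(), noise = numeric(), sn = numeric()))
  }
  noise_at <- estimate_noise(spectrum, window_mz = noise_window_mz)
  # parabolic apex refinement from the three points around each maximum
  y1 <- y[idx - 1L]; y2 <- y[idx]; y3 <- y[idx + 1L]
  denom <- y1 - 2 * y2 + y3
  shift <- ifelse(abs(denom) > 0, 0.5 * (y1 - y3) / denom, 0)
  shift <- pmin(pmax(shift, -0.5), 0.5)
  dm <- stats::median(diff(spectrum$mz))
  apex_mz <- spectrum$mz[idx] + shift * dm
  apex_int <- y2 - 0.25 * (y1 - y3) * shift

  # trapezoidal area in a fixed +/- 0.15 Da window via cumulative sums
  cum <- cumsum((y[-1] + y[-n]) / 2 * diff(spectrum$mz))
  cum <- c(0, cum)
  lo <- findInterval(apex_mz - 0.15, spectrum$mz)
  hi <- findInterval(apex_mz + 0.15, spectrum$mz)
  area <- cum[pmax(hi, 1)] - cum[pmax(lo, 1)]

  noise <- noise_at(apex_mz)
  out <- tibble::tibble(mz = apex_mz, intensity = apex_int, area = area,
                        noise = noise, sn = apex_int / noise)
  out[out$sn >= sn_cutoff, ]
}
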