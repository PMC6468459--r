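#' Targeted extraction of glycan analytes
#'
#' Integrates, for each target composition, the area under the curve in
#' windows around its first `n_isotopes` isotopologue m/z values (default
#' three, which limits the overlap of neighbouring glycan envelopes), and
#' corrects the summed area by the theoretical isotopic fractions so that
#' the corrected area estimates the full envelope.  Also reports the ppm
#' error of the monoisotopic apex, the signal-to-noise ratio, and a quality
#' score defined as the mean absolute deviation between the observed and
#' theoretical isotopologue fractions.
#'
#' @param spectrum a calibrated, smoothed, baseline-corrected spectrum.
#' @param targets tibble with column `composition` (a `theoretical_mz`
#'   column is recomputed if absent).
#' @param n_isotopes isotopologues integrated per analyte.
#' @param window_sigma integration half-width per isotopologue, as a
#'   multiple of `peak_sigma`.
#' @param peak_sigma assumed peak width (sigma, Da).
#' @param isotope_spacing isotopologue spacing (Da).
#' @param noise_window_mz window for the local noise estimate (Da).
#' The corrected area additionally divides out the fraction of a Gaussian
#' peak the +/- `window_sigma` window captures, so that for an isolated
#' noiseless analyte it estimates the full envelope area.
#'
#' @return A tibble with one row per target: `composition`,
#'   `theoretical_mz`, `observed_mz`, `ppm_error`, `sn`, `qs`, `raw_area`,
#'   `corrected_area`, `absent`.
#' @export
extract_analytes <- function(spectrum, targets, n_isotopes = 3,
                             window_sigma = 2, peak_sigma = 0.05,
                             isotope_spacing = .default_isotope_spacing,
                             noise_window_mz = 20) {
  stopifnot("composition" %in% names(targets))
  comp <- targets$composition
  theo <- composition_mass(comp)
  pat <- isotopic_pattern(comp, k = n_isotopes, spacing = isotope_spacing)
  noise_at <- estimate_noise(spectrum, window_mz = noise_window_mz)

  mz <- spectrum$mz
  y <- spectrum$intensity
  n <- length(mz)
  cum <- c(0, cumsum((y[-1] + y[-n]) / 2 * diff(mz)))
  half <- window_sigma * peak_sigma
  coverage <- 2 * stats::pnorm(window_sigma) - 1

  rows <- lapply(seq_along(comp), function(i) {
    pp <- pat[pat$composition ==
                render_composition(parse_composition(comp[[i]])), ]
    centers <- theo[[i]] + (seq_len(n_isotopes) - 1L) * isotope_spacing
    frac <- pp$fraction
    if (min(centers) - half < mz[1] || max(centers) + half > mz[n]) {
      return(tibble::tibble(
        composition = comp[[i]], theoretical_mz = theo[[i]],
        observed_mz = NA_real_, ppm_error = NA_real_, sn = 0, qs = NA_real_,
        raw_area = 0, corrected_area = 0, absent = TRUE))
    }
    areas <- vapply(centers, function(cm) {
      lo <- findInterval(cm - half, mz)
      hi <- findInterval(cm + half, mz)
      cum[max(hi, 1)] - cum[max(lo, 1)]
    }, numeric(1))
    raw <- sum(areas)
    corrected <- raw / sum(frac) / coverage

    # monoisotopic apex: highest point in the first window, refined
    lo <- findInterval(centers[1] - half, mz) + 1L
    hi <- findInterval(centers[1] + half, mz)
    win <- lo:hi
    j <- win[which.max(y[win])]
    if (j > 1 && j < n) {
      y1 <- y[j - 1]; y2 <- y[j]; y3 <- y[j + 1]
      denom <- y1 - 2 * y2 + y3
      shift <- if (abs(denom) > 0) 0.5 * (y1 - y3) / denom else 0
      shift <- min(max(shift, -0.5), 0.5)
      obs_mz <- mz[j] + shift * stats::median(diff(mz))
      apex <- y2 - 0.25 * (y1 - y3) * shift
    } else {
      obs_mz <- mz[j]
      apex <- y[j]
    }
    obs_frac <- if (raw > 0) areas / raw else rep(NA_real_, n_isotopes)
    qs <- mean(abs(obs_frac - frac / sum(frac)))
    tibble::tibble(
      composition = comp[[i]], theoretical_mz = theo[[i]],
      observed_mz = obs_mz,
      ppm_error = (obs_mz - theo[[i]]) / theo[[i]] * 1e6,
      sn = apex / noise_at(obs_mz), qs = qs,
      raw_area = raw, corrected_area = corrected, absent = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Per-analyte quality control
#'
#' Flags each extracted analyte as passing when its signal-to-noise ratio
#' exceeds `sn_min`, its absolute ppm error is below `ppm_max`, and its
#' quality score meets the `qs` criterion.  The quality score is a
#' deviation (smaller is better), so the default direction passes analytes
#' with `qs` at or below `qs_threshold`; set `qs_direction = "above"` to
#' apply the criterion in the opposite direction.
#'
#' @param extractions tibble from [extract_analytes()].
#' @param sn_min signal-to-noise threshold (strict: pass requires sn > this).
#' @param ppm_max absolute ppm error threshold (strict: |ppm| < this).
#' @param qs_threshold quality-score threshold.
#' @param qs_direction `"below"` (deviation score, default) or `"above"`.
#' @return The extraction tibble with a logical `passes_analyte` column
#'   plus the individual criterion flags `pass_sn`, `pass_ppm`, `pass_qs`.
#' @export
qc_analyte <- function(extractions, sn_min = 6, ppm_max = 20,
                       qs_threshold = 0.10,
                       qs_direction = c("below", "above")) {
  qs_direction <- match.arg(qs_direction)
  out <- dplyr::mutate(
    extractions,
    pass_sn = !is.na(.data$sn) & .data$sn > sn_min,
    pass_ppm = !is.na(.data$ppm_error) & abs(.data$ppm_error) < ppm_max,
    pass_qs = !is.na(.data$qs) &
      (if (qs_direction == "below") .data$qs <= qs_threshold
       else .data$qs > qs_threshold)
  )
  dplyr::mutate(out,
                passes_analyte = .data$pass_sn & .data$pass_ppm & .data$pass_qs)
}

#' Spectrum-level quality control
#'
#' A spectrum passes when the summed analyte area exceeds `min_total` and
#' strictly more than `min_fraction` of the total analyte area comes from
#' analytes with signal-to-noise above `high_sn`.
#'
#' @param extractions tibble from [extract_analytes()].
#' @param min_total minimum summed analyte area (strict: > this).
#' @param high_sn signal-to-noise level defining "high quality" analytes.
#' @param min_fraction minimum fraction of area from high-S/N analytes
#'   (strict: > this).
#' @return A one-row tibble: `pass`, `total_intensity`, `high_sn_fraction`.
#' @export
qc_spectrum <- function(extractions, min_total = 1e5, high_sn = 9,
                        min_fraction = 0.5) {
  total <- sum(extractions$raw_area)
  high <- sum(extractions$raw_area[!is.na(extractions$sn) &
                                     extractions$sn > high_sn])
  frac <- if (total > 0) high / total else 0
  tibble::tibble(pass = total > min_total & frac > min_fraction,
                 total_intensity = total, high_sn_fraction = frac)
}

#' Build a normalized glycan profile from extractions
#'
#' Keeps the analytes passing QC and rescales their corrected areas to a
#' total relative intensity of 100% per sample.  Input may contain several
#' samples (column `sample`); a sample with no passing analytes is an
#' error.
#'
#' @param extractions tibble from [qc_analyte()] (must contain
#'   `passes_analyte`); an optional `sample` column groups rows.
#' @return A tibble `sample` (if present), `composition`, `rel_abundance`
#'   summing to 100 per sample.
#' @export
build_profile <- function(extractions) {
  stopifnot("passes_analyte" %in% names(extractions))
  has_sample <- "sample" %in% names(extractions)
  df <- if (has_sample) dplyr::group_by(extractions, .data$sample)
        else extractions
  out <- df |>
    dplyr::filter(.data$passes_analyte) |>
    dplyr::mutate(rel_abundance = 100 * .data$corrected_area /
                    sum(.data$corrected_area)) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::any_of("sample"), "composition", "rel_abundance")
  n_expected <- if (has_sample) length(unique(extractions$sample)) else 1L
  n_got <- if (has_sample) length(unique(out$sample)) else
    as.integer(nrow(out) > 0)
  if (n_got < n_expected || !nrow(out)) {
    stop("no analytes passed QC for at least one sample")
  }
  if (any(!is.finite(out$rel_abundance))) {
    stop("profile normalization failed: zero total corrected area")
  }
  out
}
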