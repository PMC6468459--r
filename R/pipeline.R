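#' Process one raw spectrum into QC-flagged analyte extractions
#'
#' Runs the full preprocessing chain on a raw (or replicate-combined)
#' spectrum: Savitzky-Golay smoothing, tophat baseline correction, peak
#' picking, internal recalibration against known glycan peaks, targeted
#' isotopic-pattern-corrected extraction, and analyte- plus spectrum-level
#' quality control.
#'
#' @param spectrum a raw spectrum tibble.
#' @param targets tibble with column `composition` (the analyte list).
#' @param calibrants calibrant table, default [glyco_calibrants()].
#' @param smooth_width_mz,smooth_cycles smoothing parameters.
#' @param baseline_width_mz tophat structuring width (Da).
#' @param sn_pick peak-picking signal-to-noise cutoff.
#' @param cal_tol_ppm calibrant match tolerance (ppm).
#' @param cal_degree calibration polynomial degree.
#' @param n_isotopes isotopologues integrated per analyte.
#' @param peak_sigma assumed peak width (sigma, Da) for integration windows.
#' @param sn_min,ppm_max,qs_threshold analyte QC thresholds.
#' @return A list with elements `extractions` (QC-flagged tibble),
#'   `calibration` (`glyco_calibration`), and `spectrum_qc` (one-row
#'   tibble).
#' @export
process_spectrum <- function(spectrum, targets,
                             calibrants = glyco_calibrants(),
                             smooth_width_mz = 0.06, smooth_cycles = 4,
                             baseline_width_mz = 3, sn_pick = 3,
                             cal_tol_ppm = 100, cal_degree = 3,
                             n_isotopes = 3, peak_sigma = 0.05,
                             sn_min = 6, ppm_max = 20, qs_threshold = 0.10) {
  s <- smooth_spectrum(spectrum, width_mz = smooth_width_mz,
                       cycles = smooth_cycles)
  s <- baseline_correct(s, structuring_width_mz = baseline_width_mz)
  peaks <- pick_peaks(s, sn_cutoff = sn_pick)
  cal <- recalibrate(s, peaks, calibrants = calibrants,
                     tol_ppm = cal_tol_ppm, degree = cal_degree)
  ext <- extract_analytes(cal$spectrum, targets, n_isotopes = n_isotopes,
                          peak_sigma = peak_sigma)
  ext <- qc_analyte(ext, sn_min = sn_min, ppm_max = ppm_max,
                    qs_threshold = qs_threshold)
  list(extractions = ext, calibration = cal, spectrum_qc = qc_spectrum(ext))
}

#' Process a sample's technical replicates into a glycan profile
#'
#' Combines replicate spectra into one spectrum per sample (summed
#' point-wise), processes it with [process_spectrum()], and rescales the
#' passing analytes to a 100% profile.
#'
#' @param replicate_spectra list of spectrum tibbles for one sample.
#' @param targets analyte list (tibble with `composition`).
#' @param ... passed on to [process_spectrum()].
#' @return A list with `profile` (tibble `composition`, `rel_abundance`),
#'   `extractions`, `calibration`, `spectrum_qc`.
#' @export
process_sample <- function(replicate_spectra, targets, ...) {
  combined <- combine_replicates(replicate_spectra, method = "sum")
  res <- process_spectrum(combined, targets, ...)
  profile <- build_profile(res$extractions)
  c(list(profile = profile), res)
}

#' Simulate a cohort end to end and recover its profiles
#'
#' The full roundtrip used to validate the pipeline: generate glycan
#' profiles with known truth ([generate_profiles()]), render each sample's
#' technical replicates as synthetic MALDI-TOF spectra
#' ([render_spectrum()]), process them back into profiles
#' ([process_sample()]), and return recovered and true quantities side by
#' side.
#'
#' @param design a [cohort_design()].
#' @param params a [render_params()] object.
#' @param library composition library, default [glycan_library()].
#' @param targets analyte list used for extraction; defaults to the
#'   library itself (targeted extraction assumes a known composition list).
#' @param calibrants calibrant table for internal recalibration; defaults
#'   to the full target list (every analyte of known composition with a
#'   sufficiently strong peak can serve as a calibrant), which keeps
#'   recalibration robust when individual species are absent from a
#'   sample.
#' @param seed integer seed (defaults to the design's).
#' @param ... further arguments for [process_spectrum()].
#' @return A list of class `glyco_roundtrip`: `truth` (the generated
#'   cohort), `recovered_profiles` (tibble `sample`, `group`,
#'   `composition`, `rel_abundance`), `recovered_traits` (trait table with
#'   `sample`, `group`), `qc` (per-sample spectrum QC), `comparison`
#'   (tibble `sample`, `composition`, `true_abundance`,
#'   `recovered_abundance`).
#' @export
roundtrip_cohort <- function(design, params = render_params(),
                             library = glycan_library(), targets = NULL,
                             calibrants = NULL, seed = design$seed, ...) {
  if (!is.null(seed)) set.seed(seed)
  cohort <- generate_profiles(design, library = library, seed = NULL)
  if (is.null(targets)) targets <- library["composition"]
  if (is.null(calibrants)) {
    calibrants <- tibble::tibble(
      composition = targets$composition,
      theoretical_mz = composition_mass(targets$composition))
  }
  samples <- unique(cohort$profiles$sample)
  rec <- list()
  qc <- list()
  for (sm in samples) {
    prof <- cohort$profiles[cohort$profiles$sample == sm, ]
    reps <- lapply(seq_len(design$replicates), function(r) {
      render_spectrum(prof, params = params, seed = NULL)
    })
    res <- process_sample(reps, targets, calibrants = calibrants,
                          peak_sigma = params$peak_sigma, ...)
    rec[[sm]] <- dplyr::mutate(res$profile, sample = sm,
                               group = prof$group[[1]], .before = 1)
    qc[[sm]] <- dplyr::mutate(res$spectrum_qc, sample = sm, .before = 1)
  }
  recovered <- dplyr::bind_rows(rec)
  comparison <- dplyr::full_join(
    dplyr::select(cohort$profiles, "sample", "composition",
                  true_abundance = "rel_abundance"),
    dplyr::select(recovered, "sample", "composition",
                  recovered_abundance = "rel_abundance"),
    by = c("sample", "composition"))
  comparison <- dplyr::mutate(
    comparison,
    true_abundance = dplyr::coalesce(.data$true_abundance, 0),
    recovered_abundance = dplyr::coalesce(.data$recovered_abundance, 0))
  traits <- compute_traits(recovered)
  traits <- dplyr::left_join(
    traits,
    dplyr::distinct(cohort$profiles, .data$sample, .data$group),
    by = "sample") |>
    dplyr::relocate("group", .after = "sample")
  structure(list(truth = cohort, recovered_profiles = recovered,
                 recovered_traits = traits, qc = dplyr::bind_rows(qc),
                 comparison = comparison),
            class = "glyco_roundtrip")
}
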