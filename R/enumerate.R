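#' Enumerate glycan compositions matching a target m/z
#'
#' Exhaustively searches the residue-count box defined by `bounds` for
#' compositions whose sodiated monoisotopic m/z lies within `tol_ppm` of
#' `target_mz`.  Used to regenerate candidate analyte lists from observed
#' peak masses.
#'
#' @param target_mz target m/z (Da).
#' @param tol_ppm mass tolerance in parts per million (> 0).
#' @param bounds named integer vector of per-residue maximum counts; any of
#'   `H`, `N`, `F`, `L`, `E` may be given, others default to the standard
#'   search box (H <= 12, N <= 10, F <= 6, L <= 6, E <= 6).
#' @return A tibble with columns `composition`, `H`, `N`, `F`, `L`, `E`,
#'   `theoretical_mz`, `ppm_error`, sorted by `abs(ppm_error)`.  Zero rows
#'   when nothing matches.
#' @examples
#' enumerate_compositions(1257.423, tol_ppm = 20)
#' @export
enumerate_compositions <- function(target_mz, tol_ppm = 20,
                                   bounds = c(H = 12, N = 10, F = 6,
                                              L = 6, E = 6)) {
  stopifnot(is.numeric(target_mz), length(target_mz) == 1, tol_ppm > 0)
  b <- c(H = 12L, N = 10L, F = 6L, L = 6L, E = 6L)
  if (!is.null(names(bounds))) {
    b[names(bounds)] <- as.integer(bounds)
  } else {
    b[] <- as.integer(bounds)
  }
  if (any(is.na(b)) || any(b < 0) || any(is.infinite(b))) {
    stop("bounds must be finite non-negative counts")
  }
  tol_da <- target_mz * tol_ppm * 1e-6
  lo <- target_mz - tol_da
  hi <- target_mz + tol_da
  base <- .h2o_mass + .na_mass - .electron_mass

  # residue budget: no count can exceed what the mass window allows
  for (r in .residue_letters) {
    b[r] <- min(b[r], max(0L, floor((hi - base) / .residue_mass[[r]])))
  }

  hits <- list()
  for (h in 0:b[["H"]]) {
    mh <- base + h * .residue_mass[["H"]]
    if (mh > hi) break
    for (n in 0:b[["N"]]) {
      mn <- mh + n * .residue_mass[["N"]]
      if (mn > hi) break
      for (f in 0:b[["F"]]) {
        mf <- mn + f * .residue_mass[["F"]]
        if (mf > hi) break
        for (l in 0:b[["L"]]) {
          ml <- mf + l * .residue_mass[["L"]]
          if (ml > hi) break
          # solve the last residue directly from the remaining mass window
          e_min <- max(0, ceiling((lo - ml) / .residue_mass[["E"]]))
          e_max <- min(b[["E"]], floor((hi - ml) / .residue_mass[["E"]]))
          if (e_max < e_min) next
          for (e in e_min:e_max) {
            mz <- ml + e * .residue_mass[["E"]]
            if (mz >= lo && mz <= hi) {
              hits[[length(hits) + 1L]] <-
                c(H = h, N = n, F = f, L = l, E = e, mz = mz)
            }
          }
        }
      }
    }
  }

  if (!length(hits)) {
    return(tibble::tibble(
      composition = character(), H = integer(), N = integer(),
      F = integer(), L = integer(), E = integer(),
      theoretical_mz = numeric(), ppm_error = numeric()
    ))
  }
  m <- do.call(rbind, hits)
  out <- tibble::tibble(
    composition = render_composition(tibble::as_tibble(m[, 1:5, drop = FALSE])),
    H = as.integer(m[, "H"]), N = as.integer(m[, "N"]),
    F = as.integer(m[, "F"]), L = as.integer(m[, "L"]),
    E = as.integer(m[, "E"]),
    theoretical_mz = m[, "mz"],
    ppm_error = (m[, "mz"] - target_mz) / target_mz * 1e6
  )
  dplyr::arrange(out, abs(.data$ppm_error))
}
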