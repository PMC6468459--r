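#' Theoretical isotopic patterns of glycan compositions
#'
#' Computes the isotopologue envelope of the sodiated glycan by convolving
#' the isotope distributions of all atoms in the elemental formula
#' (C, H, N, O, Na).  Fractions are of the complete ion population, so the
#' first `k` fractions sum to at most 1; the complete pattern sums to 1.
#' Isotopologue m/z values are the monoisotopic m/z plus multiples of the
#' average isotopologue spacing.
#'
#' @inheritParams composition_mass
#' @param k number of isotopologue peaks to return (>= 1).
#' @param spacing average spacing between consecutive isotopologues (Da).
#' @return A tibble with columns `composition`, `isotope` (0-based),
#'   `mz`, and `fraction`.
#' @examples
#' isotopic_pattern("H5N2", k = 3)
#' @export
isotopic_pattern <- function(x, k = 3,
                             spacing = .default_isotope_spacing) {
  stopifnot(k >= 1)
  f <- elemental_formula(x)
  mono <- composition_mass(x)
  out <- lapply(seq_len(nrow(f)), function(i) {
    p <- .formula_pattern(as.integer(f[i, c("C", "H", "N", "O", "Na")]))
    kk <- min(k, length(p))
    tibble::tibble(
      composition = f$composition[[i]],
      isotope = seq_len(kk) - 1L,
      mz = mono[[i]] + (seq_len(kk) - 1L) * spacing,
      fraction = p[seq_len(kk)]
    )
  })
  dplyr::bind_rows(out)
}

# full isotopologue distribution for one formula given as counts of
# C, H, N, O, Na (in that order); returns numeric vector over nucleon
# offsets 0, 1, 2, ... summing to 1
.formula_pattern <- function(counts) {
  els <- names(.element_mono_mass)
  dist <- 1
  for (j in seq_along(els)) {
    n <- counts[[j]]
    if (n > 0) {
      dist <- .conv(dist, .poly_power(.element_isotopes[[els[[j]]]], n))
    }
  }
  dist / sum(dist)
}

# element distribution for n atoms: single-atom polynomial raised to the
# n-th power by exponentiation-by-squaring on convolutions
.poly_power <- function(p, n) {
  result <- 1
  base <- p
  while (n > 0) {
    if (n %% 2 == 1) result <- .conv(result, base)
    base <- .conv(base, base)
    n <- n %/% 2
  }
  result
}

.conv <- function(a, b) {
  if (identical(a, 1)) return(b)
  if (identical(b, 1)) return(a)
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[[i]] * b
  }
  # drop vanishing tail terms to keep convolutions short
  keep <- max(which(out > 1e-15))
  out[seq_len(keep)]
}
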