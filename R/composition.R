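#' Parse glycan composition strings
#'
#' Compositions are written in the H/N/F/L/E grammar used for
#' composition-level N-glycomics under linkage-specific sialic acid
#' derivatization: `H` hexose, `N` N-acetylhexosamine, `F` deoxyhexose
#' (fucose), `L` lactonized N-acetylneuraminic acid (the mass proxy for
#' alpha2,3-linkage), `E` ethyl-esterified N-acetylneuraminic acid (the
#' alpha2,6 proxy).  Residues may appear in any order on input; unmentioned
#' residues count zero.
#'
#' @param x character vector of composition strings, e.g. `"H5N4F1L1E1"`.
#' @return A tibble with columns `composition` (canonical form, fixed
#'   H,N,F,L,E order, zero counts omitted) and integer columns `H`, `N`,
#'   `F`, `L`, `E`.
#' @examples
#' parse_composition(c("H5N2", "E1L1F1N4H5"))
#' @export
parse_composition <- function(x) {
  stopifnot(is.character(x))
  counts <- matrix(0L, nrow = length(x), ncol = 5,
                   dimnames = list(NULL, .residue_letters))
  for (i in seq_along(x)) {
    s <- x[[i]]
    if (is.na(s) || !nzchar(s)) {
      stop("composition string is empty or NA at position ", i)
    }
    toks <- stringr::str_match_all(s, "([A-Za-z])(-?\\d+)")[[1]]
    consumed <- paste0(toks[, 1], collapse = "")
    if (!identical(consumed, s)) {
      bad <- stringr::str_remove_all(s, "[A-Za-z]-?\\d+")
      stop("cannot parse composition '", s, "': unexpected token '", bad, "'")
    }
    for (j in seq_len(nrow(toks))) {
      letter <- toks[j, 2]
      n <- suppressWarnings(as.integer(toks[j, 3]))
      if (!letter %in% .residue_letters) {
        stop("cannot parse composition '", s, "': unknown residue '",
             letter, "'")
      }
      if (is.na(n) || n < 0) {
        stop("cannot parse composition '", s, "': invalid count for '",
             letter, "'")
      }
      counts[i, letter] <- counts[i, letter] + n
    }
  }
  tibble::tibble(
    composition = render_composition(tibble::as_tibble(counts)),
    H = counts[, "H"], N = counts[, "N"], F = counts[, "F"],
    L = counts[, "L"], E = counts[, "E"]
  )
}

#' Render compositions in canonical form
#'
#' The canonical string lists residues in fixed H,N,F,L,E order and omits
#' zero counts; the all-zero composition renders as `"H0N0"`.
#'
#' @param counts a data frame with integer columns `H`, `N`, `F`, `L`, `E`
#'   (extra columns are ignored).
#' @return character vector of canonical composition strings.
#' @examples
#' render_composition(data.frame(H = 5, N = 4, F = 1, L = 1, E = 1))
#' @export
render_composition <- function(counts) {
  m <- .counts_matrix(counts)
  out <- vapply(seq_len(nrow(m)), function(i) {
    nz <- m[i, ] > 0
    if (!any(nz)) return("H0N0")
    paste0(.residue_letters[nz], m[i, nz], collapse = "")
  }, character(1))
  out
}

# accept composition input as character vector or data frame with count
# columns; return integer matrix with columns H,N,F,L,E
.counts_matrix <- function(x) {
  if (is.character(x)) {
    df <- parse_composition(x)
    m <- as.matrix(df[, .residue_letters])
  } else if (is.data.frame(x)) {
    missing_cols <- setdiff(.residue_letters, names(x))
    if (length(missing_cols)) {
      stop("composition table lacks columns: ",
           paste(missing_cols, collapse = ", "))
    }
    m <- as.matrix(x[, .residue_letters])
  } else {
    stop("compositions must be a character vector or a data frame of counts")
  }
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop("residue counts must be non-negative integers")
  }
  storage.mode(m) <- "integer"
  colnames(m) <- .residue_letters
  m
}

#' Sodiated monoisotopic m/z of glycan compositions
#'
#' Mass of the free reducing-end glycan as the singly charged sodium adduct
#' \eqn{[M+Na]^+}: the sum of residue masses plus water and sodium, minus one
#' electron.  Matches the printed calibrant m/z values used for internal
#' recalibration to within 0.005 Da.
#'
#' @param x compositions as a character vector or a count table
#'   (see [parse_composition()]).
#' @return numeric vector of m/z values (Da).
#' @examples
#' composition_mass("H5N2") # 1257.423
#' @export
composition_mass <- function(x) {
  m <- .counts_matrix(x)
  drop(m %*% .residue_mass) + .h2o_mass + .na_mass - .electron_mass
}

#' Elemental formula of glycan compositions
#'
#' Sums per-residue formulas and adds the terminal water and the sodium of
#' the adduct.  The monoisotopic mass of the returned formula (minus one
#' electron) equals [composition_mass()] to within 1e-4 Da.
#'
#' @inheritParams composition_mass
#' @return A tibble with columns `composition`, `C`, `H`, `N`, `O`, `Na`.
#' @examples
#' elemental_formula("H5N4E1")
#' @export
elemental_formula <- function(x) {
  m <- .counts_matrix(x)
  f <- m %*% .residue_formula
  f[, "H"] <- f[, "H"] + 2L   # + H2O
  f[, "O"] <- f[, "O"] + 1L
  f[, "Na"] <- f[, "Na"] + 1L # + Na adduct
  tibble::tibble(
    composition = render_composition(tibble::as_tibble(m)),
    C = as.integer(f[, "C"]), H = as.integer(f[, "H"]),
    N = as.integer(f[, "N"]), O = as.integer(f[, "O"]),
    Na = as.integer(f[, "Na"])
  )
}

#' Monoisotopic mass of an elemental formula
#'
#' @param formula a data frame with columns `C`, `H`, `N`, `O`, `Na`
#'   (one row per formula), as returned by [elemental_formula()].
#' @param charge charge state; the electron mass times `charge` is
#'   subtracted (default 1, the sodiated singly charged ion).
#' @return numeric vector of masses (Da).
#' @export
formula_mass <- function(formula, charge = 1) {
  els <- names(.element_mono_mass)
  m <- as.matrix(formula[, els])
  drop(m %*% .element_mono_mass) - charge * .electron_mass
}

#' Reference calibrant compositions
#'
#' The 19 glycan compositions (with their sodiated monoisotopic m/z) used
#' for internal recalibration of cell-line N-glycome spectra, spanning
#' high-mannose, fucosylated, and linkage-derivatized sialylated species
#' across m/z 1257--3632.
#'
#' @return A tibble with columns `composition` and `theoretical_mz`.
#' @export
glyco_calibrants <- function() {
  tibble::tibble(
    composition = c(
      "H5N2", "H6N2", "H7N2", "H8N2", "H5N4F1", "H5N4F2", "H5N4E1",
      "H10N2", "H6N5F1", "H5N4L1E1", "H5N4E2", "H6N5E1", "H7N6F1",
      "H6N5F4", "H6N5L1E1", "H7N6E1", "H7N6L2", "H9N8", "H7N6L4F1"
    ),
    theoretical_mz = composition_mass(c(
      "H5N2", "H6N2", "H7N2", "H8N2", "H5N4F1", "H5N4F2", "H5N4E1",
      "H10N2", "H6N5F1", "H5N4L1E1", "H5N4E2", "H6N5E1", "H7N6F1",
      "H6N5F4", "H6N5L1E1", "H7N6E1", "H7N6L2", "H9N8", "H7N6L4F1"
    ))
  )
}
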