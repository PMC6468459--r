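#' Read a two-column xy spectrum text file
#'
#' Reads whitespace- or comma-separated m/z / intensity exports (the usual
#' rendered-spectrum text format).  Lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return A `glyco_spectrum` tibble.
#' @export
read_spectrum_xy <- function(path) {
  first <- readLines(path, n = 1)
  delim <- if (grepl(",", first)) "," else NULL
  df <- if (is.null(delim)) {
    readr::read_table(path, col_names = c("mz", "intensity"),
                      col_types = "dd", comment = "#")
  } else {
    readr::read_csv(path, col_names = c("mz", "intensity"),
                    col_types = "dd", comment = "#")
  }
  new_spectrum(df$mz, df$intensity)
}

#' Write a spectrum as a two-column xy text file
#'
#' @param spectrum a spectrum tibble.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_spectrum_xy <- function(spectrum, path) {
  readr::write_delim(spectrum[, c("mz", "intensity")], path,
                     delim = " ", col_names = FALSE)
  invisible(path)
}

#' Read a gene-expression TSV (genes by samples)
#'
#' First column holds gene identifiers (any name, renamed to `gene`),
#' remaining columns one sample each, log2 scale.
#'
#' @param path file path.
#' @return A tibble with column `gene` plus one numeric column per sample.
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  names(df)[1] <- "gene"
  if (anyDuplicated(df$gene)) stop("duplicate gene identifiers in ", path)
  df
}

#' Write a composition target list as CSV
#'
#' @param targets tibble with a `composition` column; counts and
#'   theoretical m/z are recomputed for consistency.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_target_csv <- function(targets, path) {
  df <- parse_composition(targets$composition)
  df$theoretical_mz <- composition_mass(df)
  readr::write_csv(df, path)
  invisible(path)
}
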