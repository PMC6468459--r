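#' Classify N-glycan compositions into structural classes
#'
#' All N-glycans share a Man3GlcNAc2 pentasaccharide core, so a valid
#' composition carries at least two HexNAc.  The composition-level rule is:
#' N = 2 with H >= 5 is high-mannose, N = 2 with H <= 4 is paucimannose,
#' N = 3 with H >= 5 is hybrid, everything else is complex.
#'
#' @inheritParams composition_mass
#' @return character vector with values `"high-mannose"`, `"paucimannose"`,
#'   `"hybrid"`, or `"complex"`.
#' @examples
#' classify_glycan(c("H5N2", "H3N2", "H6N3", "H5N4E2"))
#' @export
classify_glycan <- function(x) {
  m <- .counts_matrix(x)
  if (any(m[, "N"] < 2)) {
    bad <- render_composition(tibble::as_tibble(m[m[, "N"] < 2, , drop = FALSE]))
    stop("invalid N-glycan composition (needs N >= 2 for the core): ",
         paste(bad, collapse = ", "))
  }
  dplyr::case_when(
    m[, "N"] == 2 & m[, "H"] >= 5 ~ "high-mannose",
    m[, "N"] == 2 & m[, "H"] <= 4 ~ "paucimannose",
    m[, "N"] == 3 & m[, "H"] >= 5 ~ "hybrid",
    TRUE ~ "complex"
  )
}

#' Per-composition structural features
#'
#' Expands compositions into the feature columns the derived-trait formulas
#' use: structural class, antenna count, and galactose count.  For complex
#' species the antenna count is `N - 2` (floored at 1; bisecting GlcNAc
#' cannot be distinguished at the composition level and inflates it by one)
#' and the galactose count is `min(H - 3, antennae)` floored at 0.
#'
#' @inheritParams composition_mass
#' @return A tibble with columns `composition`, `H`, `N`, `F`, `L`, `E`,
#'   `class`, `antennae`, `galactoses`.
#' @export
glycan_features <- function(x) {
  df <- if (is.character(x)) parse_composition(x) else
    parse_composition(render_composition(x))
  df$class <- classify_glycan(df)
  df$antennae <- ifelse(df$class == "complex", pmax(df$N - 2L, 1L), NA_integer_)
  df$galactoses <- ifelse(df$class == "complex",
                          pmax(pmin(df$H - 3L, df$antennae), 0L), NA_integer_)
  df
}

#' Derived glycan trait registry
#'
#' The single declarative home of every derived-trait formula.  Each entry
#' gives the trait name, a human-readable description, and a function of a
#' per-composition feature table (columns `ab` — abundance fraction summing
#' to 1 over the profile — plus the [glycan_features()] columns) returning
#' the trait value in percent.  Whole-profile traits are fractions of total
#' abundance; complex-only traits are abundance-weighted means over the
#' complex-type subset.  Traits whose denominator subset is empty return
#' `NA` rather than 0.
#'
#' @return A named list of trait definitions (`name`, `description`, `fun`).
#' @export
trait_registry <- function() {
  frac <- function(num_sel, den_sel = NULL) {
    force(num_sel); force(den_sel)
    function(df) {
      den <- if (is.null(den_sel)) sum(df$ab) else sum(df$ab[den_sel(df)])
      if (!isTRUE(den > 0)) return(NA_real_)
      100 * sum(df$ab[num_sel(df)]) / den
    }
  }
  wmean <- function(value, den_sel) {
    force(value); force(den_sel)
    function(df) {
      keep <- den_sel(df)
      den <- sum(df$ab[keep])
      if (!isTRUE(den > 0)) return(NA_real_)
      100 * sum(df$ab[keep] * value(df)[keep]) / den
    }
  }
  cx <- function(df) df$class == "complex"
  def <- function(name, description, fun) list(name = name,
                                               description = description,
                                               fun = fun)
  lst <- list(
    def("MultiFuc", "glycans carrying more than one fucose (% of total)",
        frac(function(df) df$F >= 2)),
    def("MonoFuc", "glycans carrying exactly one fucose (% of total)",
        frac(function(df) df$F == 1)),
    def("CFa", "multi-fucosylated fraction of complex-type glycans (%)",
        frac(function(df) cx(df) & df$F >= 2, cx)),
    def("CFc", "mono-fucosylated fraction of complex-type glycans (%)",
        frac(function(df) cx(df) & df$F == 1, cx)),
    def("SialylTotal", "glycans carrying at least one sialic acid (% of total)",
        frac(function(df) df$L + df$E >= 1)),
    def("Sia23",
        "alpha2,3-sialylation per antenna over complex-type glycans (%)",
        wmean(function(df) df$L / df$antennae, cx)),
    def("Sia26",
        "alpha2,6-sialylation per antenna over complex-type glycans (%)",
        wmean(function(df) df$E / df$antennae, cx)),
    def("SiaPerGal",
        "sialylation per galactose over galactosylated complex glycans (%)",
        wmean(function(df) (df$L + df$E) / df$galactoses,
              function(df) cx(df) & df$galactoses >= 1)),
    def("GalPerAntenna",
        "galactosylation per antenna over complex-type glycans (%)",
        wmean(function(df) df$galactoses / df$antennae, cx)),
    def("HexNAcGeHex",
        "complex glycans with HexNAc >= Hex (% of total)",
        frac(function(df) cx(df) & df$N >= df$H)),
    def("HexNAcGe7", "glycans with seven or more HexNAc (% of total)",
        frac(function(df) df$N >= 7)),
    def("CLFa",
        "multi-fucosylated, alpha2,3-sialylated fraction of complex glycans (%)",
        frac(function(df) cx(df) & df$F >= 2 & df$L >= 1, cx)),
    def("HighMannose", "high-mannose glycans (% of total)",
        frac(function(df) df$class == "high-mannose"))
  )
  stats::setNames(lst, vapply(lst, `[[`, character(1), "name"))
}

#' Compute derived glycan traits from normalized profiles
#'
#' Applies every formula in [trait_registry()] to each sample of a profile
#' table.  Traits are ratios, so they are invariant to rescaling of the
#' profile; the profile is normalized internally before evaluation.
#'
#' @param profiles long-format tibble with columns `sample`, `composition`,
#'   and `rel_abundance` (non-negative; per-sample totals need not be 100).
#' @return A tibble with one row per sample: column `sample` plus one
#'   column per registered trait (percent).
#' @examples
#' p <- tibble::tibble(sample = "s1",
#'                     composition = c("H5N2", "H5N4L1E1"),
#'                     rel_abundance = c(50, 50))
#' compute_traits(p)
#' @export
compute_traits <- function(profiles) {
  stopifnot(all(c("sample", "composition", "rel_abundance") %in%
                  names(profiles)))
  if (nrow(profiles) == 0) stop("empty profile table")
  if (any(profiles$rel_abundance < 0)) stop("abundances must be non-negative")
  reg <- trait_registry()
  feats <- glycan_features(unique(profiles$composition))
  df <- dplyr::left_join(
    dplyr::mutate(profiles,
                  composition = render_composition(
                    parse_composition(.data$composition))),
    feats, by = "composition")
  out <- df |>
    dplyr::group_by(.data$sample) |>
    dplyr::group_modify(function(g, key) {
      tot <- sum(g$rel_abundance)
      if (!isTRUE(tot > 0)) stop("profile with zero total abundance")
      g$ab <- g$rel_abundance / tot
      vals <- vapply(reg, function(tr) tr$fun(g), numeric(1))
      tibble::as_tibble(as.list(vals))
    }) |>
    dplyr::ungroup()
  out
}
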