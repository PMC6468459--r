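#' CDX1 mRNA expression of the 16 reference colorectal cancer cell lines
#'
#' The published CDX1 mRNA levels (arbitrary units) of the 16 cell lines
#' the cohort design emulates; lines below 60 units are the low-expression
#' group.
#'
#' @return A tibble with columns `cell_line`, `cdx1_mrna`, `group`.
#' @export
cdx1_reference_values <- function() {
  tibble::tibble(
    cell_line = c("HCA46", "HCC56", "GP2D", "PCJW", "LS174T", "LIM1863",
                  "SW403", "RCM1", "ISRECO1", "VACO429", "HCT116", "CC20",
                  "CAR1", "COLO678", "HDC8", "OXCO1"),
    cdx1_mrna = c(3308.59, 4115.35, 3058.48, 2598.75, 1147.36, 2862.38,
                  2964.14, 1152.22, 32.10, 28.69, 59.94, 59.51, 49.35,
                  16.21, 29.31, 49.69),
    group = rep(c("high", "low"), each = 8)
  )
}

#' Default glyco-gene simulation spec
#'
#' Per-gene baseline log2 expression, group shift (log2 fold change,
#' high minus low), and noise SD for the synthetic expression matrix.
#' Directions encode the reported associations: antenna-fucosylation
#' genes (FUT3/FUT6, with FUT2/4/5/7 as weaker trends), GMDS, the
#' transcription factors HNF1A/HNF4A, LGALS4, B4GALNT3, B3GNT3/8 and
#' MGAT4A up with high CDX1; ST3GAL3/4/6 and FUT8 down; sialyl- and
#' galactosyltransferase trends mild; ST8SIA and core branching genes
#' null.  CDX1 itself is drawn from the two-group lognormal fitted to
#' [cdx1_reference_values()] rather than from this table.
#'
#' @param noise_sd default per-gene noise SD (log2 units).
#' @return A tibble with columns `gene`, `base_log2`, `log2fc`, `sd`.
#' @export
default_gene_spec <- function(noise_sd = 0.5) {
  spec <- tibble::tribble(
    ~gene,       ~base_log2, ~log2fc,
    "FUT1",       6.0,  0.30,
    "FUT2",       6.0,  0.60,
    "FUT3",       6.5,  2.51,   # ~5.7-fold
    "FUT4",       6.5,  0.80,
    "FUT5",       5.5,  0.50,
    "FUT6",       6.5,  1.43,   # ~2.7-fold
    "FUT7",       5.5,  0.50,
    "FUT8",       8.0, -0.50,
    "FUT9",       5.5,  0.20,
    "GMDS",       7.0,  1.888,  # ~3.7-fold
    "MGAT1",      8.5,  0.00,
    "MGAT2",      8.0,  0.00,
    "MGAT3",      6.5,  0.70,
    "MGAT4A",     7.0,  1.00,
    "MGAT5",      7.5,  0.00,
    "B3GNT3",     6.5,  1.00,
    "B3GNT8",     6.0,  1.00,
    "B3GALT5",    5.5,  0.50,
    "B4GALT1",    8.5, -0.30,
    "B4GALT2",    7.5, -0.30,
    "B4GALT3",    7.5, -0.20,
    "B4GALT4",    7.0, -0.20,
    "B4GALNT3",   6.0,  1.20,
    "ST3GAL3",    7.0, -0.40,
    "ST3GAL4",    7.5, -0.40,
    "ST3GAL6",    7.0, -1.50,
    "ST6GAL1",    8.0,  0.00,
    "ST8SIA1",    5.5,  0.00,
    "ST8SIA2",    5.0,  0.00,
    "ST8SIA3",    5.0,  0.00,
    "ST8SIA4",    6.0,  0.00,
    "ST8SIA5",    5.0,  0.00,
    "HNF1A",      6.5,  1.50,
    "HNF4A",      7.0,  1.50,
    "LGALS4",     6.0,  4.524,  # ~23-fold
    "CDX2",       7.0,  3.00
  )
  spec$sd <- noise_sd
  spec
}

#' Default glyco-gene subset for differential testing
#'
#' @return Character vector of gene symbols: the fucosyltransferase,
#'   branching, galactosyl-, sialyl- and HexNAc-transferase families plus
#'   the transcription factors tested for association with the glycan
#'   phenotype.
#' @export
default_glyco_genes <- function() {
  c(default_gene_spec()$gene, "CDX1")
}

#' Generate a synthetic glyco-gene expression matrix
#'
#' Draws a log2 expression matrix (genes by samples) for the cohort, with
#' group shifts from `gene_spec` and CDX1 itself drawn from a two-group
#' lognormal fitted to the published per-line values, so that the high/low
#' ratio of arithmetic means on the linear scale matches the reference
#' design.
#'
#' @param design a [cohort_design()].
#' @param gene_spec tibble as from [default_gene_spec()].
#' @param seed integer seed (defaults to the design's plus one so profiles
#'   and expression are independent streams; `NULL` uses the current RNG
#'   state).
#' @return A list with `expr` (tibble: `gene` plus one column per sample,
#'   log2 scale), `groups` (tibble `sample`, `group`), and `truth` (tibble
#'   `gene`, `log2fc`, `fold_change`).
#' @export
generate_expression_matrix <- function(design, gene_spec = default_gene_spec(),
                                       seed = design$seed + 1L) {
  if (anyDuplicated(gene_spec$gene)) {
    stop("duplicate gene identifiers in gene_spec: ",
         paste(unique(gene_spec$gene[duplicated(gene_spec$gene)]),
               collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  groups <- c(rep("high", design$n_high), rep("low", design$n_low))
  samples <- sprintf("%s_%02d", groups,
                     c(seq_len(design$n_high), seq_len(design$n_low)))

  m <- matrix(NA_real_, nrow = nrow(gene_spec) + 1L, ncol = length(samples),
              dimnames = list(c(gene_spec$gene, "CDX1"), samples))
  for (i in seq_len(nrow(gene_spec))) {
    mu <- gene_spec$base_log2[[i]] +
      ifelse(groups == "high", gene_spec$log2fc[[i]], 0)
    m[i, ] <- stats::rnorm(length(samples), mu, gene_spec$sd[[i]])
  }
  # CDX1: lognormal per group, moments from the reference cell lines
  ref <- cdx1_reference_values()
  for (g in c("high", "low")) {
    lv <- log2(ref$cdx1_mrna[ref$group == g])
    sel <- groups == g
    m["CDX1", sel] <- stats::rnorm(sum(sel), mean(lv), stats::sd(lv))
  }

  truth <- tibble::tibble(
    gene = gene_spec$gene,
    log2fc = gene_spec$log2fc,
    fold_change = 2^gene_spec$log2fc)
  list(expr = dplyr::bind_cols(tibble::tibble(gene = rownames(m)),
                               tibble::as_tibble(m)),
       groups = tibble::tibble(sample = samples, group = groups),
       truth = truth)
}
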