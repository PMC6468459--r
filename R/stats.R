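#' Mann-Whitney comparison of derived traits between two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per trait, exact for
#' small untied samples and normal-approximated with tie correction
#' otherwise, with Bonferroni adjustment over the family of tested traits.
#' A trait constant across both groups yields p = 1 with a warning.
#'
#' @param traits trait table: column `sample` plus one numeric column per
#'   trait (a `group` column is ignored in favour of `groups`).
#' @param groups tibble with columns `sample` and `group` (values `"high"`
#'   and `"low"`).
#' @return A tibble with columns `trait`, `statistic` (U for the high
#'   group), `p_raw`, `p_bonferroni`, `mean_high`, `mean_low`, `delta`
#'   (high minus low), `n_tests`.
#' @export
mann_whitney_traits <- function(traits, groups) {
  stopifnot(all(c("sample", "group") %in% names(groups)))
  df <- dplyr::inner_join(
    dplyr::select(traits, -dplyr::any_of("group")), groups, by = "sample")
  if (!all(c("high", "low") %in% df$group)) {
    stop("both groups ('high', 'low') must be present")
  }
  trait_cols <- setdiff(names(df), c("sample", "group"))
  trait_cols <- trait_cols[vapply(df[trait_cols], is.numeric, logical(1))]
  res <- lapply(trait_cols, function(tr) {
    x <- df[[tr]][df$group == "high"]
    y <- df[[tr]][df$group == "low"]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y)) {
      return(tibble::tibble(trait = tr, statistic = NA_real_,
                            p_raw = NA_real_, mean_high = NA_real_,
                            mean_low = NA_real_, delta = NA_real_))
    }
    if (stats::sd(c(x, y)) == 0) {
      warning("trait ", tr, " is constant in both groups; p = 1")
      return(tibble::tibble(trait = tr,
                            statistic = length(x) * length(y) / 2,
                            p_raw = 1, mean_high = mean(x),
                            mean_low = mean(y), delta = 0))
    }
    exact <- length(x) <= 10 && length(y) <= 10 &&
      !any(duplicated(c(x, y)))
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                         correct = !exact))
    tibble::tibble(trait = tr, statistic = unname(wt$statistic),
                   p_raw = wt$p.value, mean_high = mean(x),
                   mean_low = mean(y), delta = mean(x) - mean(y))
  })
  out <- dplyr::bind_rows(res)
  m <- sum(!is.na(out$p_raw))
  out$p_bonferroni <- pmin(out$p_raw * m, 1)
  out$n_tests <- m
  out
}

#' Principal component analysis of glycan profiles
#'
#' Mean-centred (and by default unit-variance scaled) SVD-based PCA of the
#' per-sample composition abundances.  Constant compositions are dropped
#' before scaling.  Component signs are fixed so the largest-magnitude
#' loading of each component is positive.
#'
#' @param profiles long tibble `sample`, `composition`, `rel_abundance`.
#' @param n_components number of components to keep.
#' @param scale. unit-variance scaling (default TRUE).
#' @return An object of class `glyco_pca`: list with `scores` (tibble
#'   `sample`, `PC1`, ...), `loadings` (tibble `composition`, `PC1`, ...),
#'   `explained_variance` (fractions per kept component, non-increasing),
#'   `explained_total` (their sum), and `sdev`.
#' @export
pca_profiles <- function(profiles, n_components = 4, scale. = TRUE) {
  wide <- tidyr::pivot_wider(
    dplyr::select(profiles, "sample", "composition", "rel_abundance"),
    names_from = "composition", values_from = "rel_abundance",
    values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample
  if (nrow(m) < 2) stop("PCA needs at least two samples")
  keep <- apply(m, 2, stats::sd) > 0
  m <- m[, keep, drop = FALSE]
  fit <- stats::prcomp(m, center = TRUE, scale. = scale.)
  rank <- sum(fit$sdev > 1e-10)
  if (n_components > rank) {
    warning("n_components (", n_components, ") exceeds rank (", rank,
            "); truncated")
    n_components <- rank
  }
  k <- seq_len(n_components)
  # sign convention: largest-|loading| entry of each component positive
  for (j in k) {
    i_max <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[i_max, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(sample = rownames(fit$x)),
                              tibble::as_tibble(fit$x[, k, drop = FALSE])),
    loadings = dplyr::bind_cols(
      tibble::tibble(composition = rownames(fit$rotation)),
      tibble::as_tibble(fit$rotation[, k, drop = FALSE])),
    explained_variance = ev[k],
    explained_total = sum(ev[k]),
    sdev = fit$sdev,
    n_components = n_components),
    class = "glyco_pca")
}

#' @export
print.glyco_pca <- function(x, ...) {
  cat("PCA of glycan profiles:", x$n_components, "components explaining",
      sprintf("%.1f%%", 100 * x$explained_total), "of the variance\n")
  invisible(x)
}

#' Differential glyco-gene expression between groups
#'
#' Per-gene two-sided t-test (Welch by default) on log2 expression between
#' the high and low groups, linear-scale fold change from the difference of
#' group means, and Bonferroni adjustment over the tested gene subset.
#' Requested genes absent from the matrix are reported with `missing =
#' TRUE` rather than dropped.
#'
#' @param expr expression tibble: column `gene` plus one column per sample
#'   (log2 scale).
#' @param groups tibble `sample`, `group`.
#' @param genes character vector of genes to test; default
#'   [default_glyco_genes()].
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return A tibble `gene`, `statistic` (t), `p_raw`, `p_bonferroni`,
#'   `fold_change` (2^(mean_high - mean_low)), `mean_high`, `mean_low`,
#'   `missing`, `n_tests`.
#' @export
gene_differential <- function(expr, groups, genes = default_glyco_genes(),
                              var_equal = FALSE) {
  stopifnot("gene" %in% names(expr))
  samples_high <- groups$sample[groups$group == "high"]
  samples_low <- groups$sample[groups$group == "low"]
  if (!length(samples_high) || !length(samples_low)) {
    stop("both groups must contain samples")
  }
  res <- lapply(genes, function(g) {
    row <- expr[expr$gene == g, , drop = FALSE]
    if (!nrow(row)) {
      return(tibble::tibble(gene = g, statistic = NA_real_, p_raw = NA_real_,
                            fold_change = NA_real_, mean_high = NA_real_,
                            mean_low = NA_real_, missing = TRUE))
    }
    x <- as.numeric(row[1, samples_high])
    y <- as.numeric(row[1, samples_low])
    mh <- mean(x); ml <- mean(y)
    if (stats::sd(c(x, y)) == 0) {
      return(tibble::tibble(gene = g, statistic = 0, p_raw = 1,
                            fold_change = 2^(mh - ml), mean_high = mh,
                            mean_low = ml, missing = FALSE))
    }
    tt <- tryCatch(stats::t.test(x, y, var.equal = var_equal),
                   error = function(e) NULL)  # zero within-group variance
    tibble::tibble(gene = g,
                   statistic = if (is.null(tt)) NA_real_
                               else unname(tt$statistic),
                   p_raw = if (is.null(tt)) NA_real_ else tt$p.value,
                   fold_change = 2^(mh - ml),
                   mean_high = mh, mean_low = ml, missing = FALSE)
  })
  out <- dplyr::bind_rows(res)
  m <- sum(!out$missing & !is.na(out$p_raw))
  out$p_bonferroni <- pmin(out$p_raw * m, 1)
  out$n_tests <- m
  out
}

#' Linear regression of derived traits on gene expression
#'
#' Ordinary least squares of each trait on each gene's log2 expression over
#' the paired samples: slope, intercept, R-squared, and the two-sided p for
#' the slope.
#'
#' @param traits trait table (`sample` plus trait columns).
#' @param expr expression tibble (`gene` plus sample columns).
#' @param pairs tibble with columns `trait` and `gene`; default: all
#'   trait-gene combinations.
#' @return A tibble `trait`, `gene`, `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`.
#' @export
trait_gene_regression <- function(traits, expr, pairs = NULL) {
  trait_cols <- setdiff(names(traits), c("sample", "group"))
  trait_cols <- trait_cols[vapply(traits[trait_cols], is.numeric, logical(1))]
  sample_cols <- intersect(traits$sample, names(expr))
  if (length(sample_cols) < 3) {
    stop("fewer than 3 paired samples between traits and expression")
  }
  if (is.null(pairs)) {
    pairs <- tidyr::expand_grid(trait = trait_cols, gene = expr$gene)
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    tr <- pairs$trait[[i]]; g <- pairs$gene[[i]]
    row <- expr[expr$gene == g, , drop = FALSE]
    if (!nrow(row) || !tr %in% trait_cols) {
      return(tibble::tibble(trait = tr, gene = g, slope = NA_real_,
                            intercept = NA_real_, r_squared = NA_real_,
                            p_value = NA_real_, n = 0L))
    }
    x <- as.numeric(row[1, sample_cols])
    y <- traits[[tr]][match(sample_cols, traits$sample)]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) stop("fewer than 3 paired observations for ",
                          tr, " ~ ", g)
    fit <- stats::lm(y[ok] ~ x[ok])
    sm <- summary(fit)
    pv <- if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_
    tibble::tibble(trait = tr, gene = g,
                   slope = unname(stats::coef(fit)[2]),
                   intercept = unname(stats::coef(fit)[1]),
                   r_squared = sm$r.squared, p_value = pv,
                   n = sum(ok))
  })
  dplyr::bind_rows(res)
}

#' Fold ratio of CDX1 expression between groups
#'
#' Ratio of arithmetic group means of linear-scale expression values
#' (high over low).
#'
#' @param values numeric vector of linear-scale expression values.
#' @param groups character vector (`"high"`/`"low"`) parallel to `values`.
#' @return The fold ratio (numeric scalar).
#' @examples
#' ref <- cdx1_reference_values()
#' cdx1_fold_ratio(ref$cdx1_mrna, ref$group) # ~65
#' @export
cdx1_fold_ratio <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  mh <- mean(values[groups == "high"])
  ml <- mean(values[groups == "low"])
  if (!is.finite(ml) || ml == 0) stop("low-group mean is zero or undefined")
  mh / ml
}
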