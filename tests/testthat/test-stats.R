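mk_traits <- function(high, low, trait = "T1") {
  n1 <- length(high); n2 <- length(low)
  df <- tibble::tibble(sample = c(sprintf("h%d", 1:n1), sprintf("l%d", 1:n2)),
                       value = c(high, low))
  names(df)[2] <- trait
  df
}
mk_groups <- function(n1, n2) {
  tibble::tibble(sample = c(sprintf("h%d", 1:n1), sprintf("l%d", 1:n2)),
                 group = c(rep("high", n1), rep("low", n2)))
}

test_that("Mann-Whitney matches hand enumeration on separated groups", {
  tr <- mk_traits(c(1, 2, 3), c(4, 5, 6))
  res <- mann_whitney_traits(tr, mk_groups(3, 3))
  expect_equal(res$p_raw, 0.1)   # 2/20 labelings as extreme
  expect_equal(res$statistic, 0) # high group fully below
  expect_equal(res$p_raw, oracle_mw_pvalue(c(1, 2, 3), c(4, 5, 6)))
})

test_that("identical groups give the central statistic and p = 1", {
  tr <- mk_traits(c(1, 2, 3), c(1, 2, 3))
  res <- suppressWarnings(mann_whitney_traits(tr, mk_groups(3, 3)))
  expect_equal(res$statistic, 3 * 3 / 2)
  expect_equal(res$p_raw, 1)
})

test_that("constant traits warn and return p = 1", {
  tr <- mk_traits(c(5, 5, 5), c(5, 5, 5))
  expect_warning(res <- mann_whitney_traits(tr, mk_groups(3, 3)), "constant")
  expect_equal(res$p_raw, 1)
})

test_that("exact Mann-Whitney equals full enumeration for all n1, n2 <= 6", {
  set.seed(11)
  for (rep in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- round(runif(n1, 0, 100), 3)
    y <- round(runif(n2, 0, 100), 3)
    tr <- mk_traits(x, y)
    res <- mann_whitney_traits(tr, mk_groups(n1, n2))
    expect_equal(res$p_raw, oracle_mw_pvalue(x, y), tolerance = 1e-12)
  }
})

test_that("Bonferroni uses the trait family and stays within bounds", {
  tr <- dplyr::bind_cols(mk_traits(c(1, 2, 3), c(4, 5, 6)),
                         tibble::tibble(T2 = c(9, 1, 5, 4, 2, 8),
                                        T3 = c(2, 1, 3, 9, 8, 7)))
  res <- mann_whitney_traits(tr, mk_groups(3, 3))
  expect_equal(res$n_tests, rep(3, 3))
  expect_equal(res$p_bonferroni, pmin(res$p_raw * 3, 1))
  expect_true(all(res$p_bonferroni >= res$p_raw))
  expect_true(all(res$p_bonferroni <= 1))
})

test_that("PCA separates constructed point clouds along PC1", {
  set.seed(3)
  comps <- sprintf("C%02d", 1:10)
  mk <- function(center, n, label) {
    purrr::map_dfr(seq_len(n), function(i) {
      ab <- abs(center + rnorm(10, 0, 0.5))
      tibble::tibble(sample = sprintf("%s%d", label, i), composition = comps,
                     rel_abundance = 100 * ab / sum(ab))
    })
  }
  profiles <- dplyr::bind_rows(mk(c(rep(10, 5), rep(1, 5)), 5, "a"),
                               mk(c(rep(1, 5), rep(10, 5)), 5, "b"))
  pca <- pca_profiles(profiles, n_components = 2)
  pc1 <- pca$scores$PC1
  a <- pc1[grepl("^a", pca$scores$sample)]
  b <- pc1[grepl("^b", pca$scores$sample)]
  expect_true(max(a) < min(b) || max(b) < min(a))
})

test_that("explained variance is complete and non-increasing", {
  set.seed(4)
  profiles <- tidyr::expand_grid(sample = sprintf("s%d", 1:6),
                                 composition = sprintf("C%d", 1:4))
  profiles$rel_abundance <- runif(nrow(profiles), 1, 50)
  pca <- pca_profiles(profiles, n_components = 4)
  expect_true(all(diff(pca$explained_variance) <= 1e-12))
  full <- pca_profiles(profiles, n_components = 4, scale. = FALSE)
  expect_equal(sum(full$sdev^2) / sum(full$sdev^2), 1)
  # reconstruction at full rank
  wide <- tidyr::pivot_wider(profiles, names_from = composition,
                             values_from = rel_abundance)
  m <- scale(as.matrix(wide[, -1]), center = TRUE, scale = TRUE)
  scores <- as.matrix(pca$scores[, -1])
  loads <- as.matrix(pca$loadings[, -1])
  recon <- scores %*% t(loads)
  expect_equal(unname(recon), unname(m[, pca$loadings$composition]),
               tolerance = 1e-8)
})

test_that("components beyond the rank are truncated with a warning", {
  profiles <- dplyr::bind_rows(
    tibble::tibble(sample = "s1", composition = c("A", "B", "C"),
                   rel_abundance = c(10, 20, 70)),
    tibble::tibble(sample = "s2", composition = c("A", "B", "C"),
                   rel_abundance = c(30, 30, 40)),
    tibble::tibble(sample = "s3", composition = c("A", "B", "C"),
                   rel_abundance = c(10, 20, 70)))
  expect_warning(pca <- pca_profiles(profiles, n_components = 3),
                 "exceeds rank")
  expect_lte(pca$n_components, 2)
})

test_that("gene differential testing handles nulls, missing genes, folds", {
  d <- cohort_design(n_high = 4, n_low = 4, seed = 8)
  em <- generate_expression_matrix(d)
  res <- gene_differential(em$expr, em$groups,
                           genes = c("GMDS", "NOT_A_GENE"))
  expect_true(res$missing[res$gene == "NOT_A_GENE"])
  expect_false(res$missing[res$gene == "GMDS"])
  expect_equal(res$n_tests[1], 1)

  # identical groups: p = 1, fold = 1
  expr <- tibble::tibble(gene = "G1", s1 = 5, s2 = 5, s3 = 5, s4 = 5)
  groups <- tibble::tibble(sample = c("s1", "s2", "s3", "s4"),
                           group = c("high", "high", "low", "low"))
  r <- gene_differential(expr, groups, genes = "G1")
  expect_equal(r$p_raw, 1)
  expect_equal(r$fold_change, 1)
})

test_that("trait-gene regression matches the closed-form normal equations", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2.1, 3.9, 6.2, 7.8, 10.1)
  traits <- tibble::tibble(sample = sprintf("s%d", 1:5), T1 = y)
  expr <- tibble::tibble(gene = "G1", s1 = x[1], s2 = x[2], s3 = x[3],
                         s4 = x[4], s5 = x[5])
  res <- trait_gene_regression(traits, expr,
                               pairs = tibble::tibble(trait = "T1",
                                                      gene = "G1"))
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  expect_equal(res$slope, slope, tolerance = 1e-12)
  expect_equal(res$intercept, mean(y) - slope * mean(x), tolerance = 1e-12)
  expect_equal(res$r_squared, cor(x, y)^2, tolerance = 1e-12)

  # exact collinearity
  traits2 <- tibble::tibble(sample = sprintf("s%d", 1:5), T1 = 2 * x + 1)
  res2 <- suppressWarnings(   # lm flags the deliberately perfect fit
    trait_gene_regression(traits2, expr,
                          pairs = tibble::tibble(trait = "T1", gene = "G1")))
  expect_equal(res2$r_squared, 1, tolerance = 1e-12)
  expect_lt(res2$p_value, 1e-10)
})

test_that("regression refuses fewer than three paired samples", {
  traits <- tibble::tibble(sample = c("s1", "s2"), T1 = c(1, 2))
  expr <- tibble::tibble(gene = "G1", s1 = 1, s2 = 2)
  expect_error(trait_gene_regression(traits, expr), "fewer than 3")
})

test_that("permuted pairing destroys a real trait-gene association", {
  set.seed(9)
  x <- rnorm(16)
  y <- 3 * x + rnorm(16, 0, 0.5)
  samples <- sprintf("s%d", 1:16)
  traits <- tibble::tibble(sample = samples, T1 = y)
  expr <- dplyr::bind_cols(tibble::tibble(gene = "G1"),
                           tibble::as_tibble(as.list(setNames(x, samples))))
  obs <- trait_gene_regression(traits, expr)$r_squared
  perm <- replicate(200, {
    tp <- traits
    tp$T1 <- sample(tp$T1)
    trait_gene_regression(tp, expr)$r_squared
  })
  expect_gt(obs, quantile(perm, 0.99))
})

test_that("the reference CDX1 table yields the published fold ratio", {
  ref <- cdx1_reference_values()
  expect_equal(round(cdx1_fold_ratio(ref$cdx1_mrna, ref$group)), 65)
  expect_equal(cdx1_fold_ratio(c(4, 7, 4, 7), c("high", "low", "low", "high")),
               1)
  expect_error(cdx1_fold_ratio(c(1, 0), c("high", "low")), "zero")
  # documented behaviour: ratio of means, not mean of ratios
  v <- c(10, 30, 1, 2)
  g <- c("high", "high", "low", "low")
  expect_equal(cdx1_fold_ratio(v, g), 20 / 1.5)
  expect_false(isTRUE(all.equal(cdx1_fold_ratio(v, g), mean(c(10 / 1, 30 / 2)))))
})
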