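test_that("generation is deterministic given design and seed", {
  d <- cohort_design(n_high = 2, n_low = 2, seed = 3)
  a <- generate_profiles(d)
  b <- generate_profiles(d)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$trait_truth, b$trait_truth)
})

test_that("profiles are normalized, non-negative, and match drawn traits", {
  for (seed in c(2, 9)) {
    cc <- generate_profiles(cohort_design(n_high = 3, n_low = 3, seed = seed))
    sums <- tapply(cc$profiles$rel_abundance, cc$profiles$sample, sum)
    expect_equal(as.numeric(sums), rep(100, 6), tolerance = 1e-9)
    expect_true(all(cc$profiles$rel_abundance >= 0))
    # allocation honours the drawn trait values well within 1 point
    expect_lt(max(abs(cc$trait_truth$drawn - cc$trait_truth$achieved)), 1)
  }
})

test_that("zero-spread cohort lands on the group targets", {
  d <- cohort_design(n_high = 1, n_low = 1,
                     trait_targets = reference_trait_targets(sd = 0), seed = 4)
  cc <- generate_profiles(d)
  t <- reference_trait_targets()
  for (g in c("high", "low")) {
    tt <- cc$trait_truth[cc$trait_truth$group == g, ]
    target <- if (g == "high") t$mean_high else t$mean_low
    expect_equal(unname(tt$achieved[match(t$trait, tt$trait)]), target,
                 tolerance = 0.01)
  }
})

test_that("infeasible trait targets are rejected before sampling", {
  t <- reference_trait_targets()
  t$mean_high[t$trait == "Sia23"] <- 60   # sialylation beyond galactosylation
  t$mean_high[t$trait == "Sia26"] <- 40
  expect_error(cohort_design(trait_targets = t), "infeasible|exceeds")

  t2 <- reference_trait_targets()
  t2$mean_high[t2$trait == "HighMannose"] <- 70  # no room for 54% multifuc
  expect_error(cohort_design(trait_targets = t2), "infeasible|exceeds|room")
})

test_that("null designs do not fabricate group differences", {
  d <- cohort_design(n_high = 6, n_low = 6,
                     trait_targets = null_trait_targets(), seed = 21)
  draws <- draw_trait_values(d)
  mw <- mann_whitney_traits(draws, draws[, c("sample", "group")])
  expect_true(all(mw$p_raw > 0.001, na.rm = TRUE))
})

test_that("rendered isotope envelopes conserve the isotopic fractions", {
  p <- tibble::tibble(composition = "H5N2", rel_abundance = 100)
  par <- render_params(mz_range = c(1240, 1280), delta_mz = 0.005,
                       baseline_amplitude = 0, noise_sd = 0,
                       miscalibration = c(0, 0, 0, 0),
                       intensity_scale = 1e6, n_isotopes = 5)
  s <- render_spectrum(p, par)
  pat <- isotopic_pattern("H5N2", k = 5)
  areas <- vapply(pat$mz, function(cm) {
    sel <- s$mz >= cm - 0.3 & s$mz <= cm + 0.3
    sum(s$intensity[sel]) * 0.005
  }, numeric(1))
  expect_equal(areas / sum(areas), pat$fraction / sum(pat$fraction),
               tolerance = 1e-3)
  expect_equal(sum(areas), 1e6, tolerance = 0.01)
})

test_that("zero-intensity profiles render to baseline plus noise", {
  p <- tibble::tibble(composition = "H5N2", rel_abundance = 0)
  par <- render_params(mz_range = c(1200, 1300), delta_mz = 0.01,
                       baseline_amplitude = 100, noise_sd = 5,
                       intensity_scale = 0)
  s <- render_spectrum(p, par, seed = 1)
  expect_lt(max(s$intensity), 100 * 1.05 + 5 * 6)
  s2 <- render_spectrum(p, par, seed = 1)
  expect_identical(s$intensity, s2$intensity)  # seeded determinism
})

test_that("out-of-range compositions are omitted with a warning", {
  p <- tibble::tibble(composition = c("H5N2", "H9N8F2"),
                      rel_abundance = c(50, 50))
  par <- render_params(mz_range = c(1200, 1300), delta_mz = 0.01)
  expect_warning(s <- render_spectrum(p, par, seed = 1), "H9N8F2")
  truth <- attr(s, "rendered_truth")
  expect_false(truth$rendered[truth$composition == "H9N8F2"])
})

test_that("expression matrix recovers specified fold changes exactly at zero noise", {
  d <- cohort_design(n_high = 4, n_low = 4, seed = 6)
  gs <- default_gene_spec(noise_sd = 0)
  em <- generate_expression_matrix(d, gene_spec = gs)
  res <- gene_differential(em$expr, em$groups, genes = gs$gene)
  expect_equal(res$fold_change, em$truth$fold_change, tolerance = 1e-12)
  # GMDS encodes the ~3.7-fold shift
  expect_equal(res$fold_change[res$gene == "GMDS"], 3.7, tolerance = 0.01)
})

test_that("duplicate gene identifiers are rejected", {
  gs <- default_gene_spec()
  gs <- rbind(gs, gs[1, ])
  expect_error(generate_expression_matrix(cohort_design(seed = 1), gs),
               "duplicate")
})

test_that("simulated CDX1 mirrors the reference two-group ratio", {
  d <- cohort_design(n_high = 8, n_low = 8, seed = 13)
  em <- generate_expression_matrix(d)
  cdx1 <- 2^as.numeric(em$expr[em$expr$gene == "CDX1", em$groups$sample])
  ratio <- cdx1_fold_ratio(cdx1, em$groups$group)
  ref <- cdx1_reference_values()
  ref_ratio <- cdx1_fold_ratio(ref$cdx1_mrna, ref$group)
  # lognormal draws at n = 8: same order of magnitude, not exact
  expect_gt(ratio, ref_ratio / 4)
  expect_lt(ratio, ref_ratio * 4)
})
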