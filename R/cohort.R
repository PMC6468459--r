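#' Trait targets emulating the two-group cell-line contrast
#'
#' Per-group means (percent) for the derived traits the generator controls,
#' encoding the reported contrast between CDX1-high and CDX1-low colorectal
#' cancer cell lines: higher multi-fucosylation and HexNAc-rich glycans in
#' the high group, lower sialylation (especially alpha2,3-linked) and
#' galactosylation.  The between-line spread (`sd`, percentage points) is a
#' free generator parameter, set to 8 for every trait; boxplot-only source
#' data give no spreads.
#'
#' @param sd between-sample standard deviation in percentage points,
#'   recycled across traits.
#' @return A tibble with columns `trait`, `mean_high`, `mean_low`, `sd`.
#' @export
reference_trait_targets <- function(sd = 8) {
  tibble::tibble(
    trait = c("MultiFuc", "SialylTotal", "Sia23", "Sia26",
              "GalPerAntenna", "HexNAcGeHex", "HexNAcGe7", "HighMannose"),
    mean_high = c(54, 21, 11, 12, 72, 25, 27, 35),
    mean_low  = c(33, 36, 23, 18, 85, 12, 20, 45),
    sd = rep(sd, length.out = 8)
  )
}

#' Trait targets with no group difference
#'
#' Null version of [reference_trait_targets()]: both groups share the averaged
#' means.  Used for type-I-error simulations.
#'
#' @inheritParams reference_trait_targets
#' @return A tibble like [reference_trait_targets()].
#' @export
null_trait_targets <- function(sd = 8) {
  t <- reference_trait_targets(sd = sd)
  m <- (t$mean_high + t$mean_low) / 2
  t$mean_high <- m
  t$mean_low <- m
  t
}

#' Define a synthetic cohort
#'
#' @param n_high,n_low number of samples (cell lines) per group (>= 1).
#' @param replicates technical replicates rendered per sample.
#' @param trait_targets per-trait group means and spread, as from
#'   [reference_trait_targets()].
#' @param seed integer seed from which all randomness of the cohort flows.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_high = 8, n_low = 8, replicates = 3,
                          trait_targets = reference_trait_targets(),
                          seed = 1L) {
  stopifnot(n_high >= 1, n_low >= 1, replicates >= 1)
  design <- structure(
    list(n_high = as.integer(n_high), n_low = as.integer(n_low),
         replicates = as.integer(replicates),
         trait_targets = trait_targets, seed = as.integer(seed)),
    class = "cohort_design")
  validate_design(design)
  design
}

# shares of the profile assigned to non-complex, non-high-mannose species;
# drawn per sample within these bands
.pauci_share_range <- c(0.005, 0.015)
.hybrid_share_range <- c(0.015, 0.045)

#' Validate the joint feasibility of cohort trait targets
#'
#' Rejects trait-target combinations that no composition profile can
#' satisfy, e.g. per-antenna sialylation exceeding galactosylation per
#' antenna, or whole-profile fractions (multi-fucosylation, sialylation,
#' HexNAc traits) exceeding the non-high-mannose share of the profile.
#'
#' @param design a [cohort_design()].
#' @return The design, invisibly; errors on infeasibility.
#' @export
validate_design <- function(design) {
  t <- design$trait_targets
  needed <- reference_trait_targets()$trait
  if (!all(needed %in% t$trait)) {
    stop("trait_targets must cover: ", paste(needed, collapse = ", "))
  }
  for (grp in c("mean_high", "mean_low")) {
    v <- stats::setNames(t[[grp]], t$trait)
    .check_trait_vector(v, label = grp)
  }
  invisible(design)
}

.check_trait_vector <- function(v, label = "trait values") {
  if (any(v < 0 | v > 100)) {
    stop(label, ": trait values must lie in [0, 100]")
  }
  # complex share available after high-mannose and minor classes
  c_min <- 1 - v[["HighMannose"]] / 100 -
    .pauci_share_range[2] - .hybrid_share_range[2]
  if (c_min <= 0.05) {
    stop(label, ": high-mannose share leaves no room for complex glycans")
  }
  c_mid <- 1 - v[["HighMannose"]] / 100 - 0.04
  msgs <- c()
  # undergalactosylated antennae only occur in HexNAc>=Hex compositions,
  # so galactosylation per antenna is floored by the HexNAcGeHex share
  # (and capped near 1 because those species are never fully galactosylated)
  hx <- v[["HexNAcGeHex"]] / 100
  gal <- v[["GalPerAntenna"]] / 100
  if (gal < 1 - hx / c_mid - 1e-9) {
    msgs <- c(msgs, "GalPerAntenna below the floor implied by the HexNAcGeHex share")
  }
  if (gal > 1 - 0.15 * hx / c_mid + 1e-9) {
    msgs <- c(msgs, "GalPerAntenna too high for the requested HexNAcGeHex share")
  }
  if (v[["Sia23"]] + v[["Sia26"]] > v[["GalPerAntenna"]] + 1e-9) {
    msgs <- c(msgs, "per-antenna sialylation (Sia23 + Sia26) exceeds galactosylation per antenna")
  }
  if ((v[["Sia23"]] + v[["Sia26"]]) / 100 * c_min > v[["SialylTotal"]] / 100 + 1e-9) {
    msgs <- c(msgs, "alpha2,3/alpha2,6 per-antenna sialylation exceeds what overall sialylation allows")
  }
  for (tr in c("MultiFuc", "SialylTotal", "HexNAcGeHex", "HexNAcGe7")) {
    if (v[[tr]] / 100 > c_min + 1e-9) {
      msgs <- c(msgs, paste0(tr, " exceeds the available complex-glycan share"))
    }
  }
  if (length(msgs)) {
    stop(label, ": infeasible trait combination — ",
         paste(msgs, collapse = "; "))
  }
  invisible(TRUE)
}

#' Draw per-sample trait values for a cohort
#'
#' Samples the controlled traits around their group means (spread `sd` from
#' the design).  Because the trait space is structurally constrained —
#' per-antenna sialylation floors overall sialylation, and the HexNAc>=Hex
#' share floors the galactosylation deficit — the free traits (high-mannose
#' share, galactosylation, per-antenna sialylation, multi-fucosylation,
#' HexNAc>=7) are drawn first and the floored traits (overall sialylation,
#' HexNAc>=Hex) are drawn as their structural floor plus a non-negative
#' excess whose moments are chosen so the marginal group means still match
#' the targets.  A joint feasibility check rejects and redraws the rare
#' remaining violations.
#'
#' @param design a [cohort_design()].
#' @param seed integer seed, defaulting to the design's; `NULL` leaves the
#'   RNG state untouched (for use inside an outer seeded simulation).
#' @return A tibble with columns `sample`, `group`, and one column per
#'   controlled trait (percent).
#' @export
draw_trait_values <- function(design, seed = design$seed) {
  if (!is.null(seed)) set.seed(seed)
  t <- design$trait_targets
  groups <- c(rep("high", design$n_high), rep("low", design$n_low))
  samples <- sprintf("%s_%02d", groups,
                     c(seq_len(design$n_high), seq_len(design$n_low)))
  rows <- lapply(seq_along(samples), function(i) {
    mu_all <- stats::setNames(
      if (groups[[i]] == "high") t$mean_high else t$mean_low, t$trait)
    sd_all <- stats::setNames(t$sd, t$trait)
    for (try in seq_len(200)) {
      v <- .draw_one_sample(mu_all, sd_all)
      ok <- tryCatch({.check_trait_vector(v); TRUE}, error = function(e) FALSE)
      if (ok) break
    }
    if (!ok) stop("could not draw feasible trait values for sample ",
                  samples[[i]], "; targets too close to infeasibility")
    tibble::as_tibble(as.list(v[t$trait]))
  })
  dplyr::bind_cols(tibble::tibble(sample = samples, group = groups),
                   dplyr::bind_rows(rows))
}

# one sample's trait vector honouring the structural couplings; mu/sd in
# percent, named by trait
.draw_one_sample <- function(mu, sd) {
  rtr <- function(m, s, lo = 0, hi = 100) pmin(pmax(stats::rnorm(1, m, s), lo), hi)
  c_bar <- 1 - mu[["HighMannose"]] / 100 - 0.04

  hm <- rtr(mu[["HighMannose"]], sd[["HighMannose"]], 5, 90)
  cc <- 1 - hm / 100 - 0.04
  gal <- rtr(mu[["GalPerAntenna"]], sd[["GalPerAntenna"]], 5, 99)
  s3 <- rtr(mu[["Sia23"]], sd[["Sia23"]])
  s6 <- rtr(mu[["Sia26"]], sd[["Sia26"]])
  if (s3 + s6 > gal - 0.5) { # sialylated antennae must be galactosylated
    scl <- (gal - 0.5) / (s3 + s6)
    s3 <- s3 * scl; s6 <- s6 * scl
  }
  mf <- rtr(mu[["MultiFuc"]], sd[["MultiFuc"]], 0, 100 * (cc - 0.03))
  n7 <- rtr(mu[["HexNAcGe7"]], sd[["HexNAcGe7"]], 0, 100 * (cc - 0.03))

  # overall sialylation = per-antenna floor + excess
  st_floor <- (s3 + s6) * cc
  st_mu_floor <- (mu[["Sia23"]] + mu[["Sia26"]]) * c_bar
  st_var_floor <- (sd[["Sia23"]]^2 + sd[["Sia26"]]^2) * c_bar^2 +
    ((mu[["Sia23"]] + mu[["Sia26"]]) / 100 * sd[["HighMannose"]])^2
  st_delta <- max(mu[["SialylTotal"]] - st_mu_floor, 0)
  st_sd <- sqrt(max(sd[["SialylTotal"]]^2 - st_var_floor, 0))
  st <- min(st_floor + max(stats::rnorm(1, st_delta, st_sd), 0),
            100 * (cc - 0.02))

  # HexNAc>=Hex = galactosylation-deficit floor + excess
  hx_floor <- (1 - gal / 100) * cc * 100
  hx_mu_floor <- (1 - mu[["GalPerAntenna"]] / 100) * c_bar * 100
  hx_var_floor <- (sd[["GalPerAntenna"]] * c_bar)^2 +
    ((1 - mu[["GalPerAntenna"]] / 100) * sd[["HighMannose"]])^2
  hx_delta <- max(mu[["HexNAcGeHex"]] - hx_mu_floor, 0)
  hx_sd <- sqrt(max(sd[["HexNAcGeHex"]]^2 - hx_var_floor, 0))
  hx <- min(hx_floor + max(stats::rnorm(1, hx_delta, hx_sd), 0),
            100 * (cc - 0.02))

  c(MultiFuc = mf, SialylTotal = st, Sia23 = s3, Sia26 = s6,
    GalPerAntenna = gal, HexNAcGeHex = hx, HexNAcGe7 = n7, HighMannose = hm)
}
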