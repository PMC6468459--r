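#' Synthetic composition library
#'
#' The species pool the generator allocates abundance over: the high-mannose
#' series H5-9N2, minor paucimannose and hybrid species, and a curated set of
#' complex-type glycans spanning 0-4 fucoses, 0-2 lactonized (alpha2,3) and
#' 0-2 ethyl-esterified (alpha2,6) sialic acids, under- and fully
#' galactosylated antennae, HexNAc-rich (bisecting/LacdiNAc-like) variants,
#' and highly branched species with seven or more HexNAc.  Smaller than a
#' real cell-line peak list by design; extend by passing extra compositions.
#'
#' @param extra character vector of additional compositions to include.
#' @return A feature tibble as from [glycan_features()].
#' @export
glycan_library <- function(extra = character()) {
  # curated so that no two envelopes collide in 3-isotope extraction: all
  # pairwise monoisotopic gaps below 4.5 Da stay at least 0.22 Da away from
  # every multiple of the isotopologue spacing (drops e.g. the classic
  # Hex+HexNAc+lactone vs. two-ethyl-ester near-isobar, 0.036 Da apart)
  species <- c(
    # high-mannose
    "H5N2", "H6N2", "H7N2", "H8N2", "H9N2",
    # paucimannose and hybrid
    "H3N2F1", "H4N2", "H5N3", "H6N3", "H7N3",
    # complex, neutral
    "H3N4", "H4N4", "H5N4", "H4N5", "H5N5", "H6N5", "H7N6",
    # complex, HexNAc-rich
    "H3N5", "H5N6", "H3N4F1", "H4N5F1", "H3N4F2", "H3N5F2",
    "H4N4F2", "H4N5F2", "H4N5F3", "H5N5F2",
    # complex, fucosylated
    "H5N4F1", "H6N5F1", "H7N6F1", "H5N4F2", "H5N4F3", "H6N5F2",
    "H6N5F3", "H6N5F4", "H7N6F2", "H7N6F4",
    # complex, alpha2,3-sialylated
    "H5N4L1", "H5N4L2", "H6N5L2", "H7N6L2", "H5N4F1L1", "H5N4F2L1",
    "H6N5F3L1",
    # complex, alpha2,6-sialylated
    "H5N4E1", "H5N4E2", "H6N5E2", "H7N6E2", "H5N4F2E1", "H6N5F2E1",
    # complex, mixed linkage
    "H5N4L1E1", "H6N5L1E1", "H6N5L2E1",
    # complex, sialylated and multi-fucosylated
    "H5N4F2L2", "H5N4F2L1E1", "H6N5F2E2",
    # complex, >= 7 HexNAc (branched / poly-LacNAc-like)
    "H6N7", "H7N7", "H6N7F2", "H7N7F2", "H7N7L1",
    "H7N7E1", "H7N7L2", "H7N7F2L1", "H7N7F2E1", "H7N8F2",
    "H8N7", "H8N7F2", "H8N7F3", "H8N7E1", "H8N7F2L1",
    "H8N7F2E1", "H9N8", "H9N8F2"
  )
  glycan_features(unique(c(species, extra)))
}

# solve W a = targets, a >= 0: ridge-regularized non-negative least squares
# anchored at the random start a0, polished by cyclic projections onto the
# constraint hyperplanes intersected with the non-negative orthant;
# returns abundance fractions or NULL when the system is not met to 1e-9
.allocate_constrained <- function(a0, W, targets,
                                  constraint_scale = 50, ridge = 0.05,
                                  polish_iter = 3000) {
  n <- ncol(W)
  A <- rbind(W * constraint_scale, diag(sqrt(ridge), n))
  b <- c(targets * constraint_scale, sqrt(ridge) * a0)
  a <- tryCatch(pracma::lsqnonneg(A, b)$x, error = function(e) NULL)
  if (is.null(a)) a <- a0
  wnorm <- rowSums(W^2)
  prev <- Inf
  for (iter in seq_len(polish_iter)) {
    for (j in seq_along(targets)) {
      resid <- targets[[j]] - sum(W[j, ] * a)
      a <- a + resid / wnorm[[j]] * W[j, ]
    }
    a[a < 0] <- 0
    if (iter %% 20 == 0) {
      r <- max(abs(W %*% a - targets))
      if (r < 1e-9) return(a)
      # bail out early when the projections have stalled (infeasible draw)
      if (iter >= 200 && r > 0.9 * prev) break
      prev <- r
    }
  }
  if (max(abs(W %*% a - targets)) < 1e-7) a else NULL
}

# build the constraint matrix for one sample's trait vector; v is the named
# trait vector (percent), shares gives pauci/hybrid shares (fractions)
.trait_constraints <- function(lib, v, shares) {
  cx <- lib$class == "complex"
  c_share <- 1 - v[["HighMannose"]] / 100 - shares[["pauci"]] - shares[["hybrid"]]
  ant <- ifelse(cx, lib$antennae, 1)
  W <- rbind(
    total    = rep(1, nrow(lib)),
    hm       = as.numeric(lib$class == "high-mannose"),
    pauci    = as.numeric(lib$class == "paucimannose"),
    hybrid   = as.numeric(lib$class == "hybrid"),
    multifuc = as.numeric(lib$F >= 2),
    sialyl   = as.numeric(lib$L + lib$E >= 1),
    hexgehex = as.numeric(cx & lib$N >= lib$H),
    hexge7   = as.numeric(lib$N >= 7),
    sia23    = ifelse(cx, lib$L / ant, 0),
    sia26    = ifelse(cx, lib$E / ant, 0),
    gal      = ifelse(cx, lib$galactoses / ant, 0)
  )
  targets <- c(
    total = 1,
    hm = v[["HighMannose"]] / 100,
    pauci = shares[["pauci"]],
    hybrid = shares[["hybrid"]],
    multifuc = v[["MultiFuc"]] / 100,
    sialyl = v[["SialylTotal"]] / 100,
    hexgehex = v[["HexNAcGeHex"]] / 100,
    hexge7 = v[["HexNAcGe7"]] / 100,
    sia23 = v[["Sia23"]] / 100 * c_share,
    sia26 = v[["Sia26"]] / 100 * c_share,
    gal = v[["GalPerAntenna"]] / 100 * c_share
  )
  list(W = W, targets = targets)
}

# random interior starting point: Dirichlet weights within each class,
# scaled to the class shares implied by the trait vector
.allocation_start <- function(lib, v, shares) {
  w <- stats::rgamma(nrow(lib), shape = 1) + 1e-3
  cls <- lib$class
  share_of <- c("high-mannose" = v[["HighMannose"]] / 100,
                "paucimannose" = shares[["pauci"]],
                "hybrid" = shares[["hybrid"]])
  share_of["complex"] <- 1 - sum(share_of)
  a <- numeric(nrow(lib))
  for (k in names(share_of)) {
    sel <- cls == k
    a[sel] <- w[sel] / sum(w[sel]) * share_of[[k]]
  }
  a
}

#' Generate a cohort of glycan profiles with known truth
#'
#' Draws per-sample trait values around the group targets
#' ([draw_trait_values()]), then allocates relative abundances over the
#' composition library by cyclic projection onto the linear constraints the
#' trait formulas induce, so that the derived traits computed from each
#' generated profile match the drawn values to well within 1 percentage
#' point.  Profiles sum to 100% per sample.
#'
#' @param design a [cohort_design()].
#' @param library composition feature table, default [glycan_library()].
#' @param seed integer seed (defaults to the design's; `NULL` to use the
#'   current RNG state).
#' @return A list of class `glyco_cohort` with elements `profiles` (tibble:
#'   `sample`, `group`, `composition`, `rel_abundance` in percent),
#'   `trait_truth` (tibble: `sample`, `group`, `trait`, `drawn`,
#'   `achieved`), and `design`.
#' @export
generate_profiles <- function(design, library = glycan_library(),
                              seed = design$seed) {
  validate_design(design)
  if (!is.null(seed)) set.seed(seed)
  drawn <- draw_trait_values(design, seed = NULL)
  trait_cols <- setdiff(names(drawn), c("sample", "group"))
  profiles <- list()
  truth <- list()
  for (i in seq_len(nrow(drawn))) {
    v <- unlist(drawn[i, trait_cols])
    a <- NULL
    for (try in seq_len(80)) {
      shares <- c(pauci = stats::runif(1, .pauci_share_range[1],
                                       .pauci_share_range[2]),
                  hybrid = stats::runif(1, .hybrid_share_range[1],
                                        .hybrid_share_range[2]))
      con <- .trait_constraints(library, v, shares)
      a <- .allocate_constrained(.allocation_start(library, v, shares),
                                 con$W, con$targets)
      if (!is.null(a)) break
      # two tries per trait draw, then redraw the trait vector itself
      if (try %% 2 == 0) {
        t <- design$trait_targets
        mu <- stats::setNames(
          if (drawn$group[[i]] == "high") t$mean_high else t$mean_low,
          t$trait)
        sdv <- stats::setNames(t$sd, t$trait)
        for (k in seq_len(200)) {
          vv <- .draw_one_sample(mu, sdv)
          if (tryCatch({.check_trait_vector(vv); TRUE},
                       error = function(e) FALSE)) break
        }
        v <- vv[trait_cols]
      }
    }
    if (is.null(a)) {
      stop("allocation failed for sample ", drawn$sample[[i]],
           ": drawn trait values admit no profile over the library")
    }
    keep <- a > 1e-8
    profiles[[i]] <- tibble::tibble(
      sample = drawn$sample[[i]], group = drawn$group[[i]],
      composition = library$composition[keep],
      rel_abundance = 100 * a[keep] / sum(a[keep]))
    achieved <- compute_traits(profiles[[i]])
    truth[[i]] <- tibble::tibble(
      sample = drawn$sample[[i]], group = drawn$group[[i]],
      trait = trait_cols, drawn = unname(v),
      achieved = unlist(achieved[1, trait_cols]))
  }
  structure(list(profiles = dplyr::bind_rows(profiles),
                 trait_truth = dplyr::bind_rows(truth),
                 design = design),
            class = "glyco_cohort")
}
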