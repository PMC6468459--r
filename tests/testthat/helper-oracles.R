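# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: brute-force convolution, exhaustive search,
# full enumeration, and element-level mass summation.

# IUPAC monoisotopic atomic masses, written down independently of the
# package's constant table
oracle_atomic_mass <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
                        O = 15.9949146221, Na = 22.98976928)
oracle_electron <- 0.000549

oracle_isotopes <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  Na = c(1)
)

# isotopologue distribution by convolving one atom at a time (slow, naive)
oracle_pattern <- function(counts) {
  dist <- 1
  for (el in names(counts)) {
    p <- oracle_isotopes[[el]]
    for (k in seq_len(counts[[el]])) {
      out <- numeric(length(dist) + length(p) - 1)
      for (i in seq_along(dist)) {
        out[i:(i + length(p) - 1)] <- out[i:(i + length(p) - 1)] + dist[i] * p
      }
      dist <- out
    }
  }
  dist / sum(dist)
}

# element-level mass of a sodiated composition, from residue formulas
# written out independently
oracle_composition_mass <- function(H = 0, N = 0, F = 0, L = 0, E = 0) {
  f <- c(C = 0, H = 0, N = 0, O = 0, Na = 0)
  add <- function(f, v, times) f + v * times
  f <- add(f, c(C = 6, H = 10, N = 0, O = 5, Na = 0), H)   # hexose
  f <- add(f, c(C = 8, H = 13, N = 1, O = 5, Na = 0), N)   # HexNAc
  f <- add(f, c(C = 6, H = 10, N = 0, O = 4, Na = 0), F)   # deoxyhexose
  f <- add(f, c(C = 11, H = 15, N = 1, O = 7, Na = 0), L)  # NeuAc - H2O
  f <- add(f, c(C = 13, H = 21, N = 1, O = 8, Na = 0), E)  # NeuAc + C2H4
  f <- f + c(C = 0, H = 2, N = 0, O = 1, Na = 1)           # + H2O + Na
  sum(f * oracle_atomic_mass) - oracle_electron
}

# exhaustive nested-loop composition search over the bound box
oracle_enumerate <- function(target, tol_ppm, bounds) {
  grid <- expand.grid(H = 0:bounds[["H"]], N = 0:bounds[["N"]],
                      F = 0:bounds[["F"]], L = 0:bounds[["L"]],
                      E = 0:bounds[["E"]])
  mz <- apply(grid, 1, function(r) {
    oracle_composition_mass(r[["H"]], r[["N"]], r[["F"]], r[["L"]], r[["E"]])
  })
  ppm <- (mz - target) / target * 1e6
  hit <- abs(ppm) <= tol_ppm
  out <- grid[hit, , drop = FALSE]
  out$mz <- mz[hit]
  out[order(abs(ppm[hit])), ]
}

# exact two-sided Mann-Whitney p-value by full enumeration of labelings
oracle_mw_pvalue <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * n2 / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# 19 printed calibrant m/z values (composition, printed m/z)
printed_calibrants <- function() {
  tibble::tribble(
    ~composition, ~printed_mz,
    "H5N2",     1257.423,
    "H6N2",     1419.476,
    "H7N2",     1581.529,
    "H8N2",     1743.581,
    "H5N4F1",   1809.639,
    "H5N4F2",   1955.697,
    "H5N4E1",   1982.709,
    "H10N2",    2067.687,
    "H6N5F1",   2174.7715,
    "H5N4L1E1", 2255.793,
    "H5N4E2",   2301.835,
    "H6N5E1",   2347.8403,
    "H7N6F1",   2539.904,
    "H6N5F4",   2612.945,
    "H6N5L1E1", 2620.925,
    "H7N6E1",   2712.973,
    "H7N6L2",   2940.016,
    "H9N8",     3124.111,
    "H7N6L4F1", 3632.243
  )
}

# small fast render parameters for processing tests: narrow window around
# the analytes of interest keeps spectra to a few thousand points
test_render_params <- function(mz_range = c(1000, 3000), ...) {
  render_params(mz_range = mz_range, delta_mz = 0.02, ...)
}
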