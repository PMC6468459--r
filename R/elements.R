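# Elemental constants used by the mass engine.
#
# Monoisotopic masses and isotope abundances are IUPAC 2021 representative
# values, pinned here as the single source of truth for the package.

# masses of the lightest isotope of each element (Da)
.element_mono_mass <- c(
  C  = 12.0,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  Na = 22.98976928
)

# isotope abundance tables: per element, fractions by nucleon offset 0,1,2,...
.element_isotopes <- list(
  C  = c(0.9893, 0.0107),
  H  = c(0.999885, 0.000115),
  N  = c(0.99636, 0.00364),
  O  = c(0.99757, 0.00038, 0.00205),
  Na = c(1.0)
)

.electron_mass <- 0.000549

# default average spacing between consecutive isotopologue peaks (Da)
.default_isotope_spacing <- 1.00235

# residue monoisotopic masses (Da); L = NeuAc - H2O (lactonized,
# alpha2,3-linked proxy), E = NeuAc + C2H4 (ethyl-esterified, alpha2,6 proxy)
.residue_mass <- c(
  H = 162.052824,             # hexose
  N = 203.079373,             # N-acetylhexosamine
  F = 146.057909,             # deoxyhexose (fucose)
  L = 291.095417 - 18.010565, # lactonized NeuAc
  E = 291.095417 + 28.031300  # ethyl-esterified NeuAc
)

.h2o_mass <- 18.010565
.na_mass  <- 22.989770

# residue elemental formulas (order C, H, N, O, Na)
.residue_formula <- rbind(
  H = c(C = 6,  H = 10, N = 0, O = 5, Na = 0),  # Hex C6H10O5
  N = c(C = 8,  H = 13, N = 1, O = 5, Na = 0),  # HexNAc C8H13NO5
  F = c(C = 6,  H = 10, N = 0, O = 4, Na = 0),  # dHex C6H10O4
  L = c(C = 11, H = 15, N = 1, O = 7, Na = 0),  # NeuAc - H2O
  E = c(C = 13, H = 21, N = 1, O = 8, Na = 0)   # NeuAc + C2H4
)

.residue_letters <- c("H", "N", "F", "L", "E")
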