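# Physical constants and lookup tables used across the pipeline.
# Element masses: IUPAC monoisotopic (principal isotope) and standard
# atomic weights. Stored once here, never re-typed at call sites.

.element_mass <- list(
  monoisotopic = c(
    H = 1.0078250319,
    C = 12.0,
    N = 14.0030740052,
    O = 15.9949146221,
    S = 31.97207069
  ),
  average = c(
    H = 1.00794,
    C = 12.0107,
    N = 14.0067,
    O = 15.9994,
    S = 32.065
  )
)

# Residue (not free amino acid) elemental compositions of the 20
# standard amino acids, rows H,C,N,O,S.
.residue_formula <- rbind(
  #     H  C  N  O  S
  A = c(5, 3, 1, 1, 0),
  R = c(12, 6, 4, 1, 0),
  N = c(6, 4, 2, 2, 0),
  D = c(5, 4, 1, 3, 0),
  C = c(5, 3, 1, 1, 1),
  E = c(7, 5, 1, 3, 0),
  Q = c(8, 5, 2, 2, 0),
  G = c(3, 2, 1, 1, 0),
  H = c(7, 6, 3, 1, 0),
  I = c(11, 6, 1, 1, 0),
  L = c(11, 6, 1, 1, 0),
  K = c(12, 6, 2, 1, 0),
  M = c(9, 5, 1, 1, 1),
  F = c(9, 9, 1, 1, 0),
  P = c(7, 5, 1, 1, 0),
  S = c(5, 3, 1, 2, 0),
  T = c(7, 4, 1, 2, 0),
  W = c(10, 11, 2, 1, 0),
  Y = c(9, 9, 1, 2, 0),
  V = c(9, 5, 1, 1, 0)
)
colnames(.residue_formula) <- c("H", "C", "N", "O", "S")

.formula_mass <- function(counts, mode) {
  elem <- .element_mass[[mode]]
  sum(counts * elem[colnames(.residue_formula)])
}

.residue_mass_table <- function(mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  apply(.residue_formula, 1L, .formula_mass, mode = mode)
}

.water_mass <- function(mode = c("monoisotopic", "average")) {
  mode <- match.arg(mode)
  elem <- .element_mass[[mode]]
  2 * elem[["H"]] + elem[["O"]]
}

# Charge carriers and modification deltas (Da). Proton and Na+ are ion
# masses (electron already subtracted for Na).
.PROTON_MASS <- 1.007276
.SODIUM_CATION_MASS <- 22.989218

.mod_delta <- function(what = c("NH3", "acetyl"),
                       mode = c("monoisotopic", "average")) {
  what <- match.arg(what)
  mode <- match.arg(mode)
  elem <- .element_mass[[mode]]
  switch(what,
    NH3 = elem[["N"]] + 3 * elem[["H"]],
    acetyl = 2 * elem[["C"]] + 2 * elem[["H"]] + elem[["O"]]
  )
}

# Kyte-Doolittle hydropathy scale.
.KD_SCALE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  E = -3.5, Q = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# ClustalW strong conservation groups (used for "similarity" columns).
.STRONG_GROUPS <- c(
  "STA", "NEQK", "NHQK", "NDEQ", "QHRK", "MILV", "MILF", "HY", "FYW"
)
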