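#' Canonical amino-acid alphabet
#'
#' The fixed class order used throughout the package: the 20 canonical
#' amino acids in alphabetical one-letter order. Every probability matrix,
#' confusion matrix and class-count vector uses this order; it is persisted
#' alongside trained models.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# three-letter -> one-letter; MSE (selenomethionine) maps to M, everything
# else non-canonical is skipped at parse time
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M"
)

AA_ONE_TO_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
  X = "UNK"
)

#' Zimmerman polarity scale
#'
#' Per-residue polarity values from Zimmerman, Eliezer and Simha (1968),
#' as tabulated in AAindex entry ZIMJ680103. Residues with a value below
#' 20 are treated as non-polar (-1), all others as polar (+1); under this
#' threshold the polar class is exactly \{R, K, H, D, E\}.
#'
#' @format Named numeric vector of length 20 (one-letter codes).
#' @export
ZIMMERMAN_POLARITY <- c(
  A = 0.00,  R = 52.00, N = 3.38,  D = 49.70, C = 1.48,
  Q = 3.53,  E = 49.90, G = 0.00,  H = 51.60, I = 0.13,
  L = 0.13,  K = 49.50, M = 1.43,  F = 0.35,  P = 1.58,
  S = 1.67,  T = 1.66,  W = 2.10,  Y = 1.61,  V = 0.13
)

# formal side-chain charge at neutral pH used for the charge constraint
# channel: D/E negative, K/R/H positive (histidine grouped with the basic
# residues), everything else neutral
AA_FORMAL_CHARGE <- c(
  A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 1, I = 0, K = 1, L = 0,
  M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0, T = 0, V = 0, W = 0, Y = 0
)

# EMBOSS pKa set for Henderson-Hasselbalch net-charge and pI calculations
EMBOSS_PKA <- list(
  positive = c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5),
  negative = c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
)

# van der Waals radii (Angstrom) for the voxelised backbone elements
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52)

aa_index <- function(aa) {
  idx <- match(aa, AA_ALPHABET)
  if (anyNA(idx)) {
    stop("unknown amino-acid code(s): ",
         paste(unique(aa[is.na(idx)]), collapse = ", "))
  }
  idx
}
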