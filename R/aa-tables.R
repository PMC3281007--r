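#' @name aa_tables
#' @title Amino acid reference tables
#' @description
#' Fixed reference tables used throughout the package: physiochemical class
#' maps, maximum accessible surface areas, van der Waals radii and a baseline
#' background amino-acid composition. Shipped as package constants so that
#' derived quantities (RSA, class propensities, synthetic sequences) are
#' reproducible bit-for-bit.
#' @keywords internal
NULL

#' One-letter codes of the 20 standard amino acids
#' @export
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Three-class physiochemical map (hydrophobic / hydrophilic / neutral)
#'
#' Partition of the 20 amino acids into hydrophobic (o), hydrophilic (i) and
#' neutral (n) classes, following the IMGT-style classification used for the
#' three-class sequence propensity features and the hydrophobic core set H.
#' @export
AA_CLASS3 <- c(
  A = "o", C = "o", F = "o", I = "o", L = "o", M = "o", V = "o", W = "o",
  R = "i", N = "i", D = "i", Q = "i", E = "i", K = "i",
  G = "n", H = "n", P = "n", S = "n", T = "n", Y = "n"
)

#' Five-class side-chain map
#'
#' Partition by side-chain chemistry: nonpolar aliphatic (a), aromatic (r),
#' polar uncharged (p), positively charged (+ coded "b"), negatively charged
#' (coded "d").
#' @export
AA_CLASS5 <- c(
  G = "a", A = "a", P = "a", V = "a", L = "a", I = "a", M = "a",
  F = "r", Y = "r", W = "r",
  S = "p", T = "p", C = "p", N = "p", Q = "p",
  K = "b", R = "b", H = "b",
  D = "d", E = "d"
)

#' Eight-state secondary structure alphabet (DSSP convention)
#' @export
SSE8_ALPHABET <- c("H", "G", "I", "E", "B", "T", "S", "-")

# Maximum accessible surface area per residue type (A^2), theoretical
# Gly-X-Gly tripeptide values of Tien et al. (2013). Used to normalise
# residue SASA into RSA percentages.
MAX_ASA <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
  Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0
)

# Heavy-atom van der Waals radii (A) by element; unlisted elements fall back
# to 1.80 A. Hydrogens are ignored everywhere in this package.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90)

# Baseline amino-acid composition (UniProtKB/Swiss-Prot average, fractions).
# Fixed reference so that sequence-enrichment simulations have a stable
# background.
AA_BACKGROUND_COMPOSITION <- c(
  A = 0.0825, R = 0.0553, N = 0.0406, D = 0.0545, C = 0.0137,
  Q = 0.0393, E = 0.0675, G = 0.0707, H = 0.0227, I = 0.0596,
  L = 0.0966, K = 0.0584, M = 0.0242, F = 0.0386, P = 0.0470,
  S = 0.0656, T = 0.0534, W = 0.0108, Y = 0.0292, V = 0.0687
)

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.80
  unname(r)
}

#' Hydrophobic amino acids (class-3 hydrophobic set)
#' @return character vector of one-letter codes
#' @export
hydrophobic_residues <- function() {
  names(AA_CLASS3)[AA_CLASS3 == "o"]
}
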