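#' Composition table: residue masses for amino acids and glycans
#'
#' Monoisotopic residue masses (Da) for the 20 standard amino acids
#' (single-letter codes) and the four glycan residue classes encountered in
#' N-linked antibody glycans. A glycan "residue" is the monosaccharide minus
#' one water, i.e. the mass the sugar contributes once attached to a chain.
#'
#' @format A named numeric vector of masses in Da.
#' @examples
#' composition_table["C"]    # cysteine residue
#' composition_table["Hex"]  # hexose (Gal, Man, Glc)
#' @export
composition_table <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931,
  Hex = 162.0528, HexNAc = 203.0794, NeuNAc = 291.0954, dHex = 146.0579
)

#' Standard water reference conditions at 20 degrees C
#'
#' Solvent constants used to standardize sedimentation coefficients to
#' s20,w: density 0.99823 g/ml and viscosity 0.010019 poise.
#'
#' @format Named numeric vector with elements `density` (g/ml),
#'   `viscosity` (poise) and `temperature` (degrees C).
#' @export
water20 <- c(density = 0.99823, viscosity = 0.010019, temperature = 20)

# Avogadro's number (1/mol), used by the hydrodynamics module.
.N_AVOGADRO <- 6.02214076e23

# one-letter -> three-letter amino acid codes (plus glycan residue names)
.AA1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)
.AA3TO1 <- structure(names(.AA1TO3), names = unname(.AA1TO3))

# average amino-acid residue mass, used for unassigned coarse beads
.MASS_UNK <- 110.0

.REGIONS <- c("FAB1", "FAB2", "FC", "HINGE", "GLYCAN")
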