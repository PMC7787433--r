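# Amino-acid level constants used across the package.

#' @noRd
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Kyte-Doolittle hydropathy (raw scale, -4.5 .. 4.5)
KD_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# Charge convention: K/R positive, D/E negative, H neutral.
AA_CHARGE <- c(
  A = 0, R = 1, N = 0, D = -1, C = 0,
  Q = 0, E = -1, G = 0, H = 0, I = 0,
  L = 0, K = 1, M = 0, F = 0, P = 0,
  S = 0, T = 0, W = 0, Y = 0, V = 0
)

# Side-chain pseudo-atom geometry for the coarse-grained conformer model.
# One bead per side chain, centred along the CA->CB direction.
#   dist  : CA -> bead centre distance (Angstrom), approximate side-chain
#           centroid distances for each residue type.
#   radius: effective bead radius (Angstrom), derived from side-chain
#           volumes (r = (3V/4pi)^(1/3) on Zamyatnin residue volumes minus
#           the backbone share) and shrunk to 85% so a single sphere does
#           not overstate the collision cross-section of an articulated
#           side chain. Glycine has no bead.
SIDECHAIN_GEOMETRY <- data.frame(
  aa     = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
             "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
  dist   = c(1.53, 4.10, 2.50, 2.50, 2.10, 3.10, 3.10, 0.00, 3.10, 2.30,
             2.60, 3.50, 2.90, 3.40, 1.90, 1.70, 1.90, 3.90, 3.80, 1.95),
  radius = c(1.57, 2.55, 2.00, 1.96, 1.83, 2.17, 2.12, 0.00, 2.30, 2.21,
             2.21, 2.34, 2.21, 2.42, 1.96, 1.70, 1.91, 2.64, 2.51, 2.04),
  stringsAsFactors = FALSE
)

# Backbone heavy-atom van der Waals radii (Angstrom).
BACKBONE_RADII <- c(N = 1.55, CA = 1.70, C = 1.70, O = 1.52)

# Idealized backbone internal coordinates (trans peptide).
BACKBONE_GEOMETRY <- list(
  b_n_ca  = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.5,
  omega = 180.0,
  # side-chain bead placement frame (improper torsion N-C-CA-SC)
  a_c_ca_sc = 110.5, t_n_c_ca_sc = 122.6
)

#' @noRd
validate_residues <- function(residues, allow_x = FALSE) {
  allowed <- AA_ALPHABET
  if (allow_x) allowed <- c(allowed, "X")
  bad <- which(!(residues %in% allowed))
  if (length(bad) > 0) {
    stop(sprintf("invalid residue letter '%s' at position %d",
                 residues[bad[1]], bad[1]), call. = FALSE)
  }
  invisible(TRUE)
}
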