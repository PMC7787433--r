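# Internal-coordinate geometry helpers shared by the conformer generator
# and the docking module.

#' @noRd
geom_vector <- function() {
  g <- BACKBONE_GEOMETRY
  c(g$b_n_ca, g$b_ca_c, g$b_c_n, g$b_c_o,
    g$a_n_ca_c, g$a_ca_c_n, g$a_c_n_ca, g$a_ca_c_o,
    g$omega, g$a_c_ca_sc, g$t_n_c_ca_sc)
}

#' Dihedral angle defined by four points
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors.
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  b2u <- b2 / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2u)
  atan2(y, x) * 180 / pi
}

#' @noRd
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Atom bookkeeping: atoms are stored in build order, N, CA, C, O and an
# optional side-chain bead per residue (absent for glycine).
#' @noRd
make_atom_table <- function(residues) {
  n <- length(residues)
  sc <- residues != "G"
  per <- 4L + as.integer(sc)
  res_index <- rep(seq_len(n), per)
  name <- unlist(lapply(seq_len(n), function(i) {
    if (sc[i]) c("N", "CA", "C", "O", "SC") else c("N", "CA", "C", "O")
  }))
  scg <- SIDECHAIN_GEOMETRY[match(residues, SIDECHAIN_GEOMETRY$aa), ]
  radius <- unlist(lapply(seq_len(n), function(i) {
    r <- unname(BACKBONE_RADII)
    if (sc[i]) c(r, scg$radius[i]) else r
  }))
  data.frame(res_index = res_index, name = name, radius = radius,
             aa = residues[res_index], stringsAsFactors = FALSE)
}

#' Rebuild chain coordinates from dihedrals
#'
#' Deterministic NeRF-style chain extension from per-residue (phi, psi)
#' using the package's idealized backbone geometry (trans peptide,
#' omega = 180). The phi of the first residue does not influence the
#' internal geometry.
#'
#' @param dihedrals Numeric matrix with columns `phi`, `psi` (degrees),
#'   one row per residue. `phi[1]` may be `NA`.
#' @param seq An [idr_seq] (or string) giving the residue types (controls
#'   side-chain bead placement).
#' @return Coordinate matrix (atoms x 3, Angstrom) in atom-table order.
#' @export
rebuild_coordinates <- function(dihedrals, seq) {
  seq <- as_idr_seq(seq)
  res <- seq$residues
  stopifnot(nrow(dihedrals) == length(res))
  scg <- SIDECHAIN_GEOMETRY[match(res, SIDECHAIN_GEOMETRY$aa), ]
  phi <- dihedrals[, 1]
  phi[1] <- 0
  .rebuild_coords_cpp(phi, dihedrals[, 2], as.integer(res != "G"),
                      scg$dist, geom_vector())
}

#' Measure backbone dihedrals from coordinates
#'
#' @param conformer An `idr_conformer` (see [build_conformer]) or a list
#'   with `coords` and `atom_table`.
#' @return Matrix (residues x 2) of (phi, psi) in degrees; `phi[1]` is `NA`
#'   and `psi` of the last residue is recovered from the carbonyl oxygen.
#' @export
measure_dihedrals <- function(conformer) {
  at <- conformer$atom_table
  xyz <- conformer$coords
  n <- max(at$res_index)
  idx <- function(r, nm) which(at$res_index == r & at$name == nm)
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("phi", "psi")))
  for (r in seq_len(n)) {
    Nr <- xyz[idx(r, "N"), ]; CAr <- xyz[idx(r, "CA"), ]
    Cr <- xyz[idx(r, "C"), ]
    if (r > 1) {
      Cp <- xyz[idx(r - 1, "C"), ]
      out[r, 1] <- dihedral_angle(Cp, Nr, CAr, Cr)
    }
    if (r < n) {
      Nn <- xyz[idx(r + 1, "N"), ]
      out[r, 2] <- dihedral_angle(Nr, CAr, Cr, Nn)
    } else {
      Or <- xyz[idx(r, "O"), ]
      psi <- dihedral_angle(Nr, CAr, Cr, Or) - 180
      out[r, 2] <- ((psi + 180) %% 360) - 180
    }
  }
  out
}
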