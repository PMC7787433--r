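# Docking-by-superposition: place a rigid ligand body onto a conformer by
# least-squares superposition of the template's motif backbone onto the
# same motif in the conformer, then count hard van der Waals clashes.

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rotation + translation mapping `from` onto `to`
#' (row-per-point matrices), with a proper rotation enforced (no
#' reflection).
#'
#' @param from,to Numeric n x 3 matrices of paired points.
#' @return List with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   of the fit, and `transform(x)`, a function applying the map to an
#'   m x 3 matrix.
#' @export
kabsch_superpose <- function(from, to) {
  stopifnot(nrow(from) == nrow(to), ncol(from) == 3, ncol(to) == 3)
  cf <- colMeans(from); ct <- colMeans(to)
  P <- sweep(from, 2, cf); Q <- sweep(to, 2, ct)
  sv_p <- svd(P)$d
  if (sv_p[2] < 1e-6 * max(sv_p[1], 1)) {
    stop("degenerate (collinear) point set: superposition is ill-defined",
         call. = FALSE)
  }
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  translation <- ct - as.numeric(R %*% cf)
  transform <- function(x) sweep(x %*% t(R), 2, translation, "+")
  list(rotation = R, translation = translation, rmsd = rmsd,
       transform = transform)
}

# Backbone (N, CA, C) atom row indices of a motif span.
#' @noRd
motif_backbone_rows <- function(atom_table, motif_start, motif_length) {
  res <- motif_start:(motif_start + motif_length - 1L)
  idx <- which(atom_table$res_index %in% res &
                 atom_table$name %in% c("N", "CA", "C"))
  if (length(idx) != 3L * motif_length) {
    stop("motif residues out of range of the conformer", call. = FALSE)
  }
  idx
}

#' Superpose a template complex onto a conformer motif
#'
#' Computes the least-squares rigid transform from the template's motif
#' backbone (N, CA, C per motif residue) onto the same motif in the
#' conformer, and applies it to the template's rigid ligand body.
#'
#' @param template An `idr_template`.
#' @param conformer An `idr_conformer`.
#' @param motif_start 1-based start residue of the motif in the conformer.
#' @return List: `ligand_coords` (placed ligand atoms), `ligand_radii`,
#'   `rmsd` (Angstrom, motif backbone fit).
#' @export
superpose_template <- function(template, conformer, motif_start) {
  m <- nrow(template$motif_dihedrals)
  rows <- motif_backbone_rows(conformer$atom_table, motif_start, m)
  fit <- kabsch_superpose(template$motif_backbone, conformer$coords[rows, ,
                                                                    drop = FALSE])
  list(ligand_coords = fit$transform(template$ligand_coords),
       ligand_radii = template$ligand_radii, rmsd = fit$rmsd)
}

#' Count hard van der Waals clashes between two atom sets
#'
#' A clash is a cross pair at distance < r_i + r_j - `overlap_tol`.
#' Spatial-grid accelerated; symmetric in its arguments.
#'
#' @param coords_a,coords_b Numeric n x 3 coordinate matrices (Angstrom).
#' @param radii_a,radii_b Atom radii.
#' @param overlap_tol Allowed overlap before a pair counts as a clash
#'   (default 0.4 Angstrom).
#' @return Integer clash count.
#' @export
count_clashes <- function(coords_a, radii_a, coords_b, radii_b,
                          overlap_tol = 0.4) {
  stopifnot(all(radii_a > 0), all(radii_b > 0))
  .count_clashes_cpp(coords_a, radii_a, coords_b, radii_b, overlap_tol)
}

# Fibonacci lattice on the unit sphere.
#' @noRd
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (sqrt(5) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi * i), r * sin(phi * i), z)
}

# Default template motif dihedrals: extended peptide conformation typical
# of a short linear motif bound in a groove.
#' @noRd
SYNTH_MOTIF_DIHEDRALS <- matrix(c(-80, 130,
                                  -65, 145,
                                  -120, 125),
                                ncol = 2, byrow = TRUE,
                                dimnames = list(NULL, c("phi", "psi")))

#' Synthetic rigid template complex
#'
#' Builds a stand-in for a crystallographic motif-ligand complex: the motif
#' backbone is generated from the given dihedrals, and the ligand body is a
#' ball of atoms of radius `ligand_radius` centred `ligand_offset`
#' Angstrom from the central motif CA along the side-chain-side normal of
#' the motif. The outer surface is a Fibonacci lattice of `n_shell_atoms`
#' atoms; with `fill = TRUE` (default) the interior is occupied by
#' concentric lattice shells 3.4 Angstrom apart plus a centre atom, so the
#' body excludes volume like a solid globular domain rather than a hollow
#' cage (chain segments inside a hollow shell would go uncounted by the
#' clash rule).
#'
#' @param motif_seq Motif peptide (e.g. `"DPW"`).
#' @param motif_dihedrals Per-motif-residue (phi, psi) matrix; default an
#'   extended bound-peptide conformation.
#' @param ligand_radius Ball radius (Angstrom), default 18 (order of
#'   magnitude of a small adaptor appendage domain).
#' @param ligand_offset Distance from central motif CA to ball centre,
#'   default 22.
#' @param n_shell_atoms Number of outer-shell atoms, default 256; interior
#'   shells scale with their surface area.
#' @param atom_radius Radius of each ligand atom, default 1.7.
#' @param fill Occupy the interior (default `TRUE`); `FALSE` gives the
#'   bare outer shell.
#' @param label Template label.
#' @return An object of class `idr_template`: `motif_backbone` (3 atoms
#'   per motif residue), `motif_dihedrals`, `ligand_coords`,
#'   `ligand_radii`, `label`.
#' @export
make_synthetic_template <- function(motif_seq = "DPW",
                                    motif_dihedrals = SYNTH_MOTIF_DIHEDRALS,
                                    ligand_radius = 18, ligand_offset = 22,
                                    n_shell_atoms = 256, atom_radius = 1.7,
                                    fill = TRUE,
                                    label = "synthetic-ball") {
  stopifnot(ligand_radius > 0, ligand_offset > 0)
  seq <- as_idr_seq(motif_seq)
  m <- length(seq$residues)
  stopifnot(nrow(motif_dihedrals) == m)
  coords <- rebuild_coordinates(motif_dihedrals, seq)
  at <- make_atom_table(seq$residues)
  bb_rows <- which(at$name %in% c("N", "CA", "C"))
  centre_res <- (m + 1L) %/% 2L
  ca_row <- which(at$res_index == centre_res & at$name == "CA")
  sc_row <- which(at$res_index == centre_res & at$name == "SC")
  if (length(sc_row) == 0) {  # glycine centre: use plane normal instead
    nr <- which(at$res_index == centre_res & at$name == "N")
    cr <- which(at$res_index == centre_res & at$name == "C")
    dir <- cross3(coords[nr, ] - coords[ca_row, ], coords[cr, ] - coords[ca_row, ])
  } else {
    dir <- coords[sc_row, ] - coords[ca_row, ]
  }
  dir <- dir / sqrt(sum(dir^2))
  centre <- coords[ca_row, ] + ligand_offset * dir
  shell <- ligand_radius * fibonacci_sphere(n_shell_atoms)
  if (fill) {
    inner_radii <- if (ligand_radius > 2 * 3.4) {
      seq(ligand_radius - 3.4, 3.4, by = -3.4)
    } else numeric(0)
    inner <- lapply(inner_radii, function(r) {
      r * fibonacci_sphere(max(8L, round(n_shell_atoms * (r / ligand_radius)^2)))
    })
    shell <- rbind(shell, do.call(rbind, inner), c(0, 0, 0))
  }
  shell <- sweep(shell, 2, centre, "+")
  structure(list(motif_backbone = coords[bb_rows, , drop = FALSE],
                 motif_dihedrals = motif_dihedrals,
                 motif_seq = seq$residues,
                 ligand_coords = shell,
                 ligand_radii = rep(atom_radius, nrow(shell)),
                 label = label),
            class = "idr_template")
}

#' @export
print.idr_template <- function(x, ...) {
  cat(sprintf("<idr_template> %s: %d motif residues, %d ligand atoms\n",
              x$label, nrow(x$motif_dihedrals), nrow(x$ligand_coords)))
  invisible(x)
}

#' Internal self-consistency of a template
#'
#' Clash count between the template's own motif backbone and its ligand
#' body (zero when the ligand is placed clear of the motif).
#'
#' @param template `idr_template`.
#' @param overlap_tol Allowed overlap, default 0.4.
#' @return Integer clash count.
#' @export
template_self_clashes <- function(template, overlap_tol = 0.4) {
  bb_radii <- rep(unname(BACKBONE_RADII[c("N", "CA", "C")]),
                  nrow(template$motif_dihedrals))
  count_clashes(template$motif_backbone, bb_radii,
                template$ligand_coords, template$ligand_radii, overlap_tol)
}

#' Dock the template at every motif of every conformer
#'
#' One docking record per (conformer, motif): the template ligand is
#' placed by superposition at the motif and clashes against the whole
#' conformer are counted. A motif is accessible when its clash count is
#' strictly below `threshold`.
#'
#' @param ensemble An `idr_ensemble`.
#' @param hits `idr_motifs` for the ensemble's sequence.
#' @param template `idr_template`.
#' @param threshold Clash threshold (default 100; strict `<`).
#' @param overlap_tol Allowed overlap per atom pair (default 0.4).
#' @return data.frame with columns `conformer_id`, `motif` (1-based index
#'   into `hits$starts`), `clashes`, `rmsd`, `accessible`. The threshold
#'   is attached as attribute `threshold`.
#' @export
dock_all <- function(ensemble, hits, template, threshold = 100,
                     overlap_tol = 0.4) {
  stopifnot(threshold > 0)
  n <- ensemble$n_conformers
  nm <- length(hits$starts)
  m <- hits$motif_length
  at <- ensemble$atom_table
  radii <- at$radius
  bb_rows <- lapply(hits$starts, function(s) motif_backbone_rows(at, s, m))
  N <- n * nm
  conformer_id <- rep(seq_len(n), each = nm)
  motif <- rep(seq_len(nm), times = n)
  clashes <- integer(N)
  rmsd <- numeric(N)
  nlig <- nrow(template$ligand_coords)
  k <- 0L
  for (i in seq_len(n)) {
    xyz <- ensemble$coords[, , i]
    placed <- matrix(NA_real_, nlig * nm, 3)
    for (j in seq_len(nm)) {
      fit <- kabsch_superpose(template$motif_backbone,
                              xyz[bb_rows[[j]], , drop = FALSE])
      placed[(j - 1L) * nlig + seq_len(nlig), ] <-
        fit$transform(template$ligand_coords)
      rmsd[k + j] <- fit$rmsd
    }
    clashes[k + seq_len(nm)] <- .dock_counts_cpp(xyz, radii, placed, nlig,
                                                 template$ligand_radii,
                                                 overlap_tol)
    k <- k + nm
  }
  out <- data.frame(conformer_id = conformer_id, motif = motif,
                    clashes = clashes, rmsd = rmsd,
                    accessible = clashes < threshold)
  attr(out, "threshold") <- threshold
  attr(out, "n_conformers") <- n
  attr(out, "n_motifs") <- nm
  out
}

#' Pairwise docking of the template at accessible motif pairs
#'
#' For every conformer and every unordered pair of motifs that are both
#' individually accessible, both ligand bodies are placed and the
#' ligand-ligand clash count computed. A pair is feasible when all three
#' counts (conformer vs ligand 1, conformer vs ligand 2, ligand 1 vs
#' ligand 2) are strictly below the threshold.
#'
#' @inheritParams dock_all
#' @param singles The record returned by [dock_all] (same ensemble,
#'   template and threshold).
#' @return data.frame with columns `conformer_id`, `motif_i`, `motif_j`
#'   (i < j), `clashes_i`, `clashes_j`, `clashes_ll`, `feasible`.
#' @export
dock_pairs <- function(ensemble, hits, template, singles, threshold = 100,
                       overlap_tol = 0.4) {
  n <- ensemble$n_conformers
  nm <- length(hits$starts)
  m <- hits$motif_length
  at <- ensemble$atom_table
  bb_rows <- lapply(hits$starts, function(s) motif_backbone_rows(at, s, m))
  acc <- matrix(FALSE, n, nm)
  acc[cbind(singles$conformer_id, singles$motif)] <- singles$accessible
  cl <- matrix(NA_integer_, n, nm)
  cl[cbind(singles$conformer_id, singles$motif)] <- singles$clashes

  chunks <- vector("list", n)
  for (i in seq_len(n)) {
    vs <- which(acc[i, ])
    if (length(vs) < 2) next
    xyz <- ensemble$coords[, , i]
    placed <- lapply(vs, function(j) {
      kabsch_superpose(template$motif_backbone,
                       xyz[bb_rows[[j]], , drop = FALSE])$transform(
                         template$ligand_coords)
    })
    pr <- utils::combn(seq_along(vs), 2)
    ll <- integer(ncol(pr))
    for (p in seq_len(ncol(pr))) {
      ll[p] <- .count_clashes_cpp(placed[[pr[1, p]]], template$ligand_radii,
                                  placed[[pr[2, p]]], template$ligand_radii,
                                  overlap_tol)
    }
    chunks[[i]] <- data.frame(conformer_id = i,
                              motif_i = vs[pr[1, ]], motif_j = vs[pr[2, ]],
                              clashes_i = cl[i, vs[pr[1, ]]],
                              clashes_j = cl[i, vs[pr[2, ]]],
                              clashes_ll = ll)
  }
  chunks <- chunks[!vapply(chunks, is.null, logical(1))]
  if (length(chunks) == 0) {
    out <- data.frame(conformer_id = integer(0), motif_i = integer(0),
                      motif_j = integer(0), clashes_i = integer(0),
                      clashes_j = integer(0), clashes_ll = integer(0),
                      feasible = logical(0))
  } else {
    out <- do.call(rbind, chunks)
    out$feasible <- out$clashes_i < threshold & out$clashes_j < threshold &
      out$clashes_ll < threshold
  }
  attr(out, "threshold") <- threshold
  attr(out, "n_conformers") <- n
  attr(out, "n_motifs") <- nm
  out
}

#' Write docking records as TSV
#' @param records data.frame from [dock_all] or [dock_pairs].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_docking_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
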