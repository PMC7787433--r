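# Excluded-volume Monte-Carlo conformer generation.
#
# Chains are built residue by residue from idealized backbone geometry;
# unconstrained residues draw (phi, psi) from a discrete mixture of
# Ramachandran coil basins (per residue class), constrained residues from
# a single gaussian centred on the constraint. A hash grid rejects hard
# van der Waals overlaps between residues at least two apart, with
# resampling, bounded unwinding and whole-chain restarts on failure.

# Coil basin tables: columns weight, phi, psi, sd_phi, sd_psi (degrees).
# Weights are the tunable compaction knobs of the generator; they are
# fixed here so that homopolymer ensembles follow excluded-volume scaling
# with dimensions typical of disordered regions (see the package vignette).
#' @noRd
COIL_BASINS <- list(
  general = rbind(
    beta   = c(0.10, -140, 135, 20, 20),
    ppii   = c(0.20,  -75, 145, 20, 20),
    alphaR = c(0.60,  -65, -40, 12, 12),
    alphaL = c(0.10,   55,  45, 10, 10)),
  gly = rbind(
    beta   = c(0.25, -140, 140, 25, 25),
    ppii   = c(0.25,  -80, 150, 20, 20),
    alphaR = c(0.25,  -65, -40, 15, 15),
    alphaL = c(0.25,   75,  30, 15, 15)),
  pro = rbind(
    ppii   = c(0.65,  -65, 145, 8, 12),
    alphaR = c(0.35,  -65, -35, 8, 10)),
  prepro = rbind(
    beta   = c(0.45, -130, 140, 15, 15),
    ppii   = c(0.45,  -75, 150, 12, 12),
    alphaR = c(0.10,  -65, -40, 12, 12))
)

# Helix constraint dihedrals (alpha-helix) and default jitter.
#' @noRd
HELIX_PHI_PSI <- c(-57, -47)

#' Dihedral constraint on a residue span
#'
#' @param range Integer vector of 1-based residue positions (typically a
#'   contiguous span) the constraint applies to.
#' @param mode `"helix"` (alpha-helical phi/psi) or `"fixed"` (explicit
#'   `phi`, `psi`).
#' @param phi,psi Degrees; required for `mode = "fixed"`. May be vectors
#'   of `length(range)` for per-residue values.
#' @param jitter Gaussian standard deviation (degrees) around the
#'   constraint; draws are truncated at 3 jitter so constrained residues
#'   stay within a hard tolerance. Default 5 for helix, 0 for fixed.
#' @return An object of class `idr_constraint`.
#' @export
dihedral_constraint <- function(range, mode = c("helix", "fixed"),
                                phi = NULL, psi = NULL, jitter = NULL) {
  mode <- match.arg(mode)
  range <- as.integer(range)
  if (mode == "helix") {
    phi <- rep(HELIX_PHI_PSI[1], length(range))
    psi <- rep(HELIX_PHI_PSI[2], length(range))
    if (is.null(jitter)) jitter <- 5
  } else {
    if (is.null(phi) || is.null(psi)) {
      stop("fixed constraints require explicit phi and psi", call. = FALSE)
    }
    phi <- rep_len(phi, length(range))
    psi <- rep_len(psi, length(range))
    if (is.null(jitter)) jitter <- 0
  }
  structure(list(range = range, mode = mode, phi = phi, psi = psi,
                 jitter = jitter),
            class = "idr_constraint")
}

#' Fixed-dihedral constraints at every motif hit
#'
#' Builds one fixed constraint per motif occurrence, taking the per-residue
#' (phi, psi) from a template complex so that generated motif backbones
#' match the docking template.
#'
#' @param hits `idr_motifs` from [find_motifs].
#' @param template An `idr_template` (see [make_synthetic_template]) or a
#'   numeric matrix of per-motif-residue (phi, psi).
#' @param jitter Degrees, default 0 (exact motif dihedrals).
#' @return List of `idr_constraint` objects.
#' @export
motif_constraints <- function(hits, template, jitter = 0) {
  dih <- if (is.matrix(template)) template else template$motif_dihedrals
  stopifnot(nrow(dih) == hits$motif_length)
  lapply(hits$starts, function(s) {
    dihedral_constraint(s:(s + hits$motif_length - 1L), "fixed",
                        phi = dih[, 1], psi = dih[, 2], jitter = jitter)
  })
}

#' @noRd
check_constraints <- function(constraints, n_res) {
  seen <- integer(0)
  for (cst in constraints) {
    if (!inherits(cst, "idr_constraint")) stop("not an idr_constraint")
    if (any(cst$range < 1 | cst$range > n_res)) {
      stop("constraint range outside sequence", call. = FALSE)
    }
    if (any(cst$range %in% seen)) {
      stop("overlapping constraint spans", call. = FALSE)
    }
    seen <- c(seen, cst$range)
  }
  invisible(TRUE)
}

# Per-residue basin tables flattened for the C++ builder.
#' @noRd
residue_basins <- function(residues, constraints) {
  n <- length(residues)
  check_constraints(constraints, n)
  tabs <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- if (residues[i] == "P") "pro"
      else if (residues[i] == "G") "gly"
      else if (i < n && residues[i + 1] == "P") "prepro"
      else "general"
    tabs[[i]] <- COIL_BASINS[[cls]]
  }
  for (cst in constraints) {
    for (k in seq_along(cst$range)) {
      i <- cst$range[k]
      tabs[[i]] <- matrix(c(1, cst$phi[k], cst$psi[k], cst$jitter, cst$jitter),
                          nrow = 1)
    }
  }
  counts <- vapply(tabs, nrow, integer(1))
  tab <- do.call(rbind, tabs)
  tab[, 1] <- tab[, 1] / rep(vapply(tabs, function(m) sum(m[, 1]), numeric(1)),
                             counts)
  list(table = unname(tab),
       offset = c(0L, cumsum(counts))[seq_len(n)],
       count = counts)
}

#' @noRd
default_build_control <- function() {
  list(overlap_tol = 0.4, min_sep = 2L, max_resample = 50L,
       unwind_len = 5L, max_unwind = 100L, max_restart = 25L)
}

#' Build one sterically feasible conformer
#'
#' Self-avoiding chain of idealized backbone (N, CA, C, O) plus one
#' side-chain bead per non-glycine residue. Unconstrained residues sample
#' Ramachandran coil basins by residue class (general / glycine / proline
#' / pre-proline); constrained residues stay within 3 x jitter of their
#' constraint. On steric failure the builder resamples the residue, then
#' unwinds, then restarts, within configurable budgets.
#'
#' @param seq [idr_seq] or character string.
#' @param constraints List of [dihedral_constraint] objects (may be empty).
#' @param seed Integer RNG seed for this conformer.
#' @param control Budget/tolerance overrides, see
#'   `idrocc:::default_build_control`.
#' @return An object of class `idr_conformer`: `coords` (atoms x 3, in
#'   Angstrom), `dihedrals` (residues x 2, degrees), `atom_table`, `seed`,
#'   `seq`.
#' @export
build_conformer <- function(seq, constraints = list(), seed = 1L,
                            control = list()) {
  seq <- as_idr_seq(seq)
  res <- seq$residues
  ctrl <- utils::modifyList(default_build_control(), control)
  bas <- residue_basins(res, constraints)
  scg <- SIDECHAIN_GEOMETRY[match(res, SIDECHAIN_GEOMETRY$aa), ]
  out <- with_local_seed(seed, {
    .build_chain_cpp(as.integer(res != "G"), scg$dist, scg$radius,
                     bas$table, bas$offset, bas$count,
                     geom_vector(), unname(BACKBONE_RADII),
                     ctrl$overlap_tol, ctrl$min_sep, ctrl$max_resample,
                     ctrl$unwind_len, ctrl$max_unwind, ctrl$max_restart)
  })
  if (!isTRUE(out$ok)) {
    stop(sprintf("conformer build failed: retry budget exhausted at residue %d",
                 out$stuck), call. = FALSE)
  }
  structure(list(coords = out$coords,
                 dihedrals = cbind(phi = out$phi, psi = out$psi),
                 atom_table = make_atom_table(res),
                 seed = seed, restarts = out$restarts, seq = seq),
            class = "idr_conformer")
}

#' @export
print.idr_conformer <- function(x, ...) {
  cat(sprintf("<idr_conformer> %d residues, %d atoms (seed %d)\n",
              length(x$seq$residues), nrow(x$coords), x$seed))
  invisible(x)
}

# Deterministic per-conformer seed stream derived from a master seed.
#' @noRd
derive_seed <- function(master_seed, index) {
  p <- 2147483647
  as.integer((as.numeric(master_seed) %% p + index * 48271) %% p)
}

#' Generate a conformer ensemble
#'
#' Builds `n` independent conformers of the same sequence under the same
#' constraints. Each conformer gets its own seed derived deterministically
#' from `master_seed` and its index, so ensembles are bit-reproducible and
#' any single conformer can be rebuilt in isolation.
#'
#' @inheritParams build_conformer
#' @param n Number of conformers.
#' @param master_seed Integer master seed.
#' @param progress Print a progress line every 1000 conformers.
#' @return An object of class `idr_ensemble`: `coords` array
#'   (atoms x 3 x n), `dihedrals` array (residues x 2 x n), `atom_table`,
#'   `seeds`, `master_seed`, `seq`, `constraints`, and the total restart
#'   count `failures` across builds.
#' @export
generate_ensemble <- function(seq, constraints = list(), n, master_seed = 1L,
                              control = list(), progress = FALSE) {
  stopifnot(n >= 1)
  seq <- as_idr_seq(seq)
  at <- make_atom_table(seq$residues)
  nat <- nrow(at)
  nres <- length(seq$residues)
  coords <- array(NA_real_, c(nat, 3, n))
  dihedrals <- array(NA_real_, c(nres, 2, n))
  seeds <- integer(n)
  restarts <- 0L
  for (i in seq_len(n)) {
    seeds[i] <- derive_seed(master_seed, i)
    cf <- build_conformer(seq, constraints, seed = seeds[i], control = control)
    coords[, , i] <- cf$coords
    dihedrals[, , i] <- cf$dihedrals
    restarts <- restarts + cf$restarts
    if (progress && i %% 1000 == 0) {
      message(sprintf("  built %d/%d conformers", i, n))
    }
  }
  structure(list(coords = coords, dihedrals = dihedrals, atom_table = at,
                 seeds = seeds, master_seed = as.integer(master_seed),
                 n_conformers = as.integer(n), seq = seq,
                 constraints = constraints, failures = restarts),
            class = "idr_ensemble")
}

#' @export
print.idr_ensemble <- function(x, ...) {
  cat(sprintf("<idr_ensemble> %s: %d conformers x %d residues (seed %d)\n",
              x$seq$id, x$n_conformers, length(x$seq$residues),
              x$master_seed))
  invisible(x)
}

#' Extract one conformer from an ensemble
#' @param ensemble An `idr_ensemble`.
#' @param id Conformer index (1-based).
#' @return An `idr_conformer`.
#' @export
get_conformer <- function(ensemble, id) {
  stopifnot(id >= 1, id <= ensemble$n_conformers)
  structure(list(coords = ensemble$coords[, , id],
                 dihedrals = ensemble$dihedrals[, , id],
                 atom_table = ensemble$atom_table,
                 seed = ensemble$seeds[id], restarts = NA_integer_,
                 seq = ensemble$seq),
            class = "idr_conformer")
}

#' Count hard intra-chain clashes of a conformer
#'
#' Reference self-avoidance check: pairs of atoms at least `min_sep`
#' residues apart closer than the sum of their radii minus `overlap_tol`.
#'
#' @param conformer `idr_conformer`.
#' @param overlap_tol Allowed overlap (Angstrom), default 0.4.
#' @param min_sep Minimum residue separation, default 2.
#' @return Integer clash count.
#' @export
self_clashes <- function(conformer, overlap_tol = 0.4, min_sep = 2L) {
  at <- conformer$atom_table
  .count_self_clashes_cpp(conformer$coords, at$radius,
                          as.integer(at$res_index), as.integer(min_sep),
                          overlap_tol)
}

#' Write a conformer as a PDB file
#'
#' Single-model PDB with CA/backbone atoms and the side-chain bead written
#' as a CB pseudo-atom.
#'
#' @param conformer `idr_conformer`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conformer_pdb <- function(conformer, path) {
  at <- conformer$atom_table
  elety <- ifelse(at$name == "SC", "CB", at$name)
  aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(conformer$coords)),
                   resno = at$res_index, resid = aa3[at$aa],
                   elety = elety, chain = "A")
  invisible(path)
}
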