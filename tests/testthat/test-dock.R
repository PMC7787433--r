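test_that("superposition recovers identity and known rigid transforms", {
  tpl <- make_synthetic_template("DPW", n_shell_atoms = 64)
  # identity: fitting the template onto its own backbone leaves the ligand
  fit <- kabsch_superpose(tpl$motif_backbone, tpl$motif_backbone)
  expect_lt(fit$rmsd, 1e-9)
  expect_lt(max(abs(fit$transform(tpl$ligand_coords) - tpl$ligand_coords)),
            1e-9)
  # known rotation + translation recovered to 1e-6
  for (seed in 1:5) {
    rig <- random_rigid(seed)
    moved_bb <- apply_rigid(tpl$motif_backbone, rig)
    fit <- kabsch_superpose(tpl$motif_backbone, moved_bb)
    expect_lt(fit$rmsd, 1e-9)
    expect_lt(max(abs(fit$transform(tpl$ligand_coords) -
                        apply_rigid(tpl$ligand_coords, rig))), 1e-6)
  }
})

test_that("superposition agrees with an independent least-squares fit", {
  set.seed(23)
  P <- matrix(rnorm(27), 9, 3)
  rig <- random_rigid(4)
  Q <- apply_rigid(P, rig) + matrix(rnorm(27, sd = 0.05), 9, 3)
  fit <- kabsch_superpose(P, Q)
  # bio3d's fit of the same pairing
  ref <- bio3d::fit.xyz(fixed = as.numeric(t(Q)), mobile = as.numeric(t(P)),
                        fixed.inds = 1:27, mobile.inds = 1:27)
  ref_rmsd <- sqrt(mean(rowSums((matrix(ref, ncol = 3, byrow = TRUE) - Q)^2)))
  expect_equal(fit$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("degenerate backbones and reflections are handled", {
  line <- cbind(1:9, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "degenerate")
  # a mirrored target cannot be reached by a proper rotation
  set.seed(2)
  P <- matrix(rnorm(27), 9, 3)
  M <- P %*% diag(c(-1, 1, 1))
  fit <- kabsch_superpose(P, M)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd, 0.1)
})

test_that("clash counting matches definitions and the brute-force oracle", {
  a <- matrix(c(0, 0, 0), 1)
  b <- matrix(c(5, 0, 0), 1)
  expect_equal(count_clashes(a, 1.7, b, 1.7), 0L)
  expect_equal(count_clashes(a, 1.7, a, 1.7), 1L)
  # boundary: distance exactly r_i + r_j - tol is NOT a clash (strict <)
  b2 <- matrix(c(1.7 + 1.7 - 0.4, 0, 0), 1)
  expect_equal(count_clashes(a, 1.7, b2, 1.7), 0L)
  set.seed(31)
  for (trial in 1:8) {
    nA <- sample(50:120, 1); nB <- sample(50:120, 1)
    A <- matrix(runif(nA * 3, 0, 18), ncol = 3)
    B <- matrix(runif(nB * 3, 0, 18), ncol = 3)
    ra <- runif(nA, 1.2, 2.6); rb <- runif(nB, 1.2, 2.6)
    expect_equal(count_clashes(A, ra, B, rb, 0.4),
                 brute_clash(A, ra, B, rb, 0.4))
    # symmetry and monotonicity in the overlap tolerance
    expect_equal(count_clashes(A, ra, B, rb, 0.4),
                 count_clashes(B, rb, A, ra, 0.4))
    expect_gte(count_clashes(A, ra, B, rb, 0.2),
               count_clashes(A, ra, B, rb, 0.6))
  }
})

test_that("the synthetic template is self-consistent", {
  far <- make_synthetic_template("DPW", ligand_radius = 5, ligand_offset = 40,
                                 n_shell_atoms = 64)
  expect_equal(template_self_clashes(far), 0L)
  near <- make_synthetic_template("DPW", ligand_radius = 18,
                                  ligand_offset = 2)
  expect_gt(template_self_clashes(near), 0L)
  # motif backbone reproduces the requested dihedrals
  tpl <- make_synthetic_template("DPW")
  expect_equal(nrow(tpl$motif_backbone), 9)
  expect_gt(nrow(tpl$ligand_coords), 256)  # filled body
  shell <- make_synthetic_template("DPW", fill = FALSE)
  expect_equal(nrow(shell$ligand_coords), 256)
  # all shell atoms equidistant from the (estimated) centre
  ctr <- colMeans(shell$ligand_coords)
  expect_equal(sqrt(rowSums(sweep(shell$ligand_coords, 2, ctr)^2)),
               rep(18, 256), tolerance = 1e-3)
})

test_that("conformers built with template dihedrals fit with low RMSD", {
  sys <- tiny_system()
  cf <- get_conformer(sys$ens, 1)
  sup <- superpose_template(sys$tpl, cf, sys$hits$starts[1])
  expect_lt(sup$rmsd, 0.5)
})

test_that("docking records cover every conformer-motif combination", {
  sys <- tiny_system()
  sg <- sys$singles
  expect_equal(nrow(sg), sys$ens$n_conformers * length(sys$hits$starts))
  expect_identical(sg$accessible, sg$clashes < attr(sg, "threshold"))
  # a far-away ligand is accessible everywhere with zero clashes
  far_tpl <- sys$tpl
  far_tpl$ligand_coords <- far_tpl$ligand_coords + 500
  far <- dock_all(sys$ens, sys$hits, far_tpl)
  expect_true(all(far$accessible))
  expect_true(all(far$clashes == 0))
  # flags match a brute-force recount on a few records
  at <- sys$ens$atom_table
  for (r in c(1, 10, 30)) {
    cf <- get_conformer(sys$ens, sg$conformer_id[r])
    sup <- superpose_template(sys$tpl, cf, sys$hits$starts[sg$motif[r]])
    expect_equal(sg$clashes[r],
                 brute_clash(cf$coords, at$radius, sup$ligand_coords,
                             sup$ligand_radii, 0.4))
  }
})

test_that("pair feasibility follows the three-pair rule and is symmetric", {
  sys <- tiny_system()
  pr <- sys$pairs
  expect_true(all(pr$motif_i < pr$motif_j))
  expect_identical(pr$feasible,
                   pr$clashes_i < 100 & pr$clashes_j < 100 &
                     pr$clashes_ll < 100)
  # pairs only exist where both singles are accessible
  acc <- matrix(FALSE, sys$ens$n_conformers, length(sys$hits$starts))
  acc[cbind(sys$singles$conformer_id, sys$singles$motif)] <-
    sys$singles$accessible
  expect_true(all(acc[cbind(pr$conformer_id, pr$motif_i)]))
  expect_true(all(acc[cbind(pr$conformer_id, pr$motif_j)]))
  # ligand-ligand count is symmetric in placement order
  cf <- get_conformer(sys$ens, pr$conformer_id[1])
  p1 <- superpose_template(sys$tpl, cf, sys$hits$starts[pr$motif_i[1]])
  p2 <- superpose_template(sys$tpl, cf, sys$hits$starts[pr$motif_j[1]])
  expect_equal(count_clashes(p1$ligand_coords, p1$ligand_radii,
                             p2$ligand_coords, p2$ligand_radii),
               count_clashes(p2$ligand_coords, p2$ligand_radii,
                             p1$ligand_coords, p1$ligand_radii))
  expect_equal(pr$clashes_ll[1],
               count_clashes(p1$ligand_coords, p1$ligand_radii,
                             p2$ligand_coords, p2$ligand_radii))
})

test_that("overlapping ligand placements at adjacent motifs are infeasible", {
  # gap of 1 residue between motifs, short-offset template: the two placed
  # bodies (radius 18, centres at most 2 x 10 + anchor separation apart)
  # must intersect, whatever the motif orientations
  seqstr <- paste0("GSA", "DPW", "A", "DPW", "GSAGSAGSAGSAGSAGSAGSAETK")
  seq <- idr_seq("adj", seqstr)
  hits <- find_motifs(seq, "DPW")
  expect_equal(diff(hits$starts), 4L)
  tpl <- make_synthetic_template("DPW", ligand_offset = 10)
  ens <- generate_ensemble(seq, motif_constraints(hits, tpl), n = 6,
                           master_seed = 5)
  # singles with an unbounded threshold so every pair is enumerated
  sg <- dock_all(ens, hits, tpl, threshold = 1e9)
  pr <- dock_pairs(ens, hits, tpl, sg, threshold = 100)
  expect_equal(nrow(pr), 6L)
  expect_true(all(pr$clashes_ll > 100))
  expect_false(any(pr$feasible))
})

test_that("accessibility is monotone in the clash threshold", {
  sys <- tiny_system()
  for (cid in seq_len(sys$ens$n_conformers)) {
    sub <- sys$singles[sys$singles$conformer_id == cid, ]
    acc50 <- sub$clashes < 50
    acc100 <- sub$clashes < 100
    acc150 <- sub$clashes < 150
    expect_true(all(acc100[acc50]))
    expect_true(all(acc150[acc100]))
  }
})
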