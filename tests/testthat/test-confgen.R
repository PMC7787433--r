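test_that("a 2-mer has one effective dihedral junction and ideal CA-CA", {
  cf <- build_conformer("AA", seed = 1)
  ca <- cf$coords[cf$atom_table$name == "CA", ]
  expect_equal(sqrt(sum((ca[1, ] - ca[2, ])^2)), 3.8, tolerance = 0.1 / 3.8)
  expect_true(is.na(cf$dihedrals[1, "phi"]))
})

test_that("helix constraints give helical geometry and rise", {
  cf <- build_conformer(strrep("A", 10),
                        list(dihedral_constraint(1:10, "helix", jitter = 0)),
                        seed = 2)
  ca <- cf$coords[cf$atom_table$name == "CA", ]
  # ideal alpha-helix: ~1.5 A rise/residue -> CA1-CA10 ~ 13.5 +- 2
  expect_equal(sqrt(sum((ca[1, ] - ca[10, ])^2)), 13.5, tolerance = 2 / 13.5)
  rises <- sqrt(rowSums((ca[-1, ] - ca[-10, ])^2))
  expect_true(all(abs(rises - 3.8) < 0.1))
})

test_that("fixed constraints are echoed within the jitter tolerance", {
  cst <- dihedral_constraint(3:5, "fixed", phi = -120, psi = 120, jitter = 2)
  cf <- build_conformer(strrep("A", 8), list(cst), seed = 3)
  stored <- cf$dihedrals[3:5, ]
  expect_true(all(abs(stored[, "phi"] + 120) <= 3 * 2))
  expect_true(all(abs(stored[, "psi"] - 120) <= 3 * 2))
  # zero jitter: exact echo
  cst0 <- dihedral_constraint(3:5, "fixed", phi = -120, psi = 120)
  cf0 <- build_conformer(strrep("A", 8), list(cst0), seed = 3)
  expect_equal(unname(cf0$dihedrals[3:5, "phi"]), rep(-120, 3))
  expect_equal(unname(cf0$dihedrals[3:5, "psi"]), rep(120, 3))
})

test_that("constraint validation rejects bad spans", {
  expect_error(build_conformer("AAAA",
                               list(dihedral_constraint(3:9, "helix"))),
               "outside")
  expect_error(build_conformer("AAAAAA",
                               list(dihedral_constraint(1:3, "helix"),
                                    dihedral_constraint(3:4, "helix"))),
               "overlapping")
  expect_error(dihedral_constraint(1:3, "fixed"), "require")
})

test_that("an impossible constraint set fails with the stuck residue", {
  cst <- dihedral_constraint(1:10, "fixed", phi = 0, psi = 0, jitter = 0)
  expect_error(build_conformer(strrep("A", 10), list(cst), seed = 1,
                               control = list(max_restart = 2)),
               "failed at residue|retry budget")
})

test_that("ensembles are bit-reproducible under the same master seed", {
  s <- "SEAGKDPWPASGTK"
  e1 <- generate_ensemble(s, n = 6, master_seed = 123)
  e2 <- generate_ensemble(s, n = 6, master_seed = 123)
  expect_identical(e1$coords, e2$coords)
  expect_identical(e1$dihedrals, e2$dihedrals)
  e3 <- generate_ensemble(s, n = 6, master_seed = 124)
  expect_false(identical(e1$coords, e3$coords))
  # per-conformer rebuild from its own seed matches the stored conformer
  cf <- build_conformer(s, list(), seed = e1$seeds[4])
  expect_identical(cf$coords, get_conformer(e1, 4)$coords)
})

test_that("accepted conformers are self-avoiding and satisfy constraints", {
  sys <- tiny_system()
  for (i in seq_len(sys$ens$n_conformers)) {
    expect_equal(self_clashes(get_conformer(sys$ens, i)), 0L)
  }
  # every constrained (motif) residue within tolerance in every conformer
  tpldih <- sys$tpl$motif_dihedrals
  for (cst in sys$cons) {
    for (i in seq_len(sys$ens$n_conformers)) {
      stored <- sys$ens$dihedrals[cst$range, , i]
      expect_true(all(abs(stored[, 1] - cst$phi) <= 1e-9))
      expect_true(all(abs(stored[, 2] - cst$psi) <= 1e-9))
    }
  }
  # CA-CA virtual bonds at 3.8 +- 0.1 everywhere
  ca_rows <- which(sys$ens$atom_table$name == "CA")
  for (i in c(1, 12, 24)) {
    ca <- sys$ens$coords[ca_rows, , i]
    d <- sqrt(rowSums((ca[-1, ] - ca[-nrow(ca), ])^2))
    expect_true(all(abs(d - 3.8) < 0.1))
  }
})

test_that("dihedral -> coordinates -> dihedral round trip is exact", {
  set.seed(17)
  n <- 25
  d <- cbind(phi = runif(n, -180, 180), psi = runif(n, -180, 180))
  d[1, 1] <- NA
  sq <- paste(sample(c("A", "G", "S", "L", "K", "E", "W"), n, TRUE),
              collapse = "")
  xyz <- rebuild_coordinates(d, sq)
  cf <- list(coords = xyz,
             atom_table = idrocc:::make_atom_table(strsplit(sq, "")[[1]]))
  d2 <- measure_dihedrals(cf)
  wrap <- function(x) ((x + 180) %% 360) - 180
  expect_lt(max(abs(wrap(d[-1, 1] - d2[-1, 1]))), 1e-6)
  expect_lt(max(abs(wrap(d[, 2] - d2[, 2]))), 1e-6)
})

test_that("rebuilt ideal helix and extended chains have textbook geometry", {
  n <- 12
  helix <- rebuild_coordinates(cbind(rep(-57, n), rep(-47, n)), strrep("A", n))
  at <- idrocc:::make_atom_table(rep("A", n))
  ca <- helix[at$name == "CA", ]
  rise <- sqrt(sum((ca[1, ] - ca[n, ])^2)) / (n - 1)
  expect_equal(rise, 1.5, tolerance = 0.1 / 1.5)
  ext <- rebuild_coordinates(cbind(rep(-120, n), rep(120, n)), strrep("A", n))
  cae <- ext[at$name == "CA", ]
  d13 <- sqrt(rowSums((cae[-(1:2), ] - cae[1:(n - 2), ])^2))
  expect_true(all(d13 > 6))
})

test_that("homopolymer ensembles follow excluded-volume scaling", {
  Ns <- c(25, 50, 100)
  mean_rg <- vapply(Ns, function(N) {
    ens <- generate_ensemble(strrep("A", N), n = 60, master_seed = 31)
    mean(vapply(seq_len(60), function(i) {
      radius_of_gyration(get_conformer(ens, i))
    }, numeric(1)))
  }, numeric(1))
  nu <- unname(coef(lm(log(mean_rg) ~ log(Ns)))[2])
  expect_gt(nu, 0.45)  # quick-look bound; the full-range fit is asserted
  expect_lt(nu, 0.75)  # at N up to 200 in the acceptance suite
})

test_that("conformer PDB export round-trips coordinates", {
  cf <- build_conformer("ADPWGK", seed = 8)
  tmp <- tempfile(fileext = ".pdb")
  write_conformer_pdb(cf, tmp)
  pdb <- bio3d::read.pdb(tmp)
  xyz <- matrix(pdb$xyz, ncol = 3, byrow = TRUE)
  expect_equal(nrow(xyz), nrow(cf$coords))
  expect_equal(xyz, unname(cf$coords), tolerance = 1e-3)
  expect_equal(pdb$atom$resno, cf$atom_table$res_index)
})
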