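test_that("motif scanning finds non-overlapping literal hits", {
  expect_equal(find_motifs("ADPWGGDPWK", "DPW")$starts, c(2L, 7L))
  expect_equal(find_motifs("AAAA", "DPW")$starts, integer(0))
  expect_equal(find_motifs("", "DPW")$starts, integer(0))
  # overlapping occurrences: leftmost-first, non-overlapping by default
  expect_equal(find_motifs("DPDPDP", "DPDP")$starts, 1L)
  expect_equal(find_motifs("DPDPDP", "DPDP", overlapping = TRUE)$starts,
               c(1L, 3L))
  expect_error(find_motifs("ABZ", "DPW"), "invalid residue")
})

test_that("planted motifs in a random background are all recovered", {
  set.seed(11)
  res <- sample(c("A", "S", "G", "T", "E", "K", "L", "V"), 200, TRUE)
  planted <- c(10, 52, 99, 140, 188)
  for (s in planted) res[s:(s + 2)] <- c("D", "P", "F")
  seqstr <- paste(res, collapse = "")
  # regex-scan oracle
  oracle <- as.integer(gregexpr("DPF", seqstr)[[1]])
  got <- find_motifs(seqstr, "DPF")$starts
  expect_equal(got, oracle)
  expect_true(all(planted %in% got))
})

test_that("charge parameters follow the K/R vs D/E convention", {
  cp <- charge_params("EKEK")
  expect_equal(cp$f_plus, 0.5)
  expect_equal(cp$f_minus, 0.5)
  expect_equal(cp$FCR, 1)
  expect_equal(cp$NCPR, 0)
  expect_equal(charge_params("GGGG")$FCR, 0)
  # histidine neutral
  expect_equal(charge_params("HHKK")$f_plus, 0.5)
  expect_equal(charge_params("HHKK")$FCR, 0.5)
  # FCR + neutral fraction = 1 exactly on random sequences
  set.seed(3)
  for (i in 1:10) {
    s <- paste(sample(idrocc:::AA_ALPHABET, 40, TRUE), collapse = "")
    cp <- charge_params(s)
    neutral <- mean(!(strsplit(s, "")[[1]] %in% c("K", "R", "D", "E")))
    expect_equal(cp$FCR + neutral, 1)
  }
})

test_that("kappa is 1 for fully segregated and near 0 for alternating", {
  expect_equal(kappa_param("EEEEEKKKKK"), 1, tolerance = 1e-12)
  expect_lt(kappa_param("EKEKEKEKEK"), 0.1)
  expect_true(is.na(kappa_param("GGGGGGGG")))
})

test_that("production delta_max matches exhaustive permutation search", {
  set.seed(21)
  for (trial in 1:6) {
    repeat {
      np <- sample(1:4, 1); nm <- sample(0:4, 1); nz <- sample(0:5, 1)
      if (np + nm + nz >= 6 && np + nm + nz <= 9) break
    }
    arrs <- perms_multiset(np, nm, nz)
    for (g in c(5L, 6L)) {
      exhaustive <- max(vapply(arrs, idrocc:::blob_delta, numeric(1), g = g))
      expect_equal(idrocc:::delta_max(np, nm, nz, g), exhaustive,
                   tolerance = 1e-10)
    }
  }
})

test_that("kappa equals brute-force delta/delta_max on a 12-mer", {
  s <- "EAKGEAKGEKAG"  # 3 E, 3 K among neutrals
  ch <- unname(idrocc:::AA_CHARGE[strsplit(s, "")[[1]]])
  arrs <- perms_multiset(sum(ch > 0), sum(ch < 0), sum(ch == 0))
  ratio <- vapply(c(5L, 6L), function(g) {
    idrocc:::blob_delta(ch, g) /
      max(vapply(arrs, idrocc:::blob_delta, numeric(1), g = g))
  }, numeric(1))
  expect_equal(kappa_param(s), mean(ratio), tolerance = 1e-10)
})

test_that("kappa and omega are reversal-invariant and within [0, 1]", {
  set.seed(5)
  for (i in 1:12) {
    s <- sample(c("E", "K", "G", "S", "P", "A"), 30, TRUE)
    fwd <- paste(s, collapse = "")
    rev_ <- paste(rev(s), collapse = "")
    k1 <- kappa_param(fwd)
    expect_equal(k1, kappa_param(rev_), tolerance = 1e-12)
    expect_gte(k1, 0); expect_lte(k1, 1)
    o1 <- omega_param(fwd)
    expect_equal(o1, omega_param(rev_), tolerance = 1e-12)
    expect_gte(o1, 0); expect_lte(o1, 1)
  }
})

test_that("omega is 1 for a fully segregated binary pattern", {
  expect_equal(omega_param("PPPPPAAAAA"), 1, tolerance = 1e-12)
})

test_that("hydropathy uses the shifted Kyte-Doolittle scale", {
  expect_equal(hydropathy_mean("GGGGGGGGGG"), 4.1)
  expect_equal(hydropathy_mean("I"), 9)
  expect_equal(hydropathy_mean("R"), 0)
})

test_that("linker extraction and the length accounting identity hold", {
  seq <- idr_seq("x", "ADPWGGDPWK")
  hits <- find_motifs(seq, "DPW")
  ls <- linkers(hits, seq)
  expect_equal(ls$lengths, 2L)
  expect_equal(unname(ls$pooled_composition["G"]), 1)
  # identity: flanks + motifs + linkers = total length
  set.seed(9)
  s <- synthetic_idr_sequence("epsin_like", seed = 4)
  h <- find_motifs(s, "DPW")
  lk <- linkers(h, s)
  n_flank <- (h$starts[1] - 1) +
    (length(s$residues) - (h$starts[length(h$starts)] + h$motif_length - 1))
  expect_equal(sum(lk$lengths) + length(h$starts) * h$motif_length + n_flank,
               length(s$residues))
  expect_equal(sum(lk$pooled_composition), 1, tolerance = 1e-9)
  expect_warning(linkers(find_motifs("ADPWAA", "DPW"), idr_seq("y", "ADPWAA")),
                 "fewer than 2")
})

test_that("linker histogram pools records and detects planted bimodality", {
  # uniform spacing -> a single occupied bin
  h1 <- linker_histogram(list("ADPWGGGDPWGGGDPWA"), "DPW")
  expect_equal(sum(h1$counts > 0), 1)
  expect_equal(h1$median, 3)
  # two synthetic records with known gaps -> hand-enumerated counts
  r1 <- "DPFAADPFAAAADPF"       # gaps 2, 4
  r2 <- "GDPFAADPFG"            # gap 2
  h2 <- linker_histogram(list(r1, r2), "DPF", breaks = seq(-0.5, 6.5, 1))
  expect_equal(h2$lengths, c(2L, 4L, 2L))
  expect_equal(h2$counts[c(3, 5)], c(2L, 1L))
  # Eps15-like planting: many short gaps plus several long -> bimodal
  s <- synthetic_idr_sequence("eps15_like")
  h3 <- linker_histogram(list(s), "DPF")
  expect_gte(sum(h3$lengths <= 4), 7)
  expect_gte(sum(h3$lengths > 16), 3)
})

test_that("synthetic sequences reproduce the published motif architecture", {
  ep <- synthetic_idr_sequence("epsin_like")
  expect_equal(length(ep$residues), 240)
  hep <- find_motifs(ep, "DPW")
  expect_equal(length(hep$starts), 8)
  lep <- linkers(hep, ep)
  expect_equal(sort(lep$lengths), c(7L, 9L, 10L, 10L, 14L, 15L, 17L))
  expect_equal(unname(lep$pooled_composition["P"]), 0.27, tolerance = 0.02)

  e15 <- synthetic_idr_sequence("eps15_like")
  expect_equal(length(e15$residues), 333)
  h15 <- find_motifs(e15, "DPF")
  expect_equal(length(h15$starts), 15)
  l15 <- linkers(h15, e15)
  expect_true(all(c(2, 3, 5, 10, 14, 17, 21, 25, 58) %in% l15$lengths))
  expect_equal(unname(l15$pooled_composition["S"]), 0.16, tolerance = 0.02)

  # different seeds shuffle residues but preserve the architecture
  ep2 <- synthetic_idr_sequence("epsin_like", seed = 42)
  expect_equal(find_motifs(ep2, "DPW")$starts, hep$starts)
  expect_false(identical(ep2$residues, ep$residues))
})

test_that("characterization table and FASTA region reading round-trip", {
  tmp <- tempfile(fileext = ".fasta")
  writeLines(c(">demo some description", "ADPWGG", "DPWKEK"), tmp)
  full <- read_fasta_region(tmp)
  expect_equal(length(full$residues), 12)
  reg <- read_fasta_region(tmp, region = c(2, 7))
  expect_equal(paste(reg$residues, collapse = ""), "DPWGGD")
  expect_equal(reg$region, c(2L, 7L))
  expect_error(read_fasta_region(tmp, region = c(1, 50)), "out of bounds")

  tab <- seqchar_table(demo = full)
  expect_equal(tab$demo[tab$feature == "length"], 12)
  expect_equal(tab$demo[tab$feature == "FCR"],
               charge_params(full)$FCR)
  out <- tempfile(fileext = ".tsv")
  write_seqchar_tsv(tab, out)
  back <- read.delim(out)
  expect_equal(back$demo, tab$demo, tolerance = 1e-12)
})
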