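# helpers to fabricate docking-record shaped inputs
fake_singles <- function(acc) {
  n <- nrow(acc); m <- ncol(acc)
  out <- data.frame(conformer_id = rep(seq_len(n), times = m),
                    motif = rep(seq_len(m), each = n),
                    clashes = 0L, rmsd = 0,
                    accessible = as.vector(acc))
  attr(out, "n_conformers") <- n
  attr(out, "n_motifs") <- m
  out
}
fake_pairs <- function(acc, feasible_fun) {
  n <- nrow(acc); m <- ncol(acc)
  pi2 <- utils::combn(m, 2)
  rows <- list()
  for (cid in seq_len(n)) {
    for (p in seq_len(ncol(pi2))) {
      i <- pi2[1, p]; j <- pi2[2, p]
      if (acc[cid, i] && acc[cid, j]) {
        rows[[length(rows) + 1]] <- data.frame(
          conformer_id = cid, motif_i = i, motif_j = j,
          clashes_i = 0L, clashes_j = 0L, clashes_ll = 0L,
          feasible = feasible_fun(cid, i, j))
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(conformer_id = integer(0), motif_i = integer(0),
               motif_j = integer(0), clashes_i = integer(0),
               clashes_j = integer(0), clashes_ll = integer(0),
               feasible = logical(0))
  attr(out, "n_conformers") <- n
  attr(out, "n_motifs") <- m
  out
}

test_that("complete and empty graphs give the textbook clique sets", {
  acc <- matrix(TRUE, 1, 4)
  g <- build_graphs(fake_singles(acc), fake_pairs(acc, function(...) TRUE))
  cg <- conformer_graph(g, 1)
  expect_equal(cg$vertices, 1:4)
  expect_equal(ncol(n_bound(cg, 3)), 4)  # all C(4,3) triples
  expect_equal(ncol(n_bound(cg, 4)), 1)
  expect_equal(ncol(n_bound(cg, 5)), 0)
  # no accessible motifs -> empty graph
  acc0 <- matrix(FALSE, 1, 4)
  g0 <- build_graphs(fake_singles(acc0), fake_pairs(acc0, function(...) TRUE))
  expect_length(conformer_graph(g0, 1)$vertices, 0)
  expect_equal(max_simultaneous(g0), 0L)
})

test_that("a path graph has no triangle", {
  acc <- matrix(TRUE, 1, 3)
  path_feas <- function(cid, i, j) abs(i - j) == 1
  g <- build_graphs(fake_singles(acc), fake_pairs(acc, path_feas))
  cg <- conformer_graph(g, 1)
  expect_equal(ncol(n_bound(cg, 2)), 2)
  expect_equal(ncol(n_bound(cg, 3)), 0)
})

test_that("pair records at non-accessible vertices are rejected", {
  acc <- matrix(c(TRUE, FALSE, TRUE), 1, 3)
  pr <- data.frame(conformer_id = 1L, motif_i = 1L, motif_j = 2L,
                   clashes_i = 0L, clashes_j = 0L, clashes_ll = 0L,
                   feasible = TRUE)
  attr(pr, "n_conformers") <- 1L
  attr(pr, "n_motifs") <- 3L
  expect_error(build_graphs(fake_singles(acc), pr), "non-accessible")
})

test_that("clique enumeration matches brute force and igraph on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(41)
  for (trial in 1:60) {
    m <- sample(3:8, 1)
    acc <- matrix(runif(m) < 0.8, 1, m)
    edge_p <- runif(1, 0.2, 0.9)
    feas <- function(cid, i, j) runif(1) < edge_p
    g <- build_graphs(fake_singles(acc), fake_pairs(acc, feas))
    cg <- conformer_graph(g, 1)
    ig <- if (nrow(cg$edges) > 0) {
      igraph::graph_from_edgelist(matrix(as.integer(cg$edges), ncol = 2),
                                  directed = FALSE)
    }
    for (n in 2:min(5, m)) {
      mine <- n_bound(cg, n)
      brute <- brute_cliques(cg$vertices, cg$edges, n)
      expect_equal(ncol(mine), ncol(brute))
      if (ncol(mine) > 0) {
        key <- function(mm) sort(apply(mm, 2, paste, collapse = "-"))
        expect_equal(key(mine), key(brute))
      }
      if (!is.null(ig)) {
        ig_n <- igraph::cliques(ig, min = n, max = n)
        expect_equal(ncol(mine), length(ig_n))
      }
    }
    # summarize_level totals agree with per-graph enumeration
    for (n in 1:3) {
      s <- summarize_level(g, n)
      expect_equal(s$total_conformers,
                   as.integer(ncol(brute_cliques(cg$vertices, cg$edges,
                                                 n)) > 0))
    }
  }
})

test_that("level summaries count combinations over all C(m, n) subsets", {
  # 5 conformers complete on 3 motifs -> total = 5 at every level, sd 0
  acc <- matrix(TRUE, 5, 3)
  g <- build_graphs(fake_singles(acc), fake_pairs(acc, function(...) TRUE))
  for (n in 1:3) {
    s <- summarize_level(g, n)
    expect_equal(s$total_conformers, 5L)
    expect_equal(s$mean_conformers, 5)
    expect_equal(s$sd_conformers, 0)
    expect_length(s$per_combination_counts, choose(3, n))
  }
  expect_equal(summarize_level(g, 4)$total_conformers, 0L)
  # hand-checked mixed fixture: conformer 1 complete, conformer 2 only
  # pair (1,2), conformer 3 nothing
  acc <- rbind(c(TRUE, TRUE, TRUE), c(TRUE, TRUE, FALSE),
               c(FALSE, FALSE, FALSE))
  g2 <- build_graphs(fake_singles(acc), fake_pairs(acc, function(...) TRUE))
  s1 <- summarize_level(g2, 1)
  expect_equal(s1$total_conformers, 2L)
  expect_equal(unname(s1$per_combination_counts), c(2, 2, 1))
  s2 <- summarize_level(g2, 2)
  expect_equal(s2$total_conformers, 2L)
  expect_equal(unname(s2$per_combination_counts), c(2, 1, 1))
  expect_equal(s2$mean_conformers, mean(c(2, 1, 1)))
  s3 <- summarize_level(g2, 3)
  expect_equal(s3$total_conformers, 1L)
  expect_equal(max_simultaneous(g2), 3L)
})

test_that("n-bound levels are nested", {
  sys <- tiny_system()
  g <- build_graphs(sys$singles, sys$pairs)
  lt <- bound_level_table(g)
  members <- attr(lt, "members")
  expect_true(all(diff(lt$total_conformers) <= 0))
  for (r in 2:length(members)) {
    expect_true(all(members[[r]] <= members[[r - 1]]))
  }
  # a K5 among empties
  acc <- rbind(matrix(FALSE, 3, 5), rep(TRUE, 5))
  g5 <- build_graphs(fake_singles(acc), fake_pairs(acc, function(...) TRUE))
  expect_equal(max_simultaneous(g5), 5L)
})
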