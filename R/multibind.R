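# Inference of n-bound sub-ensembles from single and pairwise docking
# feasibility. A conformer can hold ligands at a motif subset S
# simultaneously iff every motif in S is accessible and every pair in S
# is pair-feasible, i.e. S is a clique of the conformer's compatibility
# graph. This deliberately reproduces the pairwise approximation of the
# underlying method (no three-body ligand checks).

#' Build per-conformer motif compatibility graphs
#'
#' Vertices are the accessible motifs of a conformer, edges the feasible
#' motif pairs.
#'
#' @param singles data.frame from [dock_all].
#' @param pairs data.frame from [dock_pairs].
#' @return Object of class `idr_compat`: `accessible` (conformers x
#'   motifs logical matrix), `pair_feasible` (conformers x motif-pairs
#'   logical matrix), `pair_index` (2 x n_pairs motif pairs, i < j),
#'   `n_motifs`, `n_conformers`.
#' @export
build_graphs <- function(singles, pairs) {
  n <- attr(singles, "n_conformers")
  nm <- attr(singles, "n_motifs")
  if (is.null(n)) n <- max(singles$conformer_id)
  if (is.null(nm)) nm <- max(singles$motif)
  acc <- matrix(FALSE, n, nm)
  acc[cbind(singles$conformer_id, singles$motif)] <- singles$accessible
  pair_index <- if (nm >= 2) utils::combn(nm, 2) else
    matrix(integer(0), nrow = 2)
  np <- ncol(pair_index)
  pf <- matrix(FALSE, n, np)
  if (nrow(pairs) > 0) {
    col_of <- matrix(0L, nm, nm)
    for (p in seq_len(np)) col_of[pair_index[1, p], pair_index[2, p]] <- p
    bad <- !acc[cbind(pairs$conformer_id, pairs$motif_i)] |
      !acc[cbind(pairs$conformer_id, pairs$motif_j)]
    if (any(bad)) {
      stop("pair record references a non-accessible motif", call. = FALSE)
    }
    pf[cbind(pairs$conformer_id,
             col_of[cbind(pairs$motif_i, pairs$motif_j)])] <- pairs$feasible
  }
  structure(list(accessible = acc, pair_feasible = pf,
                 pair_index = pair_index, n_motifs = nm, n_conformers = n),
            class = "idr_compat")
}

#' @export
print.idr_compat <- function(x, ...) {
  cat(sprintf("<idr_compat> %d conformers, %d motifs, %d feasible pairs\n",
              x$n_conformers, x$n_motifs, sum(x$pair_feasible)))
  invisible(x)
}

#' Extract one conformer's compatibility graph
#' @param graphs `idr_compat` from [build_graphs].
#' @param id Conformer index.
#' @return List with `vertices` (accessible motif indices) and `edges`
#'   (2-column matrix of feasible pairs).
#' @export
conformer_graph <- function(graphs, id) {
  v <- which(graphs$accessible[id, ])
  e <- graphs$pair_index[, graphs$pair_feasible[id, ], drop = FALSE]
  list(vertices = v, edges = t(e))
}

# Logical clique-indicator matrix: conformers x C(m, n) subsets.
# A subset is a clique for a conformer iff all its motif pairs are
# feasible (pair feasibility implies vertex accessibility) and, for
# n == 1, iff the motif is accessible.
#' @noRd
clique_indicator <- function(graphs, n, subsets = NULL) {
  m <- graphs$n_motifs
  if (is.null(subsets)) {
    if (n > m) return(list(subsets = matrix(integer(0), nrow = n),
                           indicator = matrix(FALSE, graphs$n_conformers, 0)))
    subsets <- utils::combn(m, n)
  }
  if (n == 1) {
    return(list(subsets = subsets,
                indicator = graphs$accessible[, subsets[1, ], drop = FALSE]))
  }
  pi2 <- graphs$pair_index
  col_of <- matrix(0L, m, m)
  for (p in seq_len(ncol(pi2))) col_of[pi2[1, p], pi2[2, p]] <- p
  P <- graphs$pair_feasible
  storage.mode(P) <- "numeric"
  nsub <- ncol(subsets)
  npair_sub <- choose(n, 2)
  M <- matrix(0, ncol(pi2), nsub)
  for (s in seq_len(nsub)) {
    prs <- utils::combn(subsets[, s], 2)
    M[col_of[cbind(prs[1, ], prs[2, ])], s] <- 1
  }
  ind <- (P %*% M) == npair_sub
  list(subsets = subsets, indicator = ind)
}

#' Motif subsets bindable simultaneously by one conformer
#'
#' The n-vertex cliques of a conformer's compatibility graph: exactly the
#' motif n-subsets at which the conformer can hold n ligands at once
#' under the pairwise-feasibility rule.
#'
#' @param graph A single-conformer graph from [conformer_graph] (list with
#'   `vertices` and `edges`).
#' @param n Ligand count, >= 1.
#' @return Matrix with `n` rows, one column per feasible motif subset
#'   (empty when none).
#' @export
n_bound <- function(graph, n) {
  stopifnot(n >= 1)
  v <- graph$vertices
  if (n > length(v)) return(matrix(integer(0), nrow = n))
  if (n == 1) return(matrix(v, nrow = 1))
  adj <- matrix(FALSE, max(c(v, 1)), max(c(v, 1)))
  if (nrow(graph$edges) > 0) {
    adj[graph$edges] <- TRUE
    adj[graph$edges[, 2:1, drop = FALSE]] <- TRUE
  }
  cand <- utils::combn(v, n)
  ok <- apply(cand, 2, function(s) {
    prs <- utils::combn(s, 2)
    all(adj[t(prs)])
  })
  cand[, ok, drop = FALSE]
}

#' Summarize an n-bound level across the ensemble
#'
#' @param graphs `idr_compat` from [build_graphs].
#' @param n Ligand count.
#' @return List of class `idr_bound_summary`: `n`, `total_conformers`
#'   (conformers with at least one feasible n-subset),
#'   `per_combination_counts` (named vector over all C(m, n) subsets,
#'   zero-count combinations included), `mean_conformers`,
#'   `sd_conformers` over combinations, and `member` (logical vector over
#'   conformers).
#' @export
summarize_level <- function(graphs, n) {
  ci <- clique_indicator(graphs, n)
  counts <- colSums(ci$indicator)
  names(counts) <- apply(ci$subsets, 2, paste, collapse = "+")
  member <- rowSums(ci$indicator) > 0
  structure(list(n = n, total_conformers = sum(member),
                 per_combination_counts = counts,
                 mean_conformers = if (length(counts)) mean(counts) else NA_real_,
                 sd_conformers = if (length(counts) > 1) stats::sd(counts) else 0,
                 member = member),
            class = "idr_bound_summary")
}

#' Maximum number of simultaneously bindable ligands
#'
#' Max over conformers of the maximum clique size of the compatibility
#' graph.
#'
#' @param graphs `idr_compat`.
#' @return Integer (0 when no motif is accessible anywhere).
#' @export
max_simultaneous <- function(graphs) {
  best <- 0L
  for (n in seq_len(graphs$n_motifs)) {
    ci <- clique_indicator(graphs, n)
    if (ncol(ci$indicator) == 0 || !any(ci$indicator)) break
    best <- n
  }
  best
}

#' n-bound level table across all populated levels
#'
#' @param graphs `idr_compat`.
#' @param max_n Highest level to tabulate (default: all motifs).
#' @return data.frame with one row per level n: `total_conformers`,
#'   `mean_conformers`, `sd_conformers`; the full-ensemble row (n = 0) is
#'   included first. Level membership vectors are attached as attribute
#'   `members` (list indexed by as.character(n)).
#' @export
bound_level_table <- function(graphs, max_n = NULL) {
  if (is.null(max_n)) max_n <- graphs$n_motifs
  rows <- list(data.frame(n = 0, total_conformers = graphs$n_conformers,
                          mean_conformers = graphs$n_conformers,
                          sd_conformers = 0))
  members <- list("0" = rep(TRUE, graphs$n_conformers))
  for (n in seq_len(max_n)) {
    s <- summarize_level(graphs, n)
    rows[[length(rows) + 1]] <- data.frame(
      n = n, total_conformers = s$total_conformers,
      mean_conformers = s$mean_conformers, sd_conformers = s$sd_conformers)
    members[[as.character(n)]] <- s$member
    if (s$total_conformers == 0) break
  }
  out <- do.call(rbind, rows)
  attr(out, "members") <- members
  out
}
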