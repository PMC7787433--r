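# Statistical co-accessibility of motif pairs: hypergeometric enrichment
# with Benjamini-Hochberg correction, mutual information, and signed
# partial mutual information over binary per-conformer accessibility.

#' Upper-tail hypergeometric p-value for co-accessibility
#'
#' Probability of observing at least `k` conformers feasibly binding both
#' motifs when `K` of `N` conformers allow motif i, `n` allow motif j,
#' and the two were independent: P(X >= k), X ~ Hypergeometric(N, K, n).
#'
#' @param N Full ensemble size.
#' @param K Conformers accessible at motif i.
#' @param n Conformers accessible at motif j.
#' @param k Conformers feasibly binding both simultaneously.
#' @return p-value.
#' @export
hypergeom_pvalue <- function(N, K, n, k) {
  if (any(c(N, K, n, k) < 0) || k > min(K, n) || K > N || n > N) {
    stop("invalid hypergeometric input: need 0 <= k <= min(K, n) <= N",
         call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement over the family of tested motif pairs.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_correct <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Mutual information of a 2x2 contingency table
#'
#' MI = sum p(a,b) log2( p(a,b) / (p(a) p(b)) ), with 0 log 0 = 0.
#' Reported in bits.
#'
#' @param joint_counts 2x2 nonnegative count matrix (rows: state of motif
#'   i, columns: state of motif j).
#' @return MI in bits (>= 0).
#' @export
mutual_information <- function(joint_counts) {
  joint_counts <- as.matrix(joint_counts)
  stopifnot(all(dim(joint_counts) == c(2, 2)), all(joint_counts >= 0))
  tot <- sum(joint_counts)
  if (tot == 0) stop("empty contingency table", call. = FALSE)
  p <- joint_counts / tot
  pa <- rowSums(p); pb <- colSums(p)
  mi <- 0
  for (a in 1:2) for (b in 1:2) {
    if (p[a, b] > 0) {
      mi <- mi + p[a, b] * log2(p[a, b] / (pa[a] * pb[b]))
    }
  }
  max(mi, 0)
}

#' Signed partial mutual information
#'
#' The mutual information signed by the direction of the association:
#' positive when the observed co-occurrence p(1,1) exceeds the
#' independence expectation p(1,.) p(.,1) (binding at one motif increases
#' the likelihood of binding at the other), negative when it falls short.
#'
#' @param joint_counts 2x2 count matrix with cell \[1,1\] = both bound
#'   ... cell \[2,2\] = neither.
#' @return Signed MI in bits; `abs(partial_mi) == mutual_information`.
#' @export
partial_mi <- function(joint_counts) {
  joint_counts <- as.matrix(joint_counts)
  mi <- mutual_information(joint_counts)
  tot <- sum(joint_counts)
  p11 <- joint_counts[1, 1] / tot
  expected <- (sum(joint_counts[1, ]) / tot) * (sum(joint_counts[, 1]) / tot)
  sign(p11 - expected) * mi
}

#' Full co-accessibility analysis over motif pairs
#'
#' Assembles, for every motif pair, the hypergeometric input (N = ensemble
#' size, K and n = single-motif accessible counts, k = conformers whose
#' pair docking is feasible under the three-pair rule) and computes the
#' p-value, BH q-value, mutual information and signed partial MI. The
#' hypergeometric enrichment uses the pair-feasible k (simultaneous
#' binding); the 2x2 mutual-information table is built from the joint
#' accessibility states of the two motifs (its both-accessible count can
#' exceed k when the two placed ligand bodies collide, and a contingency
#' table over binary states must use the state overlap to stay
#' well-formed).
#'
#' @param singles data.frame from [dock_all].
#' @param pairs data.frame from [dock_pairs].
#' @param N Full ensemble size; defaults to the count recorded in
#'   `singles`.
#' @param alpha Significance level on q (default 0.05).
#' @return data.frame of class `idr_pair_stats`, one row per motif pair:
#'   `motif_i`, `motif_j`, `N`, `K`, `n`, `k`, `p_value`, `q_value`,
#'   `mi`, `part_mi`, `co_accessible`. Square matrices of p, q, MI and
#'   part-MI are attached as attribute `matrices`.
#' @export
coaccessibility_analysis <- function(singles, pairs, N = NULL, alpha = 0.05) {
  if (is.null(N)) N <- attr(singles, "n_conformers")
  nm <- attr(singles, "n_motifs")
  if (is.null(nm)) nm <- max(singles$motif)
  if (is.null(N)) N <- max(singles$conformer_id)
  acc <- matrix(FALSE, N, nm)
  acc[cbind(singles$conformer_id, singles$motif)] <- singles$accessible
  acc_counts <- colSums(acc)
  pair_idx <- utils::combn(nm, 2)
  np <- ncol(pair_idx)
  k <- integer(np)
  for (p in seq_len(np)) {
    sel <- pairs$motif_i == pair_idx[1, p] & pairs$motif_j == pair_idx[2, p]
    k[p] <- sum(pairs$feasible[sel])
  }
  K <- acc_counts[pair_idx[1, ]]
  n_j <- acc_counts[pair_idx[2, ]]
  pvals <- numeric(np); mi <- numeric(np); pmi <- numeric(np)
  for (p in seq_len(np)) {
    pvals[p] <- hypergeom_pvalue(N, K[p], n_j[p], k[p])
    k_acc <- sum(acc[, pair_idx[1, p]] & acc[, pair_idx[2, p]])
    tab <- matrix(c(k_acc, n_j[p] - k_acc,
                    K[p] - k_acc, N - K[p] - n_j[p] + k_acc), 2, 2)
    mi[p] <- mutual_information(tab)
    pmi[p] <- partial_mi(tab)
  }
  q <- bh_correct(pvals)
  out <- data.frame(motif_i = pair_idx[1, ], motif_j = pair_idx[2, ],
                    N = N, K = K, n = n_j, k = k,
                    p_value = pvals, q_value = q, mi = mi, part_mi = pmi,
                    co_accessible = q < alpha)
  mat <- function(v) {
    m <- matrix(NA_real_, nm, nm)
    m[cbind(pair_idx[1, ], pair_idx[2, ])] <- v
    m[cbind(pair_idx[2, ], pair_idx[1, ])] <- v
    m
  }
  attr(out, "matrices") <- list(p = mat(pvals), q = mat(q), mi = mat(mi),
                                part_mi = mat(pmi))
  attr(out, "alpha") <- alpha
  class(out) <- c("idr_pair_stats", class(out))
  out
}

#' Simulate binary per-motif accessibility masks
#'
#' Synthetic ensemble of accessibility indicators for calibration and
#' planted-signal studies: each motif is accessible independently with
#' probability `p_access`, except for optional planted pair couplings.
#' A coupling `list(i, j, rho)` mixes motif j's mask toward motif i's:
#' with probability `rho` conformer-level accessibility at j copies the
#' state at i (excess co-occurrence), the rest stays independent.
#'
#' @param n_conformers Number of conformers.
#' @param n_motifs Number of motifs.
#' @param p_access Per-motif accessibility probability (scalar or vector).
#' @param couplings List of `list(i =, j =, rho =)` planted couplings.
#' @param seed Integer seed.
#' @return List with `accessible` (logical matrix), and `singles` /
#'   `pairs` data.frames in the same shape [dock_all] / [dock_pairs]
#'   produce (pair feasibility = AND of the two masks), ready for
#'   [coaccessibility_analysis].
#' @export
simulate_accessibility <- function(n_conformers, n_motifs, p_access = 0.3,
                                   couplings = list(), seed = 1L) {
  p_access <- rep_len(p_access, n_motifs)
  acc <- with_local_seed(seed, {
    a <- vapply(seq_len(n_motifs), function(j) {
      stats::runif(n_conformers) < p_access[j]
    }, logical(n_conformers))
    for (cp in couplings) {
      copy <- stats::runif(n_conformers) < cp$rho
      a[copy, cp$j] <- a[copy, cp$i]
    }
    a
  })
  singles <- data.frame(
    conformer_id = rep(seq_len(n_conformers), times = n_motifs),
    motif = rep(seq_len(n_motifs), each = n_conformers),
    clashes = NA_integer_, rmsd = NA_real_,
    accessible = as.vector(acc))
  attr(singles, "n_conformers") <- n_conformers
  attr(singles, "n_motifs") <- n_motifs
  pair_idx <- utils::combn(n_motifs, 2)
  chunks <- lapply(seq_len(ncol(pair_idx)), function(p) {
    i <- pair_idx[1, p]; j <- pair_idx[2, p]
    both <- which(acc[, i] & acc[, j])
    if (length(both) == 0) return(NULL)
    data.frame(conformer_id = both, motif_i = i, motif_j = j,
               clashes_i = NA_integer_, clashes_j = NA_integer_,
               clashes_ll = NA_integer_, feasible = TRUE)
  })
  chunks <- chunks[!vapply(chunks, is.null, logical(1))]
  pairs <- if (length(chunks)) do.call(rbind, chunks) else
    data.frame(conformer_id = integer(0), motif_i = integer(0),
               motif_j = integer(0), clashes_i = integer(0),
               clashes_j = integer(0), clashes_ll = integer(0),
               feasible = logical(0))
  attr(pairs, "n_conformers") <- n_conformers
  attr(pairs, "n_motifs") <- n_motifs
  list(accessible = acc, singles = singles, pairs = pairs)
}

#' Write pair-statistic matrices as TSV files
#'
#' @param stats `idr_pair_stats` from [coaccessibility_analysis].
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_pair_matrices <- function(stats, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mats <- attr(stats, "matrices")
  paths <- character(0)
  for (nm in names(mats)) {
    p <- file.path(dir, paste0("pair_", nm, ".tsv"))
    utils::write.table(mats[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
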