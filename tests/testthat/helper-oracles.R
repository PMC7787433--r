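# Independent brute-force oracles shared across test files. These stay
# deliberately naive (O(n^2) scans, exhaustive enumeration) so they are
# independent of the production implementations they check.

# O(n^2) cross-set clash count
brute_clash <- function(A, ra, B, rb, tol) {
  count <- 0L
  for (i in seq_len(nrow(A))) {
    d <- sqrt(colSums((t(B) - A[i, ])^2))
    count <- count + sum(d < ra[i] + rb - tol)
  }
  count
}

# exhaustive n-clique enumeration from a vertex set + edge matrix
brute_cliques <- function(vertices, edges, n) {
  adj <- matrix(FALSE, 32, 32)
  if (nrow(edges) > 0) {
    adj[edges] <- TRUE
    adj[edges[, 2:1, drop = FALSE]] <- TRUE
  }
  if (n > length(vertices)) return(matrix(integer(0), nrow = n))
  if (n == 1) return(matrix(vertices, nrow = 1))
  cand <- utils::combn(vertices, n)
  keep <- apply(cand, 2, function(s) {
    prs <- utils::combn(s, 2)
    all(adj[t(prs)])
  })
  cand[, keep, drop = FALSE]
}

# entropy-route mutual information (bits), independent of the sum formula
mi_entropy <- function(tab) {
  p <- tab / sum(tab)
  H <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
  H(rowSums(p)) + H(colSums(p)) - H(as.vector(p))
}

# hand-rolled BH step-up with monotone floor
bh_manual <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# all distinct arrangements of a charge multiset (for exhaustive delta_max)
perms_multiset <- function(n_plus, n_minus, n_zero) {
  syms <- rep(c(1, -1, 0), c(n_plus, n_minus, n_zero))
  res <- list()
  rec <- function(prefix, remaining) {
    if (length(remaining) == 0) {
      res[[length(res) + 1]] <<- prefix
      return()
    }
    for (u in unique(remaining)) {
      i <- match(u, remaining)
      rec(c(prefix, u), remaining[-i])
    }
  }
  rec(numeric(0), syms)
  res
}

# rigid-transform helper: random rotation (QR of a gaussian matrix) + shift
random_rigid <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 20))
}
apply_rigid <- function(x, rig) sweep(x %*% t(rig$R), 2, rig$t, "+")

# small cached fixtures (built once per test run)
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# a small two-motif test system: 46-residue sequence, 24 conformers
tiny_system <- function() {
  fixture("tiny_system", function() {
    seqstr <- paste0("SEAGK", "DPW", "PASGTPAEK", "DPW", "SGAETKPASGQAEKGSATSEPAKSGA")
    seq <- idr_seq("tiny", seqstr)
    hits <- find_motifs(seq, "DPW")
    tpl <- make_synthetic_template("DPW")
    cons <- motif_constraints(hits, tpl)
    ens <- generate_ensemble(seq, cons, n = 24, master_seed = 99)
    singles <- dock_all(ens, hits, tpl)
    pairs <- dock_pairs(ens, hits, tpl, singles)
    list(seq = seq, hits = hits, tpl = tpl, cons = cons, ens = ens,
         singles = singles, pairs = pairs)
  })
}
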