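# Synthetic multivalent IDR sequences.
#
# These constructors build sequences with a prescribed motif architecture
# (literal motif, ordered linker lengths, linker and flank composition) and
# are used as synthetic stand-ins for real multivalent IDRs in tests and
# demonstrations. Compositions are realized exactly (largest-remainder
# allocation) and shuffled reproducibly; assembly is rejected and reshuffled
# if a spurious motif occurrence appears outside the planted positions.

#' @noRd
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Largest-remainder integer allocation of n residues to a composition.
#' @noRd
allocate_composition <- function(composition, n) {
  if (n == 0) return(character(0))
  composition <- composition / sum(composition)
  exact <- composition * n
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0) {
    order_rem <- order(exact - base, decreasing = TRUE)
    base[order_rem[seq_len(left)]] <- base[order_rem[seq_len(left)]] + 1
  }
  rep(names(composition), times = base)
}

#' Build a sequence with a planted motif architecture
#'
#' Assembles `n_flank` flank residues, then alternating motifs and linkers
#' (in the given order), then a C-terminal flank. Linker residues are drawn
#' from `linker_composition` exactly (largest-remainder rounding over the
#' pooled linker residues) and placed by a seeded shuffle; likewise for the
#' flanks with `flank_composition`. If shuffling creates an occurrence of
#' the motif outside the planted positions, the affected pools are
#' reshuffled (deterministically, bounded retries).
#'
#' @param pattern Literal motif peptide (e.g. `"DPW"`).
#' @param linker_lengths Integer vector of inter-motif gap lengths, in
#'   sequence order; the number of motifs is `length(linker_lengths) + 1`.
#' @param linker_composition Named per-amino-acid fractions for linker
#'   residues.
#' @param flank_composition Named fractions for flank residues.
#' @param n_flank,c_flank Flank lengths before the first / after the last
#'   motif.
#' @param seed Integer seed controlling the shuffles.
#' @param id Identifier for the resulting record.
#' @return An [idr_seq]; attribute `motif_starts` holds the planted 1-based
#'   motif start positions.
#' @export
build_motif_sequence <- function(pattern, linker_lengths, linker_composition,
                                 flank_composition, n_flank, c_flank,
                                 seed = 1L, id = "synthetic") {
  pattern_chars <- strsplit(toupper(pattern), "")[[1]]
  m <- length(pattern_chars)
  linker_lengths <- as.integer(linker_lengths)
  n_motifs <- length(linker_lengths) + 1L
  pool_n <- sum(linker_lengths)
  linker_pool <- allocate_composition(linker_composition, pool_n)
  flank_pool <- allocate_composition(flank_composition, n_flank + c_flank)

  starts <- integer(n_motifs)
  starts[1] <- n_flank + 1L
  for (i in seq_len(n_motifs - 1L)) {
    starts[i + 1] <- starts[i] + m + linker_lengths[i]
  }
  total <- n_flank + c_flank + n_motifs * m + pool_n

  with_local_seed(seed, {
    for (attempt in 1:200) {
      lp <- sample(linker_pool)
      fp <- sample(flank_pool)
      res <- character(total)
      res[seq_len(n_flank)] <- fp[seq_len(n_flank)]
      if (c_flank > 0) {
        res[(total - c_flank + 1L):total] <- fp[n_flank + seq_len(c_flank)]
      }
      used <- 0L
      for (i in seq_len(n_motifs)) {
        res[starts[i]:(starts[i] + m - 1L)] <- pattern_chars
        if (i <= length(linker_lengths) && linker_lengths[i] > 0) {
          seg <- lp[used + seq_len(linker_lengths[i])]
          res[(starts[i] + m):(starts[i] + m + linker_lengths[i] - 1L)] <- seg
          used <- used + linker_lengths[i]
        }
      }
      found <- find_motifs(paste(res, collapse = ""), pattern,
                           overlapping = TRUE)$starts
      if (setequal(found, starts)) {
        out <- idr_seq(id, res)
        attr(out, "motif_starts") <- starts
        return(out)
      }
    }
  })
  stop("could not assemble a sequence without spurious motif hits",
       call. = FALSE)
}

# Compositions used by the packaged synthetic IDRs. Linker compositions
# follow the reported human linker enrichments (proline-rich for the
# Epsin-like architecture: 27% P, 23% A, 19.5% G; serine-led for the
# Eps15-like architecture: 16% S); flanks use a generic disordered,
# slightly acidic composition.
#' @noRd
SYNTH_COMPOSITIONS <- list(
  epsin_linker = c(P = 0.270, A = 0.230, G = 0.195, S = 0.110, T = 0.050,
                   Q = 0.045, E = 0.040, D = 0.030, K = 0.020, V = 0.010),
  eps15_linker = c(S = 0.16, A = 0.12, T = 0.10, G = 0.10, P = 0.08,
                   E = 0.09, D = 0.07, Q = 0.06, N = 0.05, K = 0.05,
                   V = 0.04, L = 0.04, R = 0.02, I = 0.02),
  flank = c(E = 0.10, D = 0.06, K = 0.06, R = 0.02, P = 0.10, S = 0.13,
            A = 0.11, G = 0.10, T = 0.08, Q = 0.08, N = 0.04, V = 0.05,
            L = 0.04, M = 0.01, I = 0.02)
)

#' Packaged synthetic multivalent IDR sequences
#'
#' Two synthetic sequences that reproduce the published motif architecture
#' of the two endocytic IDRs studied with this package:
#' \describe{
#'   \item{`epsin_like`}{240 residues, 8 `DPW` motifs, inter-motif gaps
#'     7, 9, 10, 10, 14, 15, 17 (in that order), proline-rich linkers.}
#'   \item{`eps15_like`}{333 residues, 15 `DPF` motifs, the 12 reported
#'     human gap lengths 2, 2, 2, 3, 3, 5, 10, 14, 17, 21, 25, 58 plus two
#'     short gaps (2 and 3) to complete the 14 gaps implied by 15 motifs,
#'     serine-led linkers.}
#' }
#' These are synthetic stand-ins: motif spacing, linker/flank composition
#' and region length match the published architecture, but the residue
#' order is randomized, so descriptor values that depend on exact residue
#' placement (kappa, omega) are not those of the real proteins.
#'
#' @param kind `"epsin_like"` or `"eps15_like"`.
#' @param seed Integer seed for the composition shuffles.
#' @return An [idr_seq] with attribute `motif_starts`.
#' @export
synthetic_idr_sequence <- function(kind = c("epsin_like", "eps15_like"),
                                   seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "epsin_like") {
    build_motif_sequence(
      pattern = "DPW",
      linker_lengths = c(7, 9, 10, 10, 14, 15, 17),
      linker_composition = SYNTH_COMPOSITIONS$epsin_linker,
      flank_composition = SYNTH_COMPOSITIONS$flank,
      n_flank = 25, c_flank = 109,
      seed = seed, id = "synthetic-epsin-like")
  } else {
    build_motif_sequence(
      pattern = "DPF",
      linker_lengths = c(2, 2, 2, 2, 3, 3, 3, 5, 10, 14, 17, 21, 25, 58),
      linker_composition = SYNTH_COMPOSITIONS$eps15_linker,
      flank_composition = SYNTH_COMPOSITIONS$flank,
      n_flank = 110, c_flank = 11,
      seed = seed, id = "synthetic-eps15-like")
  }
}
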