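# Sequence-level characterization: motif scanning, charge-patterning
# descriptors (kappa/omega), hydropathy, linker spacing and composition.

#' Scan a sequence for a literal short motif
#'
#' Finds occurrences of a literal peptide (e.g. the AP2-alpha binding
#' tripeptides `DPW` / `DPF`) left to right. By default hits may not
#' overlap: after accepting a hit at position p the scan resumes at
#' p + motif length.
#'
#' @param seq An [idr_seq] or a plain character string.
#' @param pattern Literal peptide, length >= 2.
#' @param overlapping Allow overlapping hits (default `FALSE`).
#' @return An object of class `idr_motifs`: list with `pattern`, `starts`
#'   (sorted 1-based start positions) and `motif_length`.
#' @examples
#' find_motifs("ADPWGGDPWK", "DPW")$starts  # 2, 7
#' @export
find_motifs <- function(seq, pattern, overlapping = FALSE) {
  seq <- as_idr_seq(seq)
  pattern <- toupper(pattern)
  if (nchar(pattern) < 2) stop("pattern must have length >= 2", call. = FALSE)
  validate_residues(strsplit(pattern, "")[[1]])
  s <- paste(seq$residues, collapse = "")
  m <- nchar(pattern)
  starts <- integer(0)
  i <- 1L
  while (i <= nchar(s) - m + 1L) {
    if (substr(s, i, i + m - 1L) == pattern) {
      starts <- c(starts, i)
      i <- i + (if (overlapping) 1L else m)
    } else {
      i <- i + 1L
    }
  }
  structure(list(pattern = pattern, starts = starts, motif_length = m),
            class = "idr_motifs")
}

#' @export
print.idr_motifs <- function(x, ...) {
  cat(sprintf("<idr_motifs> %s x%d at [%s]\n", x$pattern, length(x$starts),
              paste(x$starts, collapse = ", ")))
  invisible(x)
}

#' Charge-composition parameters
#'
#' Fractions of positive (K, R) and negative (D, E) residues, their sum
#' (FCR, fraction of charged residues) and difference (NCPR, net charge
#' per residue). Histidine is counted neutral.
#'
#' @param seq An [idr_seq] or character string.
#' @return List with `f_plus`, `f_minus`, `FCR`, `NCPR`.
#' @export
charge_params <- function(seq) {
  seq <- as_idr_seq(seq)
  if (length(seq$residues) == 0) stop("empty sequence", call. = FALSE)
  ch <- AA_CHARGE[seq$residues]
  f_plus <- mean(ch > 0)
  f_minus <- mean(ch < 0)
  list(f_plus = f_plus, f_minus = f_minus,
       FCR = f_plus + f_minus, NCPR = f_plus - f_minus)
}

# Blob charge asymmetry for one window size g on a ternary charge vector.
# sigma of a stretch = (f+ - f-)^2 / (f+ + f-), with 0 for uncharged blobs.
#' @noRd
blob_delta <- function(charge, g) {
  n <- length(charge)
  if (n < g) return(NA_real_)
  pos <- as.numeric(charge > 0)
  neg <- as.numeric(charge < 0)
  cp <- cumsum(pos); cn <- cumsum(neg)
  i <- seq_len(n - g + 1L)
  wp <- (cp[i + g - 1L] - c(0, cp)[i]) / g
  wn <- (cn[i + g - 1L] - c(0, cn)[i]) / g
  fcr_w <- wp + wn
  sig_w <- ifelse(fcr_w > 0, (wp - wn)^2 / fcr_w, 0)
  fp <- mean(pos); fm <- mean(neg)
  sig_seq <- if (fp + fm > 0) (fp - fm)^2 / (fp + fm) else 0
  mean((sig_w - sig_seq)^2)
}

# Deterministic most-segregated rearrangement search (compiled): maximal
# blob asymmetry over block arrangements [Sa][Z1][Other][Z2][Sb][Z3],
# scanning every end-split of one charge species and every three-way
# split of the neutral block. A single neutral block (the textbook
# construction) misses optima that park neutrals or a few charges at the
# chain ends, which matters for the short-window edge terms.
#' @noRd
delta_max <- function(n_plus, n_minus, n_zero, g) {
  .delta_max_cpp(as.integer(n_plus), as.integer(n_minus),
                 as.integer(n_zero), as.integer(g))
}

#' @noRd
kappa_from_charge <- function(charge, windows = c(5L, 6L)) {
  n_plus <- sum(charge > 0); n_minus <- sum(charge < 0)
  n_zero <- length(charge) - n_plus - n_minus
  if (n_plus + n_minus == 0) return(NA_real_)
  ratios <- vapply(windows, function(g) {
    dm <- delta_max(n_plus, n_minus, n_zero, g)
    if (!is.finite(dm) || dm == 0) return(NA_real_)
    blob_delta(charge, g) / dm
  }, numeric(1))
  mean(ratios, na.rm = TRUE)
}

#' Charge-patterning parameter kappa
#'
#' Blob-based charge asymmetry of the sequence, averaged over window sizes
#' 5 and 6 and normalized by the asymmetry of the most charge-segregated
#' rearrangement of the same composition, giving a value in \[0, 1\]
#' (0 = well-mixed charges, 1 = fully segregated).
#'
#' @param seq An [idr_seq] or character string.
#' @param windows Blob window sizes (default `c(5, 6)`).
#' @return Kappa in \[0, 1\], or `NA` when the sequence has no charged
#'   residues (kappa is undefined, not zero).
#' @examples
#' kappa_param("EEEEEKKKKK")  # 1
#' @export
kappa_param <- function(seq, windows = c(5L, 6L)) {
  seq <- as_idr_seq(seq)
  kappa_from_charge(unname(AA_CHARGE[seq$residues]), windows = windows)
}

#' Charge+proline patterning parameter omega
#'
#' Same blob/normalization machinery as [kappa_param] on the binary
#' alphabet \{D, E, K, R, P\} versus all other residues.
#'
#' @inheritParams kappa_param
#' @return Omega in \[0, 1\], `NA` if one of the two groups is empty.
#' @export
omega_param <- function(seq, windows = c(5L, 6L)) {
  seq <- as_idr_seq(seq)
  grp <- seq$residues %in% c("D", "E", "K", "R", "P")
  if (all(grp) || !any(grp)) return(NA_real_)
  charge <- ifelse(grp, 1, -1)
  kappa_from_charge(charge, windows = windows)
}

#' Mean hydropathy on the shifted Kyte-Doolittle scale
#'
#' Mean over residues of (Kyte-Doolittle value + 4.5), i.e. reported on a
#' 0-9 scale.
#'
#' @inheritParams kappa_param
#' @return Mean hydropathy in \[0, 9\].
#' @export
hydropathy_mean <- function(seq) {
  seq <- as_idr_seq(seq)
  mean(KD_HYDROPATHY[seq$residues] + 4.5)
}

#' Linker lengths and pooled composition between motif hits
#'
#' Linkers are the residues strictly between consecutive motif hits;
#' flanks before the first and after the last hit are excluded.
#'
#' @param hits An `idr_motifs` object from [find_motifs].
#' @param seq The sequence the hits were found in.
#' @return An object of class `idr_linkers`: list with `lengths` (integer
#'   vector, one per inter-motif gap) and `pooled_composition` (named
#'   per-amino-acid fraction over all linker residues).
#' @export
linkers <- function(hits, seq) {
  seq <- as_idr_seq(seq)
  if (length(hits$starts) < 2) {
    warning("fewer than 2 motif hits; empty linker set")
    return(structure(list(lengths = integer(0),
                          pooled_composition = setNames(numeric(20), AA_ALPHABET)),
                     class = "idr_linkers"))
  }
  s <- hits$starts
  m <- hits$motif_length
  lens <- s[-1] - (s[-length(s)] + m)
  segs <- unlist(lapply(seq_len(length(s) - 1L), function(i) {
    from <- s[i] + m
    to <- s[i + 1] - 1L
    if (to >= from) seq$residues[from:to] else character(0)
  }))
  comp <- setNames(numeric(20), AA_ALPHABET)
  if (length(segs) > 0) {
    tab <- table(factor(segs, levels = AA_ALPHABET))
    comp <- as.numeric(tab) / length(segs)
    names(comp) <- AA_ALPHABET
  }
  structure(list(lengths = as.integer(lens), pooled_composition = comp),
            class = "idr_linkers")
}

#' Pooled histogram of inter-motif distances across records
#'
#' Scans each record independently for the motif, pools the inter-motif
#' gap lengths and bins them.
#'
#' @param records List of [idr_seq] objects (or character strings).
#' @param pattern Literal motif peptide.
#' @param breaks Histogram breaks passed to [graphics::hist] semantics;
#'   default unit bins covering the observed range.
#' @return List with `lengths` (pooled), `counts`, `breaks`, `mids`,
#'   `median` and `mad` of the pooled distribution.
#' @export
linker_histogram <- function(records, pattern, breaks = NULL) {
  pooled <- unlist(lapply(records, function(r) {
    h <- find_motifs(r, pattern)
    if (length(h$starts) < 2) return(integer(0))
    suppressWarnings(linkers(h, r)$lengths)
  }))
  if (length(pooled) == 0) {
    return(list(lengths = integer(0), counts = integer(0),
                breaks = numeric(0), mids = numeric(0),
                median = NA_real_, mad = NA_real_))
  }
  if (is.null(breaks)) breaks <- seq(-0.5, max(pooled) + 0.5, by = 1)
  h <- hist(pooled, breaks = breaks, plot = FALSE)
  list(lengths = pooled, counts = h$counts, breaks = h$breaks, mids = h$mids,
       median = median(pooled), mad = mad(pooled))
}

#' Full sequence-characterization table
#'
#' Computes the standard descriptor panel (length, charge fractions, FCR,
#' NCPR, kappa, omega, hydropathy) for one or more sequences, one column
#' per sequence.
#'
#' @param ... Named [idr_seq] objects or character strings.
#' @return A data.frame with a `feature` column and one value column per
#'   sequence.
#' @export
seqchar_table <- function(...) {
  seqs <- list(...)
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    names(seqs) <- vapply(seqs, function(s) as_idr_seq(s)$id, character(1))
  }
  rows <- c("length", "f_minus", "f_plus", "FCR", "NCPR",
            "kappa", "omega", "hydropathy")
  out <- data.frame(feature = rows, stringsAsFactors = FALSE)
  for (nm in names(seqs)) {
    s <- as_idr_seq(seqs[[nm]])
    cp <- charge_params(s)
    out[[nm]] <- c(length(s$residues), cp$f_minus, cp$f_plus, cp$FCR, cp$NCPR,
                   kappa_param(s), omega_param(s), hydropathy_mean(s))
  }
  out
}

#' Write a characterization table as TSV
#' @param tab Data frame from [seqchar_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seqchar_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
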