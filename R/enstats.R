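# Per-conformer and per-ensemble geometry/energy statistics: radius of
# gyration, end-to-end distance, sliding-window R_G, a pluggable energy
# scorer, and 20th-percentile quadrant classification in EED-energy space.

#' Radius of gyration
#'
#' Unweighted root-mean-squared distance of the selected atoms to their
#' centroid.
#'
#' @param conformer `idr_conformer`, or a plain numeric atoms x 3 matrix.
#' @param selection Optional integer atom-row selection (default: all
#'   stored atoms, i.e. backbone plus side-chain beads).
#' @return R_G in Angstrom.
#' @export
radius_of_gyration <- function(conformer, selection = NULL) {
  xyz <- if (is.matrix(conformer)) conformer else conformer$coords
  if (!is.null(selection)) xyz <- xyz[selection, , drop = FALSE]
  if (nrow(xyz) == 0) stop("empty atom selection", call. = FALSE)
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

#' End-to-end distance
#'
#' Euclidean distance between the CA atoms of the first and last residue
#' (configurable to N of the first vs C of the last).
#'
#' @param conformer `idr_conformer`.
#' @param atoms `"ca"` (default, CA to CA) or `"nc"` (N-terminal N to
#'   C-terminal C).
#' @return EED in Angstrom.
#' @export
end_to_end <- function(conformer, atoms = c("ca", "nc")) {
  atoms <- match.arg(atoms)
  at <- conformer$atom_table
  n <- max(at$res_index)
  if (atoms == "ca") {
    a <- which(at$res_index == 1 & at$name == "CA")
    b <- which(at$res_index == n & at$name == "CA")
  } else {
    a <- which(at$res_index == 1 & at$name == "N")
    b <- which(at$res_index == n & at$name == "C")
  }
  sqrt(sum((conformer$coords[a, ] - conformer$coords[b, ])^2))
}

#' Sliding-window radius of gyration along the chain
#'
#' R_G of all stored atoms of each `window`-residue span, one value per
#' window start.
#'
#' @param conformer `idr_conformer`.
#' @param window Window length in residues (default 50).
#' @param step Start offset between windows (default 1).
#' @return data.frame with `start` (first residue of the window) and `rg`.
#' @export
sliding_window_rg <- function(conformer, window = 50L, step = 1L) {
  at <- conformer$atom_table
  n <- max(at$res_index)
  if (window > n) stop("window longer than the chain", call. = FALSE)
  starts <- seq.int(1L, n - window + 1L, by = step)
  rg <- vapply(starts, function(s) {
    rows <- which(at$res_index >= s & at$res_index < s + window)
    radius_of_gyration(conformer$coords[rows, , drop = FALSE])
  }, numeric(1))
  data.frame(start = starts, rg = rg)
}

# --- energy scorer registry -------------------------------------------

scorer_registry <- new.env(parent = emptyenv())

#' Register an energy scorer
#'
#' A scorer is a function `f(conformer)` returning a single number; lower
#' values should correspond to more compact / more favourable conformers.
#'
#' @param name Scorer name.
#' @param fn Scoring function.
#' @return `name`, invisibly.
#' @export
register_scorer <- function(name, fn) {
  stopifnot(is.function(fn))
  assign(name, fn, envir = scorer_registry)
  invisible(name)
}

#' Conformer energy through a registered scorer
#'
#' The default scorer, `"ca_contacts"`, scores compactness as minus the
#' number of CA-CA contacts closer than 8 Angstrom between residues at
#' least 3 apart in sequence: compact conformers have many contacts and
#' hence low (negative) energy, preserving the compact = low-energy
#' pairing used in the quadrant analysis. This is a structural proxy, not
#' a physical force field; quadrant outputs carry the scorer name.
#'
#' @param conformer `idr_conformer`.
#' @param scorer Registered scorer name (default `"ca_contacts"`).
#' @return Scorer units (dimensionless for the default).
#' @export
conformer_energy <- function(conformer, scorer = "ca_contacts") {
  if (!exists(scorer, envir = scorer_registry)) {
    stop(sprintf("unknown scorer '%s'; registered: %s", scorer,
                 paste(ls(scorer_registry), collapse = ", ")), call. = FALSE)
  }
  get(scorer, envir = scorer_registry)(conformer)
}

#' @noRd
ca_rows <- function(atom_table) which(atom_table$name == "CA")

# default scorer installed at load time
#' @noRd
scorer_ca_contacts <- function(conformer, cutoff = 8, min_sep = 3L) {
  ca <- conformer$coords[ca_rows(conformer$atom_table), , drop = FALSE]
  -.ca_contact_count_cpp(ca, cutoff, as.integer(min_sep))
}

.onLoad <- function(libname, pkgname) {
  register_scorer("ca_contacts", scorer_ca_contacts)
}

# --- ensemble-level tables --------------------------------------------

#' Per-conformer dimension and energy records
#'
#' @param ensemble `idr_ensemble`.
#' @param scorer Energy scorer name (see [conformer_energy]).
#' @return data.frame with `conformer_id`, `rg`, `eed`, `energy`; scorer
#'   name kept as attribute `scorer`.
#' @export
dimension_records <- function(ensemble, scorer = "ca_contacts") {
  n <- ensemble$n_conformers
  ca <- ca_rows(ensemble$atom_table)
  rg <- numeric(n); eed <- numeric(n); en <- numeric(n)
  first_ca <- ca[1]; last_ca <- ca[length(ca)]
  for (i in seq_len(n)) {
    xyz <- ensemble$coords[, , i]
    rg[i] <- radius_of_gyration(xyz)
    eed[i] <- sqrt(sum((xyz[first_ca, ] - xyz[last_ca, ])^2))
    en[i] <- conformer_energy(get_conformer(ensemble, i), scorer)
  }
  out <- data.frame(conformer_id = seq_len(n), rg = rg, eed = eed,
                    energy = en)
  attr(out, "scorer") <- scorer
  out
}

#' Dimension statistics of n-bound sub-ensembles
#'
#' Joins an n-bound level table with per-conformer dimension records and
#' reports mean/sd of R_G and EED per level.
#'
#' @param level_table Output of [bound_level_table] (carries level
#'   membership).
#' @param records Output of [dimension_records].
#' @return data.frame with one row per level: conformer totals plus
#'   `rg_mean`, `rg_sd`, `eed_mean`, `eed_sd`.
#' @export
bound_dimension_table <- function(level_table, records) {
  members <- attr(level_table, "members")
  stats <- lapply(seq_len(nrow(level_table)), function(r) {
    mem <- members[[as.character(level_table$n[r])]]
    sub <- records[mem, , drop = FALSE]
    data.frame(rg_mean = mean(sub$rg), rg_sd = stats::sd(sub$rg),
               eed_mean = mean(sub$eed), eed_sd = stats::sd(sub$eed))
  })
  cbind(level_table, do.call(rbind, stats))
}

#' Quadrant thresholds from a reference ensemble
#'
#' The low/high cut on each axis is the given percentile (default 20) of
#' the reference records.
#'
#' @param records Reference [dimension_records] (normally the full
#'   ensemble).
#' @param percentile Percentile in (0, 100), default 20.
#' @return List of class `idr_quadrant_thresholds`: `eed_cut`,
#'   `energy_cut`, `percentile`, `scorer`.
#' @export
quadrant_thresholds <- function(records, percentile = 20) {
  structure(list(
    eed_cut = unname(stats::quantile(records$eed, percentile / 100,
                                     type = 7)),
    energy_cut = unname(stats::quantile(records$energy, percentile / 100,
                                        type = 7)),
    percentile = percentile,
    scorer = attr(records, "scorer")),
    class = "idr_quadrant_thresholds")
}

#' Classify conformers into EED-energy quadrants
#'
#' "Low" is strict `<` the cut. Fractions are reported in the order
#' (low EED, low energy), (low EED, high energy), (high EED, high energy),
#' (high EED, low energy).
#'
#' @param records [dimension_records] rows to classify (any subset).
#' @param thresholds [quadrant_thresholds] from the reference ensemble.
#' @return Named numeric fractions summing to 1.
#' @export
quadrant_classify <- function(records, thresholds) {
  low_eed <- records$eed < thresholds$eed_cut
  low_en <- records$energy < thresholds$energy_cut
  n <- nrow(records)
  c(low_eed_low_energy = sum(low_eed & low_en) / n,
    low_eed_high_energy = sum(low_eed & !low_en) / n,
    high_eed_high_energy = sum(!low_eed & !low_en) / n,
    high_eed_low_energy = sum(!low_eed & low_en) / n)
}

#' Quadrant fractions per n-bound level
#'
#' @param level_table Output of [bound_level_table].
#' @param records Full-ensemble [dimension_records].
#' @param thresholds [quadrant_thresholds]; default computed from
#'   `records` at the 20th percentile.
#' @return data.frame, one row per level with the four quadrant fractions.
#' @export
bound_quadrant_table <- function(level_table, records, thresholds = NULL) {
  if (is.null(thresholds)) thresholds <- quadrant_thresholds(records)
  members <- attr(level_table, "members")
  rows <- lapply(seq_len(nrow(level_table)), function(r) {
    mem <- members[[as.character(level_table$n[r])]]
    as.data.frame(as.list(quadrant_classify(records[mem, , drop = FALSE],
                                            thresholds)))
  })
  out <- cbind(level_table[, "n", drop = FALSE], do.call(rbind, rows))
  attr(out, "scorer") <- thresholds$scorer
  out
}
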