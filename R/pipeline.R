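# End-to-end orchestration: sequence characterization -> ensemble
# generation -> docking -> multivalent occupancy -> dimension/energy
# statistics -> co-accessibility, with TSV reporting and full
# seed-determinism from one master seed.

#' Run configuration
#'
#' Collects every knob of an end-to-end run. Either `fasta` (+ optional
#' `fasta_region`) or `sequence` must be given.
#'
#' @param sequence An [idr_seq], a character string, or `NULL` when
#'   reading from FASTA.
#' @param fasta,fasta_id,fasta_region FASTA path, record id prefix and
#'   `c(start, end)` region (used when `sequence` is `NULL`).
#' @param motif Literal motif peptide (default `"DPW"`).
#' @param helix_span Integer residue span constrained to a helix at the
#'   N-terminus (default `1:18`); `NULL` for none.
#' @param n_conformers Ensemble size (default 10000; cluster-scale runs
#'   simply raise this).
#' @param master_seed Master RNG seed.
#' @param clash_threshold Docking clash threshold (default 100).
#' @param overlap_tol Allowed atom-pair overlap, Angstrom (default 0.4).
#' @param sliding_window Window length for local R_G profiles (default
#'   50).
#' @param quadrant_percentile Percentile for quadrant cuts (default 20).
#' @param alpha Co-accessibility significance level (default 0.05).
#' @param scorer Energy scorer name (default `"ca_contacts"`).
#' @param template `idr_template` or `NULL` to build the default
#'   synthetic template for the motif.
#' @param max_level Deepest n-bound level to tabulate (default: number of
#'   motifs).
#' @param out_dir Output directory for TSV artifacts, or `NULL` to skip
#'   writing.
#' @return List of class `idr_config`.
#' @export
run_config <- function(sequence = NULL, fasta = NULL, fasta_id = NULL,
                       fasta_region = NULL, motif = "DPW",
                       helix_span = 1:18, n_conformers = 10000,
                       master_seed = 1L, clash_threshold = 100,
                       overlap_tol = 0.4, sliding_window = 50,
                       quadrant_percentile = 20, alpha = 0.05,
                       scorer = "ca_contacts", template = NULL,
                       max_level = NULL, out_dir = NULL) {
  if (is.null(sequence) && is.null(fasta)) {
    stop("either sequence or fasta must be given", call. = FALSE)
  }
  stopifnot(clash_threshold > 0, overlap_tol >= 0,
            quadrant_percentile > 0, quadrant_percentile < 100)
  cfg <- list(sequence = if (!is.null(sequence)) as_idr_seq(sequence),
              fasta = fasta, fasta_id = fasta_id,
              fasta_region = fasta_region, motif = motif,
              helix_span = helix_span,
              n_conformers = as.integer(n_conformers),
              master_seed = as.integer(master_seed),
              clash_threshold = clash_threshold, overlap_tol = overlap_tol,
              sliding_window = as.integer(sliding_window),
              quadrant_percentile = quadrant_percentile, alpha = alpha,
              scorer = scorer, template = template, max_level = max_level,
              out_dir = out_dir)
  class(cfg) <- "idr_config"
  cfg
}

#' @noRd
config_hash <- function(config) {
  keep <- config[setdiff(names(config), "out_dir")]
  digest::digest(keep, algo = "md5")
}

#' Run the full occupancy analysis
#'
#' Executes the whole workflow for one configuration: motif scan and
#' sequence descriptors, constrained ensemble generation, docking at
#' every motif, pairwise docking, n-bound level inference, dimension and
#' quadrant statistics per level, sliding-window R_G per level, and motif
#' pair co-accessibility. All randomness derives from
#' `config$master_seed`.
#'
#' @param config An [run_config] object.
#' @param progress Print per-stage progress messages.
#' @return List of class `idr_report`: `config_hash`, `sequence_params`,
#'   `motifs`, `linkers`, `levels` (dimension table per n-bound level),
#'   `quadrants`, `pair_stats`, `window_rg` (per-level mean profile),
#'   `counts` (docking accounting), plus the intermediate `singles`,
#'   `pairs` records and the `dimension` records.
#' @export
run_pipeline <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "idr_config"))
  say <- function(...) if (progress) message(sprintf(...))

  seq <- config$sequence
  if (is.null(seq)) {
    seq <- read_fasta_region(config$fasta, id = config$fasta_id,
                             region = config$fasta_region)
  }
  say("stage seqchar: %d residues", length(seq$residues))
  hits <- find_motifs(seq, config$motif)
  if (length(hits$starts) == 0) stop("no motif hits in sequence", call. = FALSE)
  seq_params <- seqchar_table(seq = seq)
  linker_set <- if (length(hits$starts) >= 2) linkers(hits, seq) else NULL

  template <- config$template
  if (is.null(template)) {
    template <- make_synthetic_template(motif_seq = config$motif)
  }

  constraints <- motif_constraints(hits, template)
  if (!is.null(config$helix_span)) {
    helix <- setdiff(config$helix_span, unlist(lapply(constraints, `[[`,
                                                      "range")))
    if (length(helix) > 0) {
      constraints <- c(list(dihedral_constraint(helix, "helix")), constraints)
    }
  }

  say("stage confgen: %d conformers", config$n_conformers)
  ens <- generate_ensemble(seq, constraints, n = config$n_conformers,
                           master_seed = config$master_seed,
                           progress = progress)

  say("stage dock: %d x %d dockings", config$n_conformers,
      length(hits$starts))
  singles <- dock_all(ens, hits, template, threshold = config$clash_threshold,
                      overlap_tol = config$overlap_tol)
  pairs <- dock_pairs(ens, hits, template, singles,
                      threshold = config$clash_threshold,
                      overlap_tol = config$overlap_tol)

  say("stage multibind")
  graphs <- build_graphs(singles, pairs)
  level_table <- bound_level_table(graphs, max_n = config$max_level)

  say("stage enstats")
  records <- dimension_records(ens, scorer = config$scorer)
  levels <- bound_dimension_table(level_table, records)
  thresholds <- quadrant_thresholds(records,
                                    percentile = config$quadrant_percentile)
  quadrants <- bound_quadrant_table(level_table, records, thresholds)

  members <- attr(level_table, "members")
  window_rg <- NULL
  if (config$sliding_window <= length(seq$residues)) {
    prof <- window_rg_profiles(ens, config$sliding_window)
    window_rg <- do.call(rbind, lapply(names(members), function(nm) {
      mem <- members[[nm]]
      if (!any(mem)) return(NULL)
      data.frame(level = as.integer(nm), start = prof$start,
                 mean_rg = colMeans(prof$rg[mem, , drop = FALSE]),
                 sd_rg = apply(prof$rg[mem, , drop = FALSE], 2, stats::sd))
    }))
  }

  say("stage coaccess")
  pair_stats <- coaccessibility_analysis(singles, pairs,
                                         N = config$n_conformers,
                                         alpha = config$alpha)

  report <- structure(list(
    config = config, config_hash = config_hash(config),
    sequence_params = seq_params, motifs = hits, linkers = linker_set,
    levels = levels, quadrants = quadrants, pair_stats = pair_stats,
    window_rg = window_rg,
    counts = list(n_conformers = config$n_conformers,
                  n_motifs = length(hits$starts),
                  docking_attempts = config$n_conformers *
                    length(hits$starts),
                  pair_attempts = nrow(pairs),
                  build_restarts = ens$failures),
    singles = singles, pairs = pairs, dimension = records,
    ensemble = ens),
    class = "idr_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# per-conformer sliding-window R_G matrix for an ensemble
#' @noRd
window_rg_profiles <- function(ensemble, window) {
  at <- ensemble$atom_table
  nres <- length(ensemble$seq$residues)
  starts <- seq_len(nres - window + 1L)
  rows <- lapply(starts, function(s) {
    which(at$res_index >= s & at$res_index < s + window)
  })
  n <- ensemble$n_conformers
  rg <- matrix(NA_real_, n, length(starts))
  for (i in seq_len(n)) {
    xyz <- ensemble$coords[, , i]
    rg[i, ] <- vapply(rows, function(rr) {
      radius_of_gyration(xyz[rr, , drop = FALSE])
    }, numeric(1))
  }
  list(start = starts, rg = rg)
}

#' @export
print.idr_report <- function(x, ...) {
  cat(sprintf("<idr_report> %s (%s)\n", x$config$motif, x$config_hash))
  cat(sprintf("  %d conformers, %d motifs, %d docking attempts\n",
              x$counts$n_conformers, x$counts$n_motifs,
              x$counts$docking_attempts))
  cat(sprintf("  levels populated to n = %d; co-accessible pairs: %d\n",
              max(x$levels$n[x$levels$total_conformers > 0]),
              sum(x$pair_stats$co_accessible)))
  invisible(x)
}

#' Write the report tables of a run
#'
#' @param report `idr_report` from [run_pipeline].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) {
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(report$sequence_params, "sequence_params.tsv")
  wt(report$levels, "bound_levels.tsv")
  wt(report$quadrants, "quadrants.tsv")
  wt(as.data.frame(report$pair_stats), "pair_stats.tsv")
  if (!is.null(report$window_rg)) wt(report$window_rg, "window_rg.tsv")
  write_pair_matrices(report$pair_stats, file.path(dir, "matrices"))
  summary <- list(config_hash = report$config_hash,
                  master_seed = report$config$master_seed,
                  counts = report$counts,
                  co_accessible_pairs = sum(report$pair_stats$co_accessible),
                  max_simultaneous =
                    max(report$levels$n[report$levels$total_conformers > 0]))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Compare two run reports
#'
#' Side-by-side contrasts of two completed runs: per-level conformer
#' shrink factors (level n total / level n-1 total), dimension trends
#' against n, and co-accessible pair counts.
#'
#' @param report_a,report_b `idr_report` objects.
#' @return List with `shrink` (data.frame of per-level survival
#'   fractions), `dimension_trend` (sign of the R_G trend over populated
#'   levels), and `co_accessible` counts; class `idr_comparison`.
#' @export
compare_runs <- function(report_a, report_b) {
  shrink_of <- function(rep) {
    lv <- rep$levels[rep$levels$total_conformers > 0, ]
    data.frame(n = lv$n[-1],
               survival = lv$total_conformers[-1] /
                 lv$total_conformers[-nrow(lv)])
  }
  trend_of <- function(rep) {
    lv <- rep$levels[rep$levels$total_conformers > 0, ]
    if (nrow(lv) < 2) return(0)
    sign(stats::coef(stats::lm(rg_mean ~ n, data = lv))[["n"]])
  }
  structure(list(
    shrink = list(a = shrink_of(report_a), b = shrink_of(report_b)),
    mean_survival = c(a = mean(shrink_of(report_a)$survival),
                      b = mean(shrink_of(report_b)$survival)),
    dimension_trend = c(a = trend_of(report_a), b = trend_of(report_b)),
    co_accessible = c(a = sum(report_a$pair_stats$co_accessible),
                      b = sum(report_b$pair_stats$co_accessible))),
    class = "idr_comparison")
}
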