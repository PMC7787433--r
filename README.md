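# idrocc — ensemble occupancy analysis of intrinsically disordered regions

Multivalent disordered regions such as the C-terminal IDRs of the
endocytic adaptors Epsin and Eps15 carry many copies of a short linear
motif (DPW / DPF) that all bind the same partner domain (the AP2&alpha;
appendage). `idrocc` asks ensemble-scale questions about such regions:

* which conformers of the free ensemble can sterically accommodate a
  bound partner at each motif (*accessibility*),
* how many partners one chain can hold simultaneously (*n*-bound
  sub-ensembles),
* whether bound sub-ensembles are systematically more extended than the
  free ensemble (*binding-induced expansion*), and
* whether accessibility at one motif is statistically coupled to
  accessibility at another (*co-accessibility*).

It is aimed at structural bioinformaticians studying multivalent IDR -
partner systems who need a reproducible, scriptable version of this
analysis at desk scale.

## The model in brief

**Ensembles.** Conformers are grown residue-by-residue in internal
coordinates (idealized backbone, one side-chain bead per residue, trans
peptide), sampling (&phi;, &psi;) from Ramachandran coil-basin mixtures
per residue class, with helix and motif dihedral constraints, and hard
excluded volume enforced during growth (clash = distance < r_i + r_j −
0.4 Å between residues ≥ 2 apart, with resampling / unwinding /
restart). Ensembles are bit-reproducible from a master seed.

**Docking by superposition.** A rigid template (motif backbone + ligand
body) is placed at each motif by least-squares superposition of the motif
backbone (proper rotation only). A motif is *accessible* if the placed
body makes fewer than 100 hard clashes with the conformer (strict `<`;
50/150 as alternates). A motif *pair* is feasible if all three body pairs
(conformer–L1, conformer–L2, L1–L2) pass the same rule.

**Occupancy inference.** Per conformer, accessible motifs and feasible
pairs form a compatibility graph; the conformer can hold *n* ligands at a
motif subset iff the subset is an *n*-clique. Level tables report
conformer totals and per-combination statistics for every *n*.

**Statistics.** Dimensions (R_G over all atoms, CA–CA end-to-end
distance, sliding-window R_G), a pluggable compactness "energy" scorer
with 20th-percentile EED-energy quadrant classification, and per-pair
co-accessibility: upper-tail hypergeometric p-values P(X ≥ k) with
X ~ Hypergeom(N, K, n), BH correction over all motif pairs, mutual
information (bits) and signed partial MI.

The methods vignette (`vignettes/idr-occupancy-methods.Rmd`) documents
every model choice, parameter and limitation.

## Worked example

A 500-conformer run on the packaged Epsin-like synthetic architecture
(240 residues, 8 DPW motifs at the published gap lengths, proline-rich
linkers):

```r
library(idrocc)
seq <- synthetic_idr_sequence("epsin_like")
hits <- find_motifs(seq, "DPW")
hits
#> <idr_motifs> DPW x8 at [26, 36, 48, 61, 74, 91, 109, 129]
linkers(hits, seq)$lengths
#> [1]  7  9 10 10 14 15 17

cfg <- run_config(sequence = seq, motif = "DPW",
                  n_conformers = 500, master_seed = 7)
rep <- run_pipeline(cfg)
round(subset(rep$levels, total_conformers > 0,
             c(n, total_conformers, rg_mean, eed_mean)), 2)
#>   n total_conformers rg_mean eed_mean
#> 1 0              500   47.91   114.47
#> 2 1              500   47.91   114.47
#> 3 2              495   47.97   114.40
#> 4 3              463   48.54   115.96
#> 5 4              363   49.99   120.29
#> 6 5              230   52.26   125.81
#> 7 6              102   55.01   136.24
#> 8 7               29   56.60   142.61
#> 9 8                6   63.36   164.45
sum(rep$pair_stats$co_accessible)
#> [1] 0
```

Reading the level table: row *n* describes the sub-ensemble of conformers
that can hold *n* ligands simultaneously. Totals shrink with *n* (docking
filters the ensemble) while mean R_G and end-to-end distance grow —
binding-induced expansion: only the more extended conformers can host
many bulky partners at once. For this proline-spaced 8-motif
architecture no motif pair is significantly co-accessible (q ≥ 0.05 for
all 28 pairs), the behaviour expected of well-separated motifs on an
excluded-volume chain.

`run_pipeline()` also writes TSV/JSON reports (`out_dir =`), and
`compare_runs()` contrasts two architectures (per-level survival,
dimension trends, co-accessible pair counts).

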