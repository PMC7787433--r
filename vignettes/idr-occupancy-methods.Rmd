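---
title: "Ensemble occupancy analysis of disordered regions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble occupancy analysis of disordered regions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question idrocc addresses

Intrinsically disordered regions (IDRs) of endocytic adaptor proteins such
as Epsin and Eps15 carry many copies of short linear motifs (the
tripeptides DPW and DPF) that bind the same partner, the alpha-appendage
domain of adaptor protein 2 (AP2&alpha;). Because a disordered chain is an
ensemble rather than a structure, the natural questions are ensemble-level
ones: which conformers can sterically accommodate a bound partner at a
given motif, how many partners can one chain hold at once, how does the
bound sub-ensemble differ in its dimensions from the free ensemble
(binding-induced expansion), and is accessibility at one motif
statistically coupled to accessibility at another (co-accessibility)?

`idrocc` implements this analysis end to end: excluded-volume Monte-Carlo
generation of conformer ensembles under dihedral constraints, rigid
docking of a ligand body by superposition at each motif with van der Waals
clash filtering, inference of *n*-bound sub-ensembles from single and
pairwise docking feasibility, dimension and energy statistics per
sub-ensemble, and hypergeometric / mutual-information statistics of motif
pair co-accessibility.

# The conformer model

Chains are built in internal coordinates with idealized backbone geometry
(N&ndash;CA 1.458 &Aring;, CA&ndash;C 1.525 &Aring;, C&ndash;N 1.329
&Aring;, standard bond angles, trans peptide with &omega; fixed at
180&deg;). Each residue contributes the four backbone heavy atoms and, for
all residues except glycine, a single side-chain bead placed along the
CA&rarr;CB direction at the approximate side-chain centroid distance. The
bead radii derive from residue volumes and are scaled to 85% of the
enclosing-sphere value: a single sphere that fully enclosed an articulated
side chain would overstate its collision cross-section, and the shrunken
beads reproduce disordered-ensemble dimensions (below) without giving up
self-avoidance.

Unconstrained residues draw (&phi;, &psi;) from a discrete mixture of
Ramachandran coil basins with gaussian jitter, by residue class:

| class | basins (weight, &phi;, &psi;, sd) |
|---|---|
| general | &beta; (0.10, &minus;140, 135, 20&deg;), PPII (0.20, &minus;75, 145, 20&deg;), &alpha;R (0.60, &minus;65, &minus;40, 12&deg;), &alpha;L (0.10, 55, 45, 10&deg;) |
| glycine | four basins with equal weight and wider jitter, including a mirrored &alpha;L |
| proline | &phi; restricted near &minus;65&deg;; PPII (0.65) and &alpha; (0.35) &psi; basins |
| pre-proline | extended-shifted (&beta; 0.45, PPII 0.45, &alpha;R 0.10) |

Self-avoidance is enforced during growth: an atom pair at least two
residues apart closer than $r_i + r_j - 0.4$ &Aring; is a hard clash, and
a clashing residue is resampled up to 50 times, after which the last 5
residues are unwound; after 100 unwinds the chain restarts (all budgets
configurable). Accepted conformers contain zero hard clashes by
construction, which the test suite re-verifies with an independent
counter.

Constraints are first-class: a helix constraint pins a span to
(&minus;57, &minus;47) with 5&deg; jitter (truncated at 3&sigma;, so the
tolerance is hard), and motif spans are pinned to the dihedrals of the
docking template so that generator and docking stay mutually consistent.
The study configuration constrains an N-terminal span (default residues
1&ndash;18, standing in for the predicted helical region at the start of
both IDRs) and every motif occurrence.

## Calibration of the basin weights

The coil-basin weights are the generator's compaction knobs. They were
fixed once so that (i) homopolymer ensembles follow excluded-volume
scaling $R_G \propto N^{\nu}$ with &nu; between the ideal-chain 0.5 and
the rod 1.0 (measured &approx; 0.57&ndash;0.59 over N = 25&ndash;200),
and (ii) constrained ensembles of the two study architectures land on the
dimension scale reported for these disordered regions (mean $R_G$ of
roughly 43 &Aring; at 240 residues and 54 &Aring; at 333 residues). The
bead model saturates near 47 &Aring; for the 240-residue architecture:
with purely repulsive excluded volume there is no attraction to compact
the chain further, so the calibrated value sits a few percent above the
reference rather than on it. Both study ensembles fall within the
&plusmn;15% band the calibration targets allow, and the acceptance suite
asserts exactly that, at 10,000 conformers per ensemble.

## What the synthetic sequences are

The real study sequences are specific UniProt regions; the package also
ships *synthetic* stand-ins (`synthetic_idr_sequence()`) that reproduce
the published motif architecture: 240 residues with 8 DPW motifs at gaps
7, 9, 10, 10, 14, 15, 17 and proline-rich linkers (27% P, 23% A, 19.5% G)
for the Epsin-like architecture; 333 residues with 15 DPF motifs,
serine-led linkers (16% S) and the reported human gap lengths for the
Eps15-like architecture. The published Eps15 list names 12 gaps where 15
motifs imply 14; the constructor adds two short gaps (2 and 3, the mode of
the short cluster) and documents the discrepancy rather than forcing
agreement. Linker and flank compositions are realized exactly
(largest-remainder allocation) and shuffled reproducibly, with planted
motifs protected from spurious duplicates.

These stand-ins carry the architecture but not the residue order of the
real proteins, so position-sensitive descriptors (kappa, omega) and any
real-sequence conclusion are out of their scope; they exist so the whole
pipeline, including ensemble-scale behavior, is testable offline. Tests
that pass on them demonstrate the machinery and the qualitative
binding-response signatures, not properties of Epsin or Eps15 themselves.

# Docking by superposition

A template complex holds a motif backbone (N, CA, C per motif residue),
the motif dihedrals, and a rigid ligand body. Docking superimposes the
template motif backbone onto the same motif in a conformer with the
optimal proper rotation (SVD-based least squares; reflections are
explicitly excluded, collinear point sets raise an error) and applies the
transform to the ligand body. Feasibility is a clash count: a placement
with fewer than `threshold` (default 100, alternates 50/150) hard clashes
against the whole conformer marks the motif *accessible*. The boundary is
strict (`<`), so a placement with exactly 100 clashes is discarded. Pair
placements additionally require the two ligand bodies not to clash with
each other (the three-pair rule: conformer&ndash;L1, conformer&ndash;L2,
L1&ndash;L2 all below threshold).

The packaged synthetic template stands in for a crystallographic
motif-ligand complex. Its ligand is a ball of 1.7-&Aring; atoms of radius
18 &Aring; (the order of magnitude of a small adaptor appendage domain)
centred 22 &Aring; from the central motif CA along the side-chain-side
normal. The surface is a 256-atom Fibonacci lattice; the interior is
filled with concentric lattice shells 3.4 &Aring; apart. The filling is a
deliberate design choice: with a hollow shell, chain segments that happen
to lie inside the ligand volume are never counted by the clash rule, the
per-motif accessibility stays near 0.9 and the *n*-bound levels barely
deplete, which abolishes the binding-response regime the analysis is
about. A solid body restores physically sensible filtering (per-motif
accessibility around 0.6 under the study configuration). `fill = FALSE`
recovers the bare shell.

Real templates can be supplied as an `idr_template` built from any source
of motif dihedrals and ligand atom coordinates; the docking layer is
agnostic to where they come from.

# Multivalent occupancy inference

Per conformer, accessible motifs are vertices and feasible pairs are
edges of a compatibility graph; a conformer can hold *n* ligands at the
motif subset *S* iff *S* is an *n*-clique. This deliberately reproduces
the pairwise approximation of the underlying method: no three-body
ligand-ligand-ligand check is performed. With at most 15 motifs the
per-conformer graphs are tiny, so the package counts cliques by direct
subset evaluation over pair-feasibility matrices (one matrix product per
level); a brute-force subset scan and an independent graph library serve
as oracles in the tests, not as the implementation.

Level summaries report, per *n*: the number of conformers with at least
one feasible *n*-subset, and the mean/sd of per-combination conformer
counts over **all** C(m, n) combinations, zero-count combinations
included (the alternative, averaging only non-empty combinations, is not
what the level tables here mean; the choice is pinned and documented).
Levels are nested by construction &mdash; every (n+1)-clique contains
n-cliques &mdash; and accessibility is monotone in the clash threshold,
so level totals at thresholds 50/100/150 nest as well; both properties
are asserted in the tests.

# Dimensions, energy, quadrants

$R_G$ is the unweighted RMS distance of all stored atoms (backbone plus
beads) to their centroid; the end-to-end distance is CA(first) to
CA(last) by default (N-to-C configurable). A sliding-window $R_G$
(default 50 residues) profiles local dimensions along the chain.

The energy scorer is a registry: the default `ca_contacts` scores
compactness as minus the number of CA&ndash;CA contacts under 8 &Aring;
between residues at least 3 apart. It is a structural proxy chosen so
that compact conformers score low ("low energy"), preserving the
compact/low-energy pairing that the quadrant analysis needs; it makes no
claim to be a physical force field, and absolute quadrant numbers from
any particular published scorer are therefore outside what this package
reproduces. Quadrant analysis fixes the low/high cut on each axis at the
20th percentile of the *full* (reference) ensemble &mdash; ties resolve by
strict `<` &mdash; and classifies any sub-ensemble against those fixed
cuts, reporting the four fractions in the order (low EED, low E),
(low EED, high E), (high EED, high E), (high EED, low E).

# Co-accessibility statistics

For motifs *i* and *j*: *N* is the ensemble size, *K* and *n* the
single-motif accessible counts, and *k* the number of conformers whose
*pair* docking is feasible under the three-pair rule. The enrichment
p-value is the upper tail P(X &ge; k) of Hypergeometric(N, K, n),
BH-corrected over all C(m, 2) pairs of one protein's motifs; pairs with
q < 0.05 are called co-accessible.

Mutual information is computed in bits from the 2&times;2 table of joint
accessibility states. The both-bound cell of that table uses the state
overlap |A<sub>i</sub> &cap; A<sub>j</sub>| rather than the pair-feasible
*k*: a contingency table over binary states must have non-negative
complements, and *k* can legitimately fall below the overlap when the two
placed bodies collide (observed in practice at closely spaced motifs).
The signed partial MI is defined as sign(p<sub>11</sub> &minus;
p<sub>1&middot;</sub>p<sub>&middot;1</sub>) &times; MI &mdash; positive
when binding at one motif makes the other more likely &mdash; which pins
down sign and magnitude in one number; its absolute value equals MI by
construction. This definition is isolated behind `partial_mi()` so an
alternative formula can replace it in one place.

`simulate_accessibility()` generates binary accessibility masks with
independent motifs or planted pair couplings (with probability &rho; the
state at motif *j* copies motif *i*, preserving the marginal), which is
how the type-I calibration (empirical P(p &lt; &alpha;) &asymp; &alpha;)
and planted-signal recovery are tested without any conformer generation.

# Determinism and numerical choices

Every stochastic stage flows from one master seed: conformer *i* of an
ensemble uses a seed derived as an affine function of the master seed and
*i* modulo 2<sup>31</sup>&minus;1, so ensembles are bit-reproducible and
any single conformer can be rebuilt in isolation. Constraint jitter is a
gaussian truncated at 3&sigma; (hard tolerance; exact at jitter 0). Clash
counting uses a hash grid whose cell size is at least the largest query
distance, making the 27-neighbourhood exact, and is verified against an
O(n&sup2;) scan. The kappa/omega normalizer &delta;<sub>max</sub> is a
deterministic search over segregated block arrangements that scans every
end-split of one charge species and every three-way split of the neutral
block; on exhaustive small-length batteries this family attains the true
maximum, which the naive single-neutral-block construction does not.
Kappa is undefined (NA, not 0) at zero FCR; histidine counts neutral;
hydropathy is reported on the shifted 0&ndash;9 Kyte&ndash;Doolittle
scale.

# Problem sizes

The package defaults to desk scale: pipelines run at 10,000 conformers by
default (`n_conformers` simply scales up for cluster use). The acceptance
checks use 10,000-conformer ensembles for dimension calibration, a
10,000 &times; 8 docking run for the binding-response signatures,
300-conformer homopolymer ensembles at four lengths for the scaling
exponent, and 1,000 mask simulations of 2,000 conformers for the
statistical calibration. The acceptance script runs the two full
pipelines at 4,000 conformers. Binding-response signatures (monotone
dimension increase, compact-quadrant depletion) are asserted over levels
holding at least 300 conformers, below which level means are too noisy to
order meaningfully.

# Known limitations

* Purely repulsive model: no attractions, no solvent, no electrostatics;
  dimensions saturate at the excluded-volume floor and compact sub-states
  of real sequences are under-represented.
* Side chains are single beads: motif side-chain packing against the
  ligand is not modelled, and clash counts are coarser than all-atom
  counts; thresholds are calibrated within the model, not transferable to
  all-atom structures.
* Rigid docking only: no induced fit, one binding orientation per
  template.
* The pairwise clique rule inherits the method's approximation; a
  three-ligand steric conflict that escapes all three pair checks would
  be missed.
* The synthetic sequences reproduce architecture, not identity; claims
  about the real Epsin/Eps15 sequences require the real UniProt records
  as input.
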