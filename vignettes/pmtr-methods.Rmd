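---
title: "Methods: screening, numbering and docking-ensemble statistics for plant melatonin receptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, numbering and docking-ensemble statistics for plant melatonin receptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmtrkit)
```

pmtrkit implements a comparative analysis workflow for putative plant
melatonin receptors (PMTRs), a family of seven-transmembrane (7TM) proteins
related to the CAND2/TPRA1 group. This vignette explains each method, its
assumptions, the tunable parameters that matter, how the synthetic-data
generators are calibrated, and what the package deliberately does not do.

## The screening cascade

Candidate PMTR homologs arrive as hit tables from a profile-HMM search
against plant proteomes. The package models the curation that follows as a
fixed, fully accounted cascade:

1. **Threshold filter** — retain hits with E-value at most
   `phase2_max_evalue` (default `1e-20`) and length within
   `[min_length, max_length]` (default 200–400 residues). All bounds are
   inclusive; the discovery phase of the same screen uses the stricter
   `phase1_max_evalue = 1e-100` together with `best_hit_per_species()`.
2. **Partial-sequence removal** — a candidate whose sequence does not start
   with methionine is a truncated gene model and is dropped.
3. **7TM consensus** — at least `min_predictor_agreement = 2` topology
   predictors must each report exactly `required_tm = 7` transmembrane
   segments. Only the TM *count* is compared across programs; boundary
   coordinates are never merged.
4. **Deduplication** — one representative per identical amino-acid sequence,
   keeping the lowest E-value (ties: lexicographically smallest id).

The stage order matters for the accounting: a record excluded by an early
stage is never re-examined by a later one, so the four exclusion counts plus
the final count always telescope back to the input count. "Redundant" is
defined as exact sequence identity — no similarity cutoff is assumed because
none would be reproducible without specifying an aligner and threshold. The
retained *set* is invariant under input permutation; with tied E-values only
the identity of a duplicate-group representative can differ, and the id
tie-break removes even that.

## Topology annotations and domain statistics

An annotation is an ordered, gap-free tiling of the sequence into NTD,
TM1–TM7, ICL1–3, ECL1–3 and CTD segments with 1-based inclusive
coordinates. `segments_from_states()` normalizes per-residue predictor
output (inside/outside/membrane) into this form and raises a data error if
the two loops flanking a TM lie on the same membrane side, since the
alternating in/out pattern is what defines a sane 7TM topology. Following
the GPCR convention the NTD is extracellular, so the loop after TM1 is
intracellular.

`consensus_topology()` accepts a protein when the TM-count quorum holds and
returns the segment boundaries of a designated primary predictor (default:
the first listed; if that predictor itself misses the required count, the
first one reporting it). Averaging boundaries across predictors was
deliberately avoided: predictors disagree by a few residues at helix ends,
and a synthetic "mean topology" would belong to no predictor at all.

Domain-length comparisons between groups (e.g. phylogenetic clades) use
pairwise two-sided Mann–Whitney tests with Holm correction
(`compare_domain_lengths`, `alpha = 0.05`). Loop lengths are small discrete
counts, often tied and skewed, so a rank test is the defensible default; the
test suite verifies by simulation (1000 null replicates, n = 20 per group)
that the realized type-I error stays at or below the nominal level.
Observations are pooled per sequence, not paired per species — species
carry different copy numbers, so no natural pairing exists.

## Generic residue numbering

To talk about "the same residue" across receptors from different species,
the package adapts the Ballesteros–Weinstein scheme used for animal GPCRs.
For each TM helix the most conserved alignment column is the *reference
residue* and receives index 50; a residue at position $p$ in helix $k$ with
reference position $r_k$ is labelled $k.(50 + p - r_k)$, rendered like
`3.50` and written in full as `E122^3.50`. Numbers increase toward the C
terminus, and within one helix index differences equal position
differences. Only TM residues are numbered, although labels a few positions
beyond strict helix bounds remain meaningful because the arithmetic depends
only on the reference.

`pick_reference_residues()` chooses the reference per TM as the
maximal-conservation column among those where the reference sequence is not
gapped and column coverage is at least 0.5 (a sparse column can look
perfectly conserved over three sequences and still be meaningless for a
family of hundreds; the 0.5 floor keeps such columns out). Conservation is
the modal non-gap residue fraction with gaps excluded from the denominator;
ties resolve to the smallest reference position. When an external
per-column conservation score is supplied (e.g. from an evolutionary-rate
server), the internal pick is cross-checked against the external top-3
ranks of its helix and kept with a warning if the two disagree — a
consensus rule that prefers agreement but never silently switches rankings.

The default AtPMTR1 scheme (`atpmtr1_scheme()`) anchors TM1–TM5 and TM7 at
positions 55, 88, 122, 155, 183 and 263. TM6 carries no default reference:
it is the least conserved helix of the family, without fully conserved
residues, so its reference must be computed from an alignment and is
flagged low-confidence in the scheme's provenance notes.

## Motif grammar and conservation

Patterns are contiguous strings of literals, `x` (any residue), `h`
(hydrophobic class) and bracketed residue sets. The hydrophobic class
defaults to {A, V, L, I, M, F, W, C}: it covers the observed instances of
the family's `h` positions (the V/I of LE[VI]S, the leucines of Y[LP]PhhY)
while excluding residues the family motifs always spell out explicitly
(Y, P, G); it is a parameter of `compile_pattern()` for users who prefer a
different convention. Matching is exact-position with overlaps allowed and
no internal gaps — every conserved PMTR motif is ungapped, so a gapped
matcher would only add failure modes. `prevalence()` counts sequences with
at least one match and names the non-matching ones, which is the unit the
family analyses use (a motif "present in 173 of 174 sequences" is a
statement about sequences, not matches).

## Docking-ensemble statistics

Docking engines explore poses heuristically, so a single run's best score
is noisy. The package's probabilistic treatment assumes many independent
runs per receptor and works on the per-run best pose (lowest affinity,
ties to the lowest model rank):

* **Ligand centers.** The center of each pose is the unweighted mean of its
  atom coordinates — the convention of averaging ligand coordinates
  directly; a mass-weighted variant is available via the `weights` argument
  of `ligand_center()`.
* **Site clustering.** Centers are clustered with DBSCAN at `eps = 7` Å and
  `min_pts = 20`. These defaults suit ensembles of several hundred to a
  thousand runs over receptor-scale geometry (binding sites tens of Å
  apart, per-site scatter of a few Å); `optimize_clustering()` exposes a
  silhouette-guided grid search for other regimes. The implementation is
  deterministic: clusters are numbered by their smallest member index and a
  border point joins the cluster of its lowest-index core neighbor. The
  test suite proves label equality against an independent brute-force
  DBSCAN on randomized point sets up to 200 points.
* **Per-site statistics.** Each cluster gets its member count, centroid,
  mean affinity and a two-sided Student-t confidence interval (default
  95%). The t interval was chosen over a bootstrap because per-site
  affinities are unimodal with n in the hundreds, where both coincide; a
  zero-variance cluster degenerates cleanly to a point interval and a
  singleton cluster reports an undefined interval. Sites are renamed in
  ascending mean-affinity order, so **site 1 is always the
  strongest-binding site** — matching the convention that the internal
  pocket, which binds more strongly, is site 1.
* **Ligand efficiency and classes.** LE = −ΔG/HA, with HA = 17 for
  melatonin (C13H16N2O2: 13 C + 2 N + 2 O). Affinity classes cut the line
  at −7 and −6 kcal·mol⁻¹ (strong/intermediate/weak, boundaries included
  downward).
* **Site comparison.** `compare_sites()` draws n = 5 values per site
  without replacement under a caller-supplied seed and applies a two-sided
  two-sample t test (Welch by default, since nothing guarantees equal
  variances between a narrow internal site and a skewed superficial one;
  `var_equal = TRUE` restores the textbook pooled test). Letters differ iff
  p < 0.05. How the original small samples were drawn from the simulations
  is not specified anywhere, so seeded random sampling is implemented as
  the only reproducible reading.

## Tunnels and transport

A tunnel profile samples the maximal sphere radius along the tunnel axis; a
transport profile samples the ligand's binding energy along the same path
from the surface to the site. Summaries are deliberately plain: length is
the last arc length, the bottleneck is the minimum radius, and Emax is the
energy maximum (the least favorable point of the journey).

The relevance rule mirrors how tunnel candidates are triaged: a tunnel is
biologically relevant iff the bottleneck is at least the ligand's minimum
cross-section radius *and* Emax is negative. The melatonin cross-section
default is 1.4 Å — strictly below the narrowest bottleneck accepted for
melatonin passage (1.5 Å) — and no maximum-length criterion is imposed by
default; both are parameters of `ligand_geometry()`.

`throughput()` reports a (0, 1] permissiveness score,
$\exp(-k \int ds / r(s)^2)$ with the integral evaluated by trapezoidal
quadrature. The external tunnel tools report a throughput number without
publishing their formula, so this is the package's own definition, built to
satisfy the properties such a score must have: it increases when any radius
increases, decreases with length at fixed radius, and reduces to
$\exp(-kL/r^2)$ for a constant radius. The default scale $k = 0.1\,$Å keeps
typical single-ligand tunnels (lengths 5–15 Å, radii 1–3 Å) away from the
saturated ends of the interval. Because the formula is a package
definition, throughput values are compared only against the package's own
closed form in tests, never against external tools.

## Synthetic data: what it emulates, and what it does not

All generators derive every draw from a single integer seed and restore the
caller's RNG state, so identical specs give byte-identical artifacts.

* `gen_family()` builds a family template (per-domain consensus residues,
  planted motifs realized once) and emits per-species copies with sampled
  domain lengths and uniform residue substitutions. Copy numbers follow the
  family's observed mix (34.5% single-copy species, 47.1% two copies,
  18.4% more than two, the latter uniform over 3–6 — six being the largest
  observed count). Loop lengths are sampled symmetrically around their
  medians (ECL3 median 8 within 6–12, ECL2 median 16, the longest loop) so
  that large-sample empirical medians recover the calibration exactly.
  Amino acids at non-planted positions are uniform over the 20 residues: no
  composition model is claimed, and every test that depends on sequence
  content uses planted structure only.
* `gen_cascade_fixture()` emits hit tables whose exclusion categories are
  exact by construction, each violating only its own rule. Hit E-values are
  log-uniform placeholders: the generator guarantees category membership,
  not realistic E-value shapes.
* `gen_pose_ensemble()` draws per-run best poses around well-separated site
  centers. Symmetric sites are Gaussian; skewed sites use a gamma draw
  standardized to the requested mean and spread, reproducing the
  right-skewed tail toward higher (less favorable) energies that
  superficial pockets show. Poses carry 17 heavy atoms with melatonin's
  element composition, and the atom-coordinate mean equals the drawn center
  exactly.
* `gen_tunnel()` produces a V-shaped radius profile whose minimum equals
  the spec bottleneck exactly (jitter is upward-only and skips the
  bottleneck sample) and an energy profile whose maximum and site-end value
  are exact for the same reason.

None of this is a substitute for real data: there is no phylogeny behind
the sequences, no 3D geometry behind the poses and no force field behind
the energies. A passing suite therefore demonstrates that the *computations*
are correct and deterministic — that the cascade accounts, the clustering
separates what is separable, the intervals cover — not that any biological
conclusion transfers to a particular proteome or structure model.

## Numerical choices and problem sizes

Boundary conventions are inclusive throughout (E-value cutoffs, length
windows, affinity class edges, conservation thresholds). Degenerate inputs
are first-class: empty cascades report `NA` retention, constant affinity
vectors give point intervals, identical small samples in `compare_sites()`
give p = 1 rather than an error, and profiles that violate their invariants
(non-increasing arc lengths, non-positive radii) raise typed errors
(`pmtr_config_error`, `pmtr_data_error`, `pmtr_parse_error`) that the CLI
maps to distinct exit codes.

The test suite sizes its simulations to keep the whole run near half a
minute while leaving comfortable statistical margins: 1000-replicate null
simulations for the rank test and the site comparison, 2000 replicates for
interval coverage, 1000-run pose ensembles over 20 seeds for end-to-end
parameter recovery, and oracle cross-checks (brute-force DBSCAN, exhaustive
regex motif matching, textbook t intervals) on randomized instances up to
200 points or 150 residues.

## Known limitations

* The package consumes predictor and engine *outputs*; it does not run
  HMMER, topology predictors, docking, alanine scanning or tunnel
  detection, and it does not build alignments or trees.
* Redundancy is exact-sequence identity; near-identical isoforms survive
  deduplication.
* The numbering scheme assumes helices map one-to-one across the family;
  receptors with fused or broken helices need manual curation.
* Motif matching is ungapped by design.
* Throughput is a package-defined score, comparable within pmtrkit runs
  but not directly against external tunnel software.
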