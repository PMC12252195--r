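# pmtrkit

Analysis toolkit for putative plant melatonin receptors (PMTRs) — the
CAND2/TPRA1-like family of seven-transmembrane (7TM) proteins proposed to
bind melatonin in plants. The package is aimed at structural
bioinformaticians who want a reproducible, fully testable version of the
comparative PMTR workflow: homolog screening, topology and residue
numbering, motif conservation, docking-ensemble statistics and tunnel
analysis, with every external engine (HMMER, topology predictors, AutoDock
Vina, tunnel tools) replaced by seeded synthetic generators with known
ground truth.

## What it computes

* **Screening cascade** (`run_cascade`): staged candidate filtering with
  full exclusion accounting — an E-value/length window (E ≤ 1e-20, 200–400
  residues), removal of partial sequences (no initial methionine), a 7TM
  consensus requiring ≥ 2 topology predictors to report exactly 7
  transmembrane segments, and exact-sequence deduplication. Every input id
  lands in exactly one report bucket.
* **Topology** (`segments_from_states`, `consensus_topology`,
  `domain_length_table`, `compare_domain_lengths`): consensus 7TM
  annotations (NTD/TM1–7/ICL1–3/ECL1–3/CTD, 1-based inclusive) and
  rank-based group comparisons of domain lengths (pairwise Mann–Whitney with
  Holm correction).
* **Generic residue numbering** (`atpmtr1_scheme`, `generic_label`,
  `assign_generic_numbers`, `map_position`): a Ballesteros–Weinstein-style
  scheme for PMTRs. The most conserved residue of each TM helix is the
  reference and gets index 50; a residue at position *p* in helix *k* with
  reference *r* is numbered *k*.(50 + *p* − *r*), e.g. E122^3.50 and Y250^7.37
  on AtPMTR1. `map_position` carries numbers across species through an
  alignment.
* **Motifs** (`compile_pattern`, `scan_motif`, `prevalence`): a small motif
  grammar (literals, `x` wildcard, `h` hydrophobic class, `[KR]` sets)
  covering the conserved family motifs YYSEM[KR]D, DFFxE[ED], QxWEC,
  LPx[RK], CHG, LEhS and Y[LP]PhhY, plus alignment conservation scanning.
* **Docking-ensemble statistics** (`analyze_docking_sites`): best pose per
  docking run, ligand centers, DBSCAN site clustering (eps = 7 Å,
  minPts = 20, silhouette-guided grid search available), per-site mean
  binding affinity with 95% Student-t confidence intervals, ligand
  efficiency LE = −ΔG/HA (melatonin: HA = 17 heavy atoms), affinity classes
  (strong ≤ −7 < intermediate ≤ −6 < weak, kcal·mol⁻¹) and a seeded n = 5
  two-sample t comparison between sites.
* **Tunnels** (`tunnel_length`, `bottleneck`, `throughput`, `is_relevant`):
  tunnel radius/energy profile summaries and the biological-relevance rule —
  the bottleneck must accommodate the ligand and the highest energy along
  the transport trajectory (Emax) must be negative.
* **Synthetic data** (`gen_family`, `gen_cascade_fixture`,
  `gen_pose_ensemble`, `gen_tunnel`): seeded generators for every input
  above, calibrated to the family's published statistics (e.g. ECL3 length
  median 8, range 6–12; ECL2 median 16; two-site pose ensembles with a
  narrow bell-shaped strong site and a right-skewed superficial site).

## Worked example

```r
library(pmtrkit)

# a 253-candidate screen with known exclusion categories
fx <- gen_cascade_fixture(cascade_fixture_spec(253, 47, 1, 13, 18, seed = 1))
res <- run_cascade(fx$hits, fx$predictions)
res$report
#> PMTR screening cascade report
#>   initial candidates : 253
#>   after threshold    : 206  (excluded 47)
#>   partial removed    : 1
#>   failed 7TM filter  : 13
#>   redundant removed  : 18
#>   final homologs     : 174  (~69% of initial)

# a 1000-run two-site docking ensemble, clustered and summarized
pe <- gen_pose_ensemble(list(
  pose_site_spec(c(0, 0, 0),  2, -7.32, 0.4, FALSE, 500),
  pose_site_spec(c(40, 0, 0), 2, -6.20, 0.5, TRUE,  500)), seed = 1)
dock <- analyze_docking_sites(pe$poses, eps = 7, min_pts = 20)
dock$sites[, c("site", "n", "mean_affinity", "ci_lo", "ci_hi",
               "ligand_efficiency", "affinity_class")]
#>   site   n mean_affinity  ci_lo  ci_hi ligand_efficiency affinity_class
#> 1    1 500        -7.311 -7.347 -7.275            0.4301         strong
#> 2    2 500        -6.219 -6.263 -6.176            0.3658   intermediate

generic_label(250, 7, atpmtr1_scheme())   # "7.37"  (Y250^7.37 on AtPMTR1)

tn <- gen_tunnel(tunnel_spec(length = 8.2, bottleneck = 1.5, seed = 1))
bottleneck(tn$tunnel)                         # 1.5
is_relevant(tn$tunnel, tn$transport)$relevant # TRUE
```

The cascade report reads: of 253 candidates, 206 survive the E-value/length
window, one partial sequence and 13 candidates without a 7TM consensus are
dropped, 18 redundant entries collapse onto their representatives, and 174
homologs remain (~69% retention). The docking table recovers the two planted
sites: the internal site (site 1) binds more strongly (mean −7.31 kcal·mol⁻¹,
LE 0.43) than the superficial one (−6.22, LE 0.37).

A thin CLI over the same pipeline lives at `inst/scripts/pmtr-run.R`
(`Rscript pmtr-run.R --config config.yaml --out report.json`).

## Documentation

The methods vignette (`vignettes/pmtr-methods.Rmd`) describes the models,
default parameters, synthetic-data calibration and known limitations.
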