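Package: pmtrkit
Title: Screening, Numbering and Docking-Ensemble Statistics for Plant Melatonin Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for the comparative analysis of putative plant
    melatonin receptors (PMTRs), a family of seven-transmembrane (7TM) proteins.
    Provides a staged homolog-screening cascade with full exclusion accounting,
    consensus 7TM topology annotation and domain-length statistics, a
    Ballesteros-Weinstein-style generic residue numbering scheme adapted to
    PMTRs, sequence motif compilation and conservation scanning, probabilistic
    docking-ensemble site statistics (best-pose extraction, DBSCAN site
    clustering, confidence intervals, ligand efficiency), and tunnel
    bottleneck/transport relevance analysis. Every external engine and dataset
    is emulated by seeded synthetic-data generators with known ground truth, so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    pracma,
    jsonlite,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
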