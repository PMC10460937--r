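Package: danai
Title: Atomic Interaction Topology Analysis of Molecular Dynamics Trajectories
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds per-frame intermolecular contact graphs over chemically
    tagged carbon centers of molecular dynamics trajectories, counts
    topologically classified micro-interaction motifs (isolated pairs, chains,
    rings, junctions) expressed in the DANAI interaction notation, and
    summarizes the per-frame counts as time series, averages and a mode-mode
    Pearson correlation matrix.  Reads DL_POLY HISTORY and multi-frame XYZ
    trajectories under periodic boundary conditions, ships a synthetic
    configuration generator for fluoroalkane-like two-center dimer liquids and
    planted-motif fixtures, and an independent brute-force motif census used
    as a testing oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
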