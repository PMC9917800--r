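Package: tcrclone
Title: TCR Repertoire Clonotyping and V(D)J Amplicon Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for T-cell receptor (TCR) repertoire analysis from
    merged amplicon reads: local-alignment assignment of V and J gene
    segments against an IMGT-style reference, extraction and translation
    of the CDR3 junction between the conserved Cys104 and Phe118 anchors
    (with the following Gly119 as a frame check), aggregation of reads
    into clonotypes with copy counts, ranks and percentage frequencies,
    V-J gene-usage matrices, cross-sample shared-clonotype tables with
    "N.D." markers, and annotation of invariant T-cell (iNKT, MAIT)
    clonotypes.  A seeded V(D)J recombination simulator generates
    ground-truthed repertoires and reads with junctional diversity, a
    skewed clone-abundance spectrum and substitution sequencing error,
    including spike-ins of user-specified clonotypes, so the whole
    pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    dplyr,
    graphics,
    grDevices,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
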