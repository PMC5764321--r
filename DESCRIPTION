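Package: ctlscan
Title: Classification of CTL-Family RING-H2 E3 Ubiquitin Ligases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects RING-H2 zinc-finger domains by a spacing grammar over the
    eight metal-ligand residues with lineage-specific spacing profiles, scans
    proteins for the degenerate 21-residue YEELL motif and other user-supplied
    motifs with a mismatch budget, and combines domain diagnostics with motif
    co-occurrence to call members of the ATL, BTL and CTL families of E3
    ubiquitin ligases. Also builds ligand-anchored alignments of RING-H2
    domains, Neighbor-Joining trees with bootstrap support, assigns plant CTLs
    to reference-anchored groups, summarises CDS and 5'UTR intron architecture
    from GFF3 gene models, and ships a seeded synthetic-data generator with
    known labels so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    purrr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    phangorn,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
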