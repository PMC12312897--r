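Package: fawtype
Title: Strain Typing of Fall Armyworm from COI and Tpi Marker Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Diagnostic-SNP strain typing for fall armyworm (Spodoptera
    frugiperda) from directly sequenced mitochondrial COIB and Z-linked
    Tpi amplicons. Provides haplotype calling on the mCOI1164D/mCOI1287R
    and gTpi183Y diagnostic sites, detection of interstrain hybrid males
    from IUPAC ambiguity codes, catalog-constrained deconvolution of
    heterozygous Tpi alleles, TpiI4a200 intron haplotype cataloguing with
    singleton re-verification, neighbor-joining phylogenetic strain
    assignment with bootstrap support and midpoint rooting, and
    collection-level population profiling (haplotype frequency profiles,
    R-chromosome carrier statistics, Pearson profile comparison, Fisher
    exact introduction-signal flagging). A seeded synthetic cohort
    generator emulating Z-linked strain inheritance serves as a test
    oracle for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    ape,
    phangorn,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
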