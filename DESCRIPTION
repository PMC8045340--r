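Package: negeseek
Title: Characterization of Nege-Like Virus Genomes and Their Small-RNA Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Annotates positive-sense nege/kita-like viral genomes (major open
    reading frames, untranslated regions, inter-ORF overlaps), locates the
    RNA-dependent RNA polymerase catalytic motifs A, B and C and classifies
    their architecture as canonical (A-B-C) or permuted (C-A-B), computes
    pairwise amino-acid and nucleotide percent-identity matrices with
    neighbor-joining clustering, predicts transmembrane segments of the SP24
    virion membrane protein by Kyte-Doolittle hydropathy scanning, and
    profiles virus-derived small interfering RNAs (size distribution, strand
    polarity, 5'-terminal nucleotide preference, genome coverage) from
    small-RNA reads mapped with zero mismatches. Includes a synthetic-data
    generator producing genomes with planted ORFs, motifs and transmembrane
    islands, plus small-RNA libraries with configurable length, strand and
    5'-nucleotide structure, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    stringi,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    BiocGenerics
Config/testthat/edition: 3
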