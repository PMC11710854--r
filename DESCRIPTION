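Package: SexChromTools
Title: Sex Chromosome Identification, Assembly Auditing, and Evolutionary
    Strata Dating from Depth, Hi-C, and Alignment Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing sex chromosomes in genome assemblies without
    chromosome-level phasing: classification of scaffolds as X- or Y-linked
    from normalized female/male sequencing-depth ratios, delineation of
    pseudoautosomal regions (PARs), assignment of unplaced scaffolds to
    chromosomes or chromosome pairs from Hi-C interaction strengths with
    one-sided rank tests, auditing of assembly gap closure by flank
    re-mapping, detection of ampliconic regions from three evidence channels
    (palindromes, self-alignment arrays, and GC-corrected depth excess),
    estimation of X/Y divergence in windows with Jukes-Cantor correction and
    bootstrap confidence intervals, dating of evolutionary strata under a
    male-mutation-bias rate model, and the tau tissue-specificity index.
    Includes a synthetic-data generator that plants known sex-linked
    scaffolds, PARs, palindromes, arrays, collapsed amplicons, assembly gaps,
    strata divergences, and tissue-specific genes so that every stage can be
    scored against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
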