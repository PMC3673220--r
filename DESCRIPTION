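Package: riboSD
Title: Internal Shine-Dalgarno Sites and Ribosome Footprint Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of internal Shine-Dalgarno (SD) sequences in bacterial
    ribosome profiling data. Detects SD sites in coding sequences by
    nearest-neighbor RNA:RNA duplex free energy against the anti-SD tail of
    16S rRNA, classifies ribosome-protected fragments as SD-containing or
    SD-free, computes per-SD/per-gene normalized footprint length
    distributions and metagene 5'/3' end-density profiles around SD sites,
    and quantifies SD read enrichment and hexamer strength/length/density
    correlations. Includes a stochastic footprint simulator that contrasts a
    single-codon pausing model with an asymmetric multi-codon ("caterpillar")
    model of SD-tethered elongation, and a synthetic fixture generator that
    plants SD sites of known strength into random ORFs for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
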