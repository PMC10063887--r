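Package: racesig
Title: K-mer Signatures, Presence-Absence Variation and Selection Scans
    for Crop Race Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing crop subpopulations ("races") from whole
    genome sequence: canonical k-mer counting, MinHash sketch (Mash)
    distances, N-way k-mer sharing and group-specific k-mer extraction;
    gene presence-absence variation (PAV) calling from k-mer coverage of
    an annotated reference; VCF filtering and descriptive variant
    statistics with a minimal codon-level effect annotator; nucleotide
    diversity, Watterson's theta, Tajima's D, Weir-Cockerham Fst, LD
    decay and a composite Tajima's-D-by-Fst selection classifier;
    haplotype-based selection scans (EHH, iHH, iHS, XP-EHH) with FDR
    control and sweep-region construction; interval algebra for
    sweep-by-QTL overlap; and distance-based relatedness (neighbor
    joining with bootstrap, principal coordinates). A synthetic-data
    module simulates structured populations under the Balding-Nichols
    model with hard sweeps, gene deletions and sequencing reads, so the
    whole pipeline can be exercised and calibrated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
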