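Package: trihelixr
Title: Genome-Wide Characterization of Trihelix (Myb/SANT-LIKE) Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the computational pipeline used in
    genome-wide gene-family characterization studies of plant trihelix
    (GT-factor / Myb/SANT-LIKE) transcription factors: two-pass profile-based
    domain identification with Gumbel E-value calibration, a per-gene catalog
    (protein length, molecular weight, isoelectric point, chromosomal
    distribution), tandem and segmental duplication detection with
    MCScanX-style collinearity chaining, Nei-Gojobori Ka/Ks estimation,
    neighbor-joining phylogeny with Poisson-corrected distances and bootstrap
    subfamily classification, IUPAC cis-element promoter scanning with
    shared-element intersection, ZOOPS EM motif discovery, expression binning
    and clustering, and 2^-ddCt qPCR quantification. A synthetic-data
    generator produces every input with known ground truth so each stage is
    verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
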