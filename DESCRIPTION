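Package: genefamr
Title: Gene Family Identification, Phylogeny, Duplication and Synteny Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for genome-wide characterization of plant
    transcription-factor gene families, modelled on the DREB (dehydration
    responsive element-binding) subfamily of AP2/ERF regulators. Identifies
    family members by homology search plus a position-specific scoring matrix
    scan of the AP2 domain with the diagnostic valine-14 / glutamate-19
    conservation filter; computes physicochemical properties (length, molecular
    weight, isoelectric point); builds neighbor-joining phylogenies from
    Poisson-corrected distances with bootstrap supports and assigns A1-A6
    subgroups against a labelled reference panel; summarizes exon/intron
    structure with intron splicing phases; discovers ungapped protein motifs by
    ZOOPS expectation-maximization; detects tandem and segmental (collinear)
    duplications, estimates Ka/Ks by the Nei-Gojobori (1986) method and dates
    duplication events; and counts cross-species syntenic orthologs. A
    deterministic synthetic-genome generator with planted ground truth makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomeInfoDb,
    GenomicRanges,
    ggplot2,
    IRanges,
    Matrix,
    purrr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
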