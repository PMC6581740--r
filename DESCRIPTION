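Package: baitprey
Title: Quantitative AP-MS Interactome Analysis from Fragment-Level DIA Intensities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for scoring affinity-purification mass-spectrometry
    (AP-MS) experiments quantified at the fragment level by data-independent
    acquisition (DIA/SWATH). Implements fragment reliability filtering,
    peptide/protein roll-up with quantile imputation, paired peptide-level
    differential tests aggregated to protein level through the beta
    distribution of the median order statistic, two-step specific/dynamic
    interactor calling with contaminant removal, iBAQ-based interaction
    stoichiometry from in-silico tryptic digestion, and SILAC light/heavy
    origin classification. Ships a fragment-level simulator with known ground
    truth (bait occupancy fractions, recruitment kinetics, contaminant
    background) so every stage can be benchmarked without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    S4Vectors,
    SummarizedExperiment,
    Biostrings
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
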