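Package: rosregulon
Title: Regulon Inference for the Rhizobium RosR Zinc-Finger Regulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for inferring the regulon of the Cys2His2
    zinc-finger transcriptional regulator RosR of Rhizobium leguminosarum
    bv. trifolii from RNA-Seq count data and genome sequence. Implements
    negative-binomial differential expression between a wild-type and a
    regulator-mutant strain with Benjamini-Hochberg FDR control, FPKM
    normalization, COG functional summaries, and strand-aware scanning of
    translation-start-relative promoter windows for matches to the 22-nt
    RosR-box binding consensus using a central-position-excluded identity
    metric and PWM log-odds scoring. Includes phenotype statistics
    (autoaggregation percentage, generation time from log-linear CFU fits)
    and a synthetic-data generator that plants motifs and simulates
    negative-binomial counts so every stage is verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
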