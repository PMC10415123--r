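Package: nptrap
Title: Nascent Transcriptome and Translatome Analysis for 4sU
    Metabolic-Labeling TRAP-Seq
Version: 0.1.0
Authors@R:
    person("nptrap", "developers", email = "nptrap@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for combined SLAM-seq /
    QuantSeq metabolic RNA labeling and translating-ribosome affinity
    purification (TRAP) experiments. Simulates 3'UTR-anchored reads and
    per-gene count tables with T>C conversion chemistry, quantifies
    converted reads into SLAM-DUNK-style tcount tables, decomposes total
    signal into nascent and pre-existing RNA with a detection-sensitivity
    correction, and provides negative-binomial differential expression,
    deltaTE regulatory classification, and gene-category shift statistics
    with hypergeometric over-representation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
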