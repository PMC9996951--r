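Package: methtf
Title: Differential DNA Methylation and Transcription Factor Binding-Site
    Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links DNA-methylation remodelling between two cell states to
    transcription-factor (TF) activity. Provides beta-to-M-value
    transformation, empirical-Bayes moderated t-testing of per-CpG
    differential methylation with Benjamini-Hochberg adjustment, enrichment
    of hypo- and hyper-methylated CpGs across CpG-island context and
    chromatin-state segmentations, correlation of methylation with gene
    expression, and the TFR/RRT statistic that ranks TFs by the hypo- versus
    hyper-methylation bias of their ChIP-seq binding sites. Includes a
    synthetic-data generator with planted, recoverable signal for
    end-to-end validation, and a pipeline driver with a thin command-line
    wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
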