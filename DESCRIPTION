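Package: divtx
Title: Divergent Transcription Analysis of Regulatory Elements from CAGE Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotation-unbiased characterization of transcriptional
    regulatory elements from CAGE 5'-end data in control and RNA
    exosome-depleted conditions. Builds CAGE tag clusters with
    summit-fraction trimming and multimodal splitting, estimates genomic
    background noise from TSS-unlikely loci, quantifies divergent
    transcription initiation in strand-specific windows anchored on open
    chromatin sites, scores exosome sensitivity and transcriptional
    directionality, classifies sites into six replicate-consistent
    classes by two-step k-means clustering, scans core-promoter and
    RNA-processing motifs with exact p-values, integrates STARR-seq
    enhancer potential and ChIP marks, and models class co-occurrence
    within topologically associating domains. A synthetic-data generator
    with planted classes makes every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    Biostrings,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
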