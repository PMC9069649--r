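Package: tfclust
Title: Binding-Site Clusters and Co-Binding Statistics for Multi-TF ChIP-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chains ChIP-seq peak summits of multiple transcription factors
    into genomic binding clusters using a gap threshold and span cap,
    characterizes the cluster-size distribution against a uniform
    random-placement Monte-Carlo null, fits power-law and exponential tails
    to size histograms, and quantifies pairwise co-binding through windowed
    co-occurrence counts, Pearson correlation of matrix rows, hierarchical
    ordering and heatmap rendering. Includes readers for simplified BED peak
    files and GFF3/TSV chromosome sizes, a synthetic-data generator with
    planted co-binding hubs for testing, and a one-shot pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
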