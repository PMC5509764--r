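Package: fcmine
Title: Pre/Post Resting-State Functional Brain Network Analysis with
    Graph Metrics and Frequent Subgraph Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds region-wise functional connectivity networks from ROI
    time series, binarizes them across a sparsity threshold space, and
    analyzes them with two complementary arms: conventional nodal network
    metrics (degree, betweenness centrality, nodal efficiency) summarized
    by area under the curve over the threshold space, and gSpan frequent
    connected-subgraph mining with minimum DFS-code canonical labels.
    Includes an inference layer (paired sign-flip permutation tests,
    Benjamini-Hochberg FDR, brain-behavior Pearson correlations with
    r-to-Cohen's-d conversion, Levene and two-way ANOVA helpers), motion
    based subject exclusion, nuisance regression, hub detection, and a
    synthetic pre/post cohort generator for end-to-end validation of the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
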