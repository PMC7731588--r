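Package: orthoflow
Title: Parallel Orthology Prediction from All-vs-All Protein Similarity
    Searches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts ortholog, inparalog and coortholog gene pairs from
    per-genome all-against-all protein similarity search results (12-column
    tabular hits), builds a normalized weighted similarity graph, and cuts it
    into ortholog groups with a built-in deterministic Markov clustering
    implementation. The pipeline is decomposed into independent per-genome
    and per-genome-pair tasks over a sparse file-per-pair layout, so stages
    can run in parallel on a laptop or be arrayed on a batch system. A
    synthetic-data module plants gene families with known ortholog and
    inparalog structure to benchmark recovery end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    Matrix,
    methods,
    parallel,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    igraph,
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
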