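Package: mvgat
Title: Multi-View Graph Attention Networks with a Membrane-Computing Scheduler
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-supervised node classification on multi-view networks: one
    shared node set observed under several edge sets (views), as in
    multi-evidence protein-protein networks or citation-plus-text-similarity
    corpora. Each view is encoded by a multi-head neighborhood attention
    network, per-view node representations are fused by a learned attention
    over views, and the whole computation is organized as a coupled membrane
    (P) system of k+4 cells with explicit evolution and communication rules.
    Includes readers for plain-text edge lists and feature tables, a
    cosine-similarity view builder, a planted-community (stochastic block
    model) generator for multi-view benchmarks, ablation variants, and
    evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
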