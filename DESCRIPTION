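Package: prombench
Title: Benchmarking Toolkit for Supervised Promoter Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building genome-scale benchmark datasets for ab initio
    promoter recognition and for training, evaluating and dissecting sequence
    classifiers on them. Benchmark datasets are constructed by sliding a fixed
    window over a genome and tagging each window as promoter (I) or
    non-promoter (O) by its contiguous overlap with TSS-anchored promoter
    regions. The package implements three published deep-learning architecture
    families (CNN, CNN with element decomposition, CNN-BiLSTM) with a built-in
    neural engine, synthetic negative-sequence generators (uniform substitution
    and composition-preserving shuffles), class-rebalancing samplers,
    imbalance-aware evaluation (Matthews correlation coefficient), JASPAR
    motif-as-filter interpretability models, per-position class-discrimination
    logos, and a seeded synthetic-genome generator with planted promoters so
    the full pipeline runs without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
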