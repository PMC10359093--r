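Package: dnadda
Title: Sequence-Based Prediction of A/B Chromatin Compartments by Delay
    Differential Analysis
Version: 0.1.0
Authors@R:
    person("dnadda", "maintainers", email = "dnadda@example.org",
           role = c("aut", "cre"))
Description: Predicts genome-wide A/B chromatin compartments from the
    nucleotide sequence alone. Genomic bins are encoded as 1D DNA walks
    (hydrogen-bond rule), per-bin and cross-bin delay-differential models
    are fitted by singular value decomposition, and a dynamical-ergodicity
    score over all bin pairs yields a sequence-only contact map.
    Compartments are called from the contact map's Pearson correlation
    matrix by principal component analysis with MAD-based outlier
    handling, ChIP-seq-guided component selection and orientation, and
    A/B scaling. Includes exhaustive delay-pair structure selection
    against a reference compartment track, evaluation metrics (r, AUC,
    ACC, F1), saddle-plot compartment strength, GC-content baselines, and
    a synthetic-fixture generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
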