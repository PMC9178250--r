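Package: bigrn
Title: Bidirectional Recurrent Network Inference of Gene Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers directed gene regulatory networks from time-series or
    pseudotime-ordered single-cell expression data. Pseudotime-ordered cells
    are converted into supervised lagged regression samples and used to train
    a recurrent regression network (a recurrent layer unrolled over the time
    lag followed by a deep stack of gene-width fully connected layers with
    periodic residual connections) under a mean-squared-error plus L1 loss.
    Gene-by-gene weight matrices extracted from the trained network act as
    candidate networks that are combined by voting, optionally weighted by
    their overlap with an incomplete prior edge set; forward-time and
    reverse-time inferences are integrated into a final ranked edge list.
    Includes AUROC/AUPRC benchmarking against reference networks and a
    synthetic data generator that simulates noisy expression dynamics from
    planted sparse networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
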