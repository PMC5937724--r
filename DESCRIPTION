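Package: gbanet
Title: Guilt-by-Association Gene Function Prediction on Differential
    Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts gene functions by neighbor voting on a differential
    co-expression network built from paired tumor/normal expression data.
    Provides k-nearest-neighbour imputation, quantile normalisation and
    probe-to-gene collapse for log2 microarray matrices; paired t-test
    differential expression with Benjamini-Hochberg false discovery rate
    control; an absolute-Spearman weighted co-expression network over the
    differentially expressed genes with a weight-bin summary; Gene
    Ontology style gene-set loading with size and DEG-overlap filters;
    three-fold cross-validated AUROC of neighbor-voting scores per gene
    set, gene multifunctionality scores, and AUC-threshold classification
    of candidate functions. A synthetic-data generator emulating a paired
    microarray design with planted differential expression and latent
    co-expression modules makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
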