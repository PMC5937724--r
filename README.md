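# gbanet

Network-based **guilt-by-association (GBA)** prediction of gene functions
from paired tumour/normal expression data.

The guilt-by-association principle says that genes sharing a network
neighbourhood tend to share function. `gbanet` operationalises it for the
kind of study design used in paired microarray analyses of esophageal
squamous cell carcinoma and similar tumours:

1. **Preprocessing** — k-nearest-neighbour imputation of missing log2
   intensities, quantile normalisation, and probe-to-gene collapse.
2. **Differential expression** — per-gene paired *t*-test on tumour −
   normal log2 differences, Benjamini–Hochberg FDR, and the strict filter
   FDR < 0.001 and |log2 FC| > 2 (an empirical-Bayes moderated *t* is
   available behind a flag).
3. **Differential co-expression network (DCN)** — the complete weighted
   graph over the DEGs with edge weights *w_ij = |ρ_ij|*, the absolute
   Spearman correlation of expression profiles across all samples, plus a
   weight-bin histogram and edge-list export.
4. **Gene-set filtering** — GO-style catalogs (GMT or two-column TSV),
   restricted to *seed* terms with 20–1000 annotated genes and
   *informative* terms covering ≥ 20 DEGs (both thresholds configurable).
5. **Neighbor voting with cross-validated AUROC** — for a term with
   annotated gene set *A*, a candidate gene *i* scores
   *s_i = Σ_{j∈A} w_ij / Σ_{j∉A, j≠i} w_ij*
   (a degree-normalised variant *s_i = Σ_{j∈A} w_ij / Σ_{j≠i} w_ij* is
   equivalent in rank). Three-fold cross-validation over the term's
   network genes yields per-fold AUROCs (midrank Mann–Whitney); terms
   with mean AUC > 0.7 are *good* and > 0.8 are *optimal* gene functions.
6. **Multifunctionality (MF)** — per gene, *MF(g) = Σ_{T∋g}
   1/(|T|·(N−|T|))* over its annotated terms in a universe of *N* genes,
   the bias baseline a single fixed gene ranking achieves across all
   functions.

A first-class synthetic-data generator emulates the paired design —
planted DE genes, patient-level latent co-expression modules, sporadic
missing values, and a catalog with module-seeded and background terms —
so the whole pipeline is testable end to end without any download.

## Worked example

Simulate the default paired study (17 tumour/normal pairs, 500 genes, 50
DE genes carrying three 10-gene co-expression modules, 40 gene sets of
which 8 are planted from modules) and run the full pipeline:

```r
library(gbanet)

cfg <- pipeline_config(simulation = sim_config(seed = 1),
                       min_deg_overlap = 3, seed = 1)
report <- run_pipeline(cfg)
report
#> <pipeline_report>
#>   n_genes: 500
#>   n_samples: 34
#>   n_degs: 50
#>   n_network_nodes: 50
#>   n_edges: 1225
#>   n_catalog_terms: 40
#>   n_seed_terms: 40
#>   n_informative_terms: 29
#>   n_terms_scored: 29
#>   ...
```

All 50 planted DE genes pass FDR < 0.001 and |log2 FC| > 2, the network
is the complete graph on them (50·49/2 = 1225 edges), and 29 of the 40
gene sets have enough DEG overlap to be scored. The fitted object is a
tibble away:

```r
dplyr::select(tidy(report$fit), term, name, mean_auc, mf_auc, label) |> head(3)
#> # A tibble: 3 × 5
#>   term  name                  mean_auc mf_auc label
#> 1 T001  planted from module 1        1  0.84  optimal
#> 2 T002  planted from module 2        1  0.712 optimal
#> 3 T003  planted from module 3        1  0.652 optimal

evaluate_against_truth(report)[c("de_recall", "planted_mean_auc",
                                 "background_mean_auc")]
#> $de_recall            [1] 1
#> $planted_mean_auc     [1] 1
#> $background_mean_auc  [1] 0.5234161
```

Every module-seeded term is recovered with mean cross-validated AUC 1
(labelled *optimal*), while background terms hover at the chance level
0.5 — exactly the separation neighbor voting is supposed to deliver when
co-expression carries functional signal. `autoplot(report$fit)` draws the
AUC histogram across terms; `plot_weight_distribution(report$histogram)`
and `plot_deg_volcano(report$deg_table)` cover the network and DEG
stages.

A thin command-line wrapper with `simulate`, `run` and `evaluate`
subcommands ships in `inst/scripts/gbanet`.

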