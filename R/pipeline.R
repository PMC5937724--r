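#' Configure a full pipeline run
#'
#' Exactly one of a file-input block (`expression` + `samples` +
#' `gene_sets`, optionally `probe_map`) or a `simulation` block (a
#' [sim_config()]) must be supplied. The thresholds default to the
#' published analysis settings: FDR < 0.001 and |log2 FC| > 2 for DEG
#' calling, term size 20--1000 and >= 20 DEG overlap for the catalog
#' filters, and AUC > 0.7 / > 0.8 for good / optimal calls.
#'
#' @param expression,samples,gene_sets,probe_map input file paths (TSV /
#'   GMT); `probe_map` optional.
#' @param simulation a [sim_config()] for a synthetic run.
#' @param fdr_max,min_abs_logfc DEG thresholds (strict).
#' @param min_set_size,max_set_size inclusive term-size window.
#' @param min_deg_overlap minimum DEG overlap per term (inclusive).
#' @param auc_good,auc_optimal strict AUC thresholds, `auc_good <
#'   auc_optimal`.
#' @param min_weight network edge threshold (0 = complete graph).
#' @param hist_bins weight-histogram bin edges.
#' @param n_folds,variant cross-validation settings.
#' @param knn_k imputation neighbours.
#' @param moderated use the moderated paired t.
#' @param seed global seed cascading to simulation and fold assignment.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(expression = NULL, samples = NULL,
                            gene_sets = NULL, probe_map = NULL,
                            simulation = NULL, fdr_max = 0.001,
                            min_abs_logfc = 2, min_set_size = 20,
                            max_set_size = 1000, min_deg_overlap = 20,
                            auc_good = 0.7, auc_optimal = 0.8,
                            min_weight = 0, hist_bins = seq(0.4, 1, 0.1),
                            n_folds = 3, variant = "ratio", knn_k = 10,
                            moderated = FALSE, seed = 1L) {
  has_files <- !is.null(expression)
  if (has_files == !is.null(simulation)) {
    abort("supply exactly one of file inputs (expression/samples/gene_sets) or a simulation block",
          class = "gbanet_config_error")
  }
  if (has_files && (is.null(samples) || is.null(gene_sets))) {
    abort("file inputs need expression, samples and gene_sets paths",
          class = "gbanet_config_error")
  }
  if (!is.null(simulation) && !inherits(simulation, "sim_config")) {
    simulation <- do.call(sim_config, simulation)
  }
  stopifnot(fdr_max > 0, min_abs_logfc >= 0, min_set_size <= max_set_size,
            min_deg_overlap >= 0, auc_good < auc_optimal, min_weight >= 0,
            n_folds >= 2, knn_k >= 1)
  structure(list(
    expression = expression, samples = samples, gene_sets = gene_sets,
    probe_map = probe_map, simulation = simulation, fdr_max = fdr_max,
    min_abs_logfc = min_abs_logfc, min_set_size = min_set_size,
    max_set_size = max_set_size, min_deg_overlap = min_deg_overlap,
    auc_good = auc_good, auc_optimal = auc_optimal,
    min_weight = min_weight, hist_bins = hist_bins, n_folds = n_folds,
    variant = variant, knn_k = knn_k, moderated = moderated,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the full guilt-by-association pipeline
#'
#' Stages, in order: load or simulate the paired expression data;
#' impute missing values (kNN) and quantile-normalise; collapse probes
#' if a probe map is given; call DEGs (paired t + BH); build the
#' absolute-Spearman co-expression network on the DEGs; filter the
#' gene-set catalog by size and DEG overlap; score every informative
#' term by cross-validated neighbor voting and classify at the AUC
#' thresholds. Identical configs produce identical reports.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, the DEG table, edge
#'   list, weight histogram, catalog summary, GBA results, MF scores and
#'   a YAML report of stage counts are written there as TSV/YAML.
#' @return Object of class `pipeline_report`: list with `counts`,
#'   `deg_table`, `degs`, `network`, `histogram`, `catalog`, `fit`,
#'   `config`, and for simulated runs `truth`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), parent = e)
    })
  }
  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- stage("simulate", simulate_study(config$simulation))
    expr <- sim$expr; samples <- sim$samples
    catalog0 <- sim$catalog; truth <- sim$truth
  } else {
    expr <- stage("load", read_expression(config$expression))
    samples <- stage("load", read_sample_sheet(config$samples))
    catalog0 <- stage("load", read_gmt(config$gene_sets))
  }
  expr <- stage("impute", impute_knn(expr, k = config$knn_k))
  expr <- stage("normalize", quantile_normalize(expr))
  if (!is.null(config$probe_map)) {
    pm <- stage("collapse", read_probe_map(config$probe_map))
    expr <- stage("collapse", collapse_probes(expr, pm))
  }
  deg_table <- stage("diffexpr", call_degs(
    expr, samples, fdr_max = config$fdr_max,
    min_abs_logfc = config$min_abs_logfc, moderated = config$moderated))
  degs <- filter_degs(deg_table, config$fdr_max, config$min_abs_logfc)
  if (nrow(degs) < 2) {
    abort(sprintf("pipeline stage 'network' failed: only %d DEG(s) called",
                  nrow(degs)))
  }
  rho <- stage("network", spearman_matrix(expr, degs$gene))
  network <- build_dcn(rho, min_weight = config$min_weight)
  histogram <- weight_histogram(network, config$hist_bins)
  seed_terms <- stage("catalog", filter_set_size(
    catalog0, config$min_set_size, config$max_set_size))
  informative <- stage("catalog", filter_deg_overlap(
    seed_terms, degs$gene, config$min_deg_overlap))
  if (n_terms(informative) == 0) {
    abort("pipeline stage 'gba' failed: no informative terms after filtering")
  }
  fit <- stage("gba", gba_predict(
    network, informative, n_folds = config$n_folds, seed = config$seed,
    variant = config$variant, good = config$auc_good,
    optimal = config$auc_optimal))
  counts <- list(
    n_genes = nrow(expr), n_samples = nrow(samples),
    n_degs = nrow(degs), n_network_nodes = length(network$nodes),
    n_edges = nrow(dcn_edges(network)),
    n_catalog_terms = n_terms(catalog0),
    n_seed_terms = n_terms(seed_terms),
    n_informative_terms = n_terms(informative),
    n_terms_scored = nrow(fit$terms), n_terms_skipped = nrow(fit$skipped),
    n_optimal = sum(fit$terms$label == "optimal"),
    n_good = sum(fit$terms$label == "good"),
    n_other = sum(fit$terms$label == "other")
  )
  report <- structure(list(
    counts = counts, deg_table = deg_table, degs = degs,
    network = network, histogram = histogram, catalog = informative,
    fit = fit, truth = truth, config = config
  ), class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (nm in names(x$counts)) cat(sprintf("  %s: %s\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' @rdname tidy.gba_fit
#' @export
glance.pipeline_report <- function(x, ...) as_tibble(x$counts)

#' Write a pipeline report's tables to disk
#'
#' @param report a `pipeline_report`.
#' @param out_dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fmt_sci <- function(x) formatC(x, format = "e", digits = 3)
  deg_out <- report$deg_table %>%
    mutate(p_value = fmt_sci(.data$p_value), fdr = fmt_sci(.data$fdr))
  readr::write_tsv(deg_out, file.path(out_dir, "deg_table.tsv"))
  readr::write_tsv(dcn_edges(report$network),
                   file.path(out_dir, "edges.tsv"))
  readr::write_tsv(report$histogram,
                   file.path(out_dir, "weight_histogram.tsv"))
  readr::write_tsv(tidy(report$catalog),
                   file.path(out_dir, "catalog_summary.tsv"))
  readr::write_tsv(tidy(report$fit), file.path(out_dir, "gba_results.tsv"))
  readr::write_tsv(report$fit$mf, file.path(out_dir, "mf_scores.tsv"))
  cfg <- report$config
  cfg_list <- unclass(cfg)
  cfg_list$simulation <- if (!is.null(cfg$simulation))
    unclass(cfg$simulation)
  yaml::write_yaml(list(counts = report$counts, config = cfg_list),
                   file.path(out_dir, "report.yaml"))
  invisible(out_dir)
}

#' Score a synthetic pipeline run against its ground truth
#'
#' Compares the pipeline's DEG calls and per-term AUCs with the planted
#' truth of the simulation that produced the data.
#'
#' @param report a `pipeline_report` from a simulated run.
#' @param truth optionally override the truth stored in the report.
#' @return A list: `de_recall`, `de_precision`, `terms` (per scored
#'   term: `term`, `mean_auc`, `label`, `planted`), `planted_mean_auc`,
#'   `background_mean_auc`, `planted_recovery_optimal` (fraction of
#'   evaluable planted terms labelled optimal; `NA` when no planted
#'   terms exist).
#' @export
evaluate_against_truth <- function(report, truth = NULL) {
  stopifnot(inherits(report, "pipeline_report"))
  truth <- truth %||% report$truth
  if (is.null(truth)) abort("no truth available: not a simulated run?")
  if (!all(truth$de_genes %in% report$deg_table$gene)) {
    abort("truth and report gene universes do not match")
  }
  called <- report$degs$gene
  de_recall <- if (length(truth$de_genes))
    mean(truth$de_genes %in% called) else NA_real_
  de_precision <- if (length(called))
    mean(called %in% truth$de_genes) else NA_real_
  terms <- report$fit$terms %>%
    select("term", "mean_auc", "label") %>%
    mutate(planted = .data$term %in% names(truth$planted_terms))
  planted <- terms[terms$planted, ]
  background <- terms[!terms$planted, ]
  list(
    de_recall = de_recall, de_precision = de_precision, terms = terms,
    planted_mean_auc = if (nrow(planted)) mean(planted$mean_auc) else NA_real_,
    background_mean_auc = if (nrow(background)) mean(background$mean_auc)
      else NA_real_,
    planted_recovery_optimal = if (length(truth$planted_terms) == 0)
      NA_real_ else if (nrow(planted) == 0) 0 else
      mean(planted$label == "optimal")
  )
}
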