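#' Configure a synthetic paired-expression study
#'
#' Bundles and validates the parameters of the synthetic-data generator.
#' The generator emulates a paired tumour/normal microarray study on the
#' log2 scale: each gene has a Gaussian baseline, each (gene, pair) shares a
#' random intercept that paired differences cancel, differentially expressed
#' (DE) genes receive a condition shift in the tumour sample, and disjoint
#' modules of DE genes share a per-sample latent factor that elevates their
#' pairwise co-expression.
#'
#' @param n_genes number of genes.
#' @param n_pairs number of tumour/normal pairs (two samples each).
#' @param n_de number of genes planted as differentially expressed.
#' @param effect_size log2-units condition shift added to tumour samples of
#'   DE genes (sign randomised per gene).
#' @param module_sizes integer vector; sizes of disjoint co-expression
#'   modules carved out of the DE genes.
#' @param module_strength latent-factor loading in `[0, 1]` shared by all
#'   members of a module.
#' @param module_factor_sd standard deviation (log2 units) of the
#'   per-patient module factor. Default 3, comparable to the disease
#'   effect: co-expression programs swing about as widely across patients
#'   as the tumour/normal difference itself. The factor is drawn once per
#'   pair and shared by the pair's two samples, so it elevates pooled
#'   co-expression without touching the paired differences.
#' @param noise_sd standard deviation (log2 units) of i.i.d. Gaussian noise.
#' @param missing_rate fraction in `[0, 1)` of entries replaced by `NA`.
#' @param n_terms number of gene sets in the synthetic catalog.
#' @param term_size_range length-2 integer vector, inclusive range of gene
#'   set sizes.
#' @param frac_planted fraction in `[0, 1]` of terms seeded from a module.
#' @param baseline_mean,baseline_sd location and scale of the Gaussian gene
#'   baselines (log2 intensity units).
#' @param pair_sd standard deviation of the per-(gene, pair) random
#'   intercept.
#' @param seed integer RNG seed; identical configs give bit-identical data.
#'
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 100, n_pairs = 6, n_de = 10,
#'                   module_sizes = c(5), n_terms = 8)
sim_config <- function(n_genes = 500, n_pairs = 17, n_de = 50,
                       effect_size = 3, module_sizes = c(10, 10, 10),
                       module_strength = 0.9, module_factor_sd = 3,
                       noise_sd = 0.5,
                       missing_rate = 0.01, n_terms = 40,
                       term_size_range = c(20, 60), frac_planted = 0.2,
                       baseline_mean = 8, baseline_sd = 2, pair_sd = 0.5,
                       seed = 1L) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) abort(sprintf("invalid `%s`: %s", field, msg),
                           class = "gbanet_config_error")
  }
  chk(is.numeric(n_genes) && n_genes >= 2, "n_genes", "need at least 2 genes")
  chk(is.numeric(n_pairs) && n_pairs >= 2, "n_pairs", "need at least 2 pairs")
  chk(is.numeric(n_de) && n_de >= 0 && n_de <= n_genes, "n_de",
      "must satisfy 0 <= n_de <= n_genes")
  chk(is.numeric(effect_size) && effect_size >= 0, "effect_size",
      "must be non-negative")
  chk(is.numeric(module_sizes) && all(module_sizes >= 2) &&
        sum(module_sizes) <= n_de || length(module_sizes) == 0,
      "module_sizes", "sizes must be >= 2 and sum to at most n_de")
  chk(is.numeric(module_strength) && module_strength >= 0 &&
        module_strength <= 1, "module_strength", "must lie in [0, 1]")
  chk(is.numeric(module_factor_sd) && module_factor_sd >= 0,
      "module_factor_sd", "must be non-negative")
  chk(is.numeric(noise_sd) && noise_sd > 0, "noise_sd", "must be positive")
  chk(is.numeric(missing_rate) && missing_rate >= 0 && missing_rate < 1,
      "missing_rate", "must lie in [0, 1)")
  chk(is.numeric(n_terms) && n_terms >= 0, "n_terms", "must be non-negative")
  chk(is.numeric(term_size_range) && length(term_size_range) == 2 &&
        term_size_range[1] >= 1 && term_size_range[1] <= term_size_range[2],
      "term_size_range", "must be an ascending pair of positive counts")
  chk(is.numeric(frac_planted) && frac_planted >= 0 && frac_planted <= 1,
      "frac_planted", "must lie in [0, 1]")
  chk(is.numeric(baseline_sd) && baseline_sd >= 0, "baseline_sd",
      "must be non-negative")
  chk(is.numeric(pair_sd) && pair_sd >= 0, "pair_sd", "must be non-negative")
  chk(is.numeric(seed) && is.finite(seed), "seed", "must be a finite integer")
  structure(list(
    n_genes = as.integer(n_genes), n_pairs = as.integer(n_pairs),
    n_de = as.integer(n_de), effect_size = effect_size,
    module_sizes = as.integer(module_sizes),
    module_strength = module_strength,
    module_factor_sd = module_factor_sd, noise_sd = noise_sd,
    missing_rate = missing_rate, n_terms = as.integer(n_terms),
    term_size_range = as.integer(term_size_range),
    frac_planted = frac_planted, baseline_mean = baseline_mean,
    baseline_sd = baseline_sd, pair_sd = pair_sd, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a paired tumour/normal expression matrix
#'
#' Draws a gene-by-sample log2 expression matrix under the paired design
#' described in [sim_config()], together with the ground truth needed to
#' score downstream recovery.
#'
#' @param config a [sim_config()] object.
#'
#' @return A list of class `gba_sim` with elements
#'   * `expr`: tibble, first column `gene`, one column per sample;
#'   * `samples`: tibble with columns `sample`, `pair`, `condition`
#'     (`"tumor"` / `"normal"`);
#'   * `truth`: `synthetic_truth` list with `de_genes`, `de_sign`,
#'     `modules` (list of gene-ID vectors), `planted_terms` (empty until
#'     [simulate_gene_sets()] is run) and `seed`.
#' @export
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 50, n_pairs = 4,
#'                                       n_de = 6, module_sizes = c(3)))
#' dim(sim$expr)
simulate_expression <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  withr::with_seed(config$seed, {
    width <- max(4, nchar(config$n_genes))
    genes <- sprintf(paste0("g%0", width, "d"), seq_len(config$n_genes))
    pairs <- sprintf("P%02d", seq_len(config$n_pairs))
    samples <- tibble(
      sample = c(rbind(paste0(pairs, "_T"), paste0(pairs, "_N"))),
      pair = rep(pairs, each = 2),
      condition = rep(c("tumor", "normal"), times = config$n_pairs)
    )
    de_genes <- sort(sample(genes, config$n_de))
    de_sign <- setNames(sample(c(-1, 1), config$n_de, replace = TRUE),
                        de_genes)
    modules <- list()
    if (length(config$module_sizes) > 0 && sum(config$module_sizes) > 0) {
      pool <- sample(de_genes)  # random disjoint carve-out of the DE genes
      idx <- 0L
      modules <- lapply(config$module_sizes, function(sz) {
        members <- sort(pool[(idx + 1L):(idx + sz)])
        idx <<- idx + sz
        members
      })
      # a co-regulated module is dysregulated coherently: one shared sign
      for (members in modules) {
        de_sign[members] <- sample(c(-1, 1), 1)
      }
    }

    n_samp <- 2L * config$n_pairs
    mu <- rnorm(config$n_genes, config$baseline_mean, config$baseline_sd)
    x <- matrix(mu, config$n_genes, n_samp)
    dimnames(x) <- list(genes, samples$sample)
    # per-(gene, pair) intercept, shared by the two samples of a pair
    b <- matrix(rnorm(config$n_genes * config$n_pairs, 0, config$pair_sd),
                config$n_genes, config$n_pairs)
    x <- x + b[, rep(seq_len(config$n_pairs), each = 2)]
    is_tumor <- samples$condition == "tumor"
    if (config$n_de > 0) {
      x[de_genes, is_tumor] <- x[de_genes, is_tumor] +
        config$effect_size * de_sign
    }
    for (m in seq_along(modules)) {
      # one latent factor per module, drawn per patient (pair) and shared
      # by the pair's two samples: co-expression without paired-difference
      # variance
      f <- rnorm(config$n_pairs, 0, config$module_factor_sd)
      fs <- f[rep(seq_len(config$n_pairs), each = 2)]
      x[modules[[m]], ] <- x[modules[[m]], ] +
        config$module_strength * rep(fs, each = length(modules[[m]]))
    }
    x <- x + matrix(rnorm(length(x), 0, config$noise_sd), nrow(x))
    if (config$missing_rate > 0) {
      miss <- runif(length(x)) < config$missing_rate
      # keep at least one observed value per row so imputation is defined
      for (i in which(rowSums(matrix(!miss, nrow(x)) ) == 0)) {
        miss[(0:(n_samp - 1)) * nrow(x) + i][1] <- FALSE
      }
      x[miss] <- NA_real_
    }
    truth <- structure(list(
      de_genes = de_genes, de_sign = de_sign, modules = modules,
      planted_terms = integer(0), seed = config$seed
    ), class = "synthetic_truth")
    structure(list(expr = expr_as_tibble(x), samples = samples,
                   truth = truth, config = config),
              class = "gba_sim")
  })
}

#' Simulate a gene-set catalog with planted terms
#'
#' Builds `n_terms` gene sets over `universe`. A fraction `frac_planted`
#' of them are "planted": each is the union of one co-expression module
#' from `truth` and random filler genes drawn from outside the DE set, so
#' that a planted term's overlap with the DE genes is exactly its module.
#' The remaining terms are uniform random subsets of the universe.
#'
#' @param truth a `synthetic_truth` from [simulate_expression()].
#' @param config the same [sim_config()].
#' @param universe character vector of gene IDs (must contain all genes in
#'   `truth`).
#'
#' @return A list with `catalog` (a [go_catalog()]) and `truth` (the input
#'   truth with `planted_terms` filled in: named integer vector mapping
#'   term ID to module index).
#' @export
simulate_gene_sets <- function(truth, config, universe) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!all(truth$de_genes %in% universe)) {
    abort("universe must contain every gene in the truth object")
  }
  if (config$term_size_range[2] > length(universe)) {
    abort("invalid `term_size_range`: maximum exceeds universe size",
          class = "gbanet_config_error")
  }
  withr::with_seed(config$seed + 1L, {
    n_planted <- if (length(truth$modules) == 0) 0L else
      as.integer(round(config$frac_planted * config$n_terms))
    sizes <- sample(seq(config$term_size_range[1], config$term_size_range[2]),
                    config$n_terms, replace = TRUE)
    ids <- sprintf("T%03d", seq_len(config$n_terms))
    non_de <- setdiff(universe, truth$de_genes)
    planted_terms <- integer(0)
    sets <- vector("list", config$n_terms)
    names(sets) <- ids
    descs <- character(config$n_terms)
    for (t in seq_len(config$n_terms)) {
      if (t <= n_planted) {
        m <- ((t - 1L) %% length(truth$modules)) + 1L
        module <- truth$modules[[m]]
        sz <- max(sizes[t], length(module))
        filler <- sample(non_de, sz - length(module))
        sets[[t]] <- sort(c(module, filler))
        descs[t] <- sprintf("planted from module %d", m)
        planted_terms[ids[t]] <- m
      } else {
        sets[[t]] <- sort(sample(universe, sizes[t]))
        descs[t] <- "background"
      }
    }
    catalog <- go_catalog(
      tidyr::unnest(tibble(term = ids, name = descs, gene = sets),
                    "gene"),
      universe = universe
    )
    truth$planted_terms <- planted_terms
    list(catalog = catalog, truth = truth)
  })
}

#' Simulate a complete study: expression, sample sheet and catalog
#'
#' Convenience wrapper chaining [simulate_expression()] and
#' [simulate_gene_sets()] with the full gene list as universe.
#'
#' @inheritParams simulate_expression
#' @return A `gba_sim` list with `expr`, `samples`, `truth` (with
#'   `planted_terms` filled) and `catalog`.
#' @export
simulate_study <- function(config) {
  sim <- simulate_expression(config)
  gs <- simulate_gene_sets(sim$truth, sim$config, sim$expr$gene)
  sim$catalog <- gs$catalog
  sim$truth <- gs$truth
  sim
}

#' Write a simulated study to disk as plain-text fixtures
#'
#' Writes the expression TSV, sample-sheet TSV, GMT gene sets and a
#' structured truth file, in the same dialects the package readers accept,
#' and returns a manifest of the paths written. Missing expression entries
#' are serialised as `"NA"`.
#'
#' @param sim a `gba_sim` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return Named character vector of file paths (the manifest), invisibly.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "gba_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "truth.tsv")
  )
  readr::write_tsv(sim$expr, paths[["expression"]], na = "NA")
  readr::write_tsv(sim$samples, paths[["samples"]])
  if (!is.null(sim$catalog)) write_gmt(sim$catalog, paths[["gene_sets"]])
  write_truth(sim$truth, paths[["truth"]])
  invisible(paths)
}

#' @rdname write_fixture
#' @param path truth file path.
#' @param truth a `synthetic_truth`.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  rows <- c(
    sprintf("seed\t%d\t", truth$seed),
    sprintf("de_gene\t%s\t%d", truth$de_genes,
            as.integer(truth$de_sign[truth$de_genes])),
    unlist(lapply(seq_along(truth$modules), function(m) {
      sprintf("module\t%d\t%s", m, truth$modules[[m]])
    })),
    if (length(truth$planted_terms)) {
      sprintf("planted_term\t%s\t%d", names(truth$planted_terms),
              as.integer(truth$planted_terms))
    }
  )
  writeLines(c("record\tkey\tvalue", rows), path)
  invisible(path)
}

#' @rdname write_fixture
#' @export
read_truth <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  de <- tab[tab$record == "de_gene", ]
  mods <- tab[tab$record == "module", ]
  pl <- tab[tab$record == "planted_term", ]
  modules <- lapply(split(mods$value, as.integer(mods$key)), sort)
  names(modules) <- NULL
  structure(list(
    de_genes = sort(de$key),
    de_sign = setNames(as.numeric(de$value), de$key)[sort(de$key)],
    modules = modules,
    planted_terms = setNames(as.integer(pl$value), pl$key),
    seed = as.integer(tab$key[tab$record == "seed"][1])
  ), class = "synthetic_truth")
}
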