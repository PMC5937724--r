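test_that("simulation respects its configuration and ground-truth invariants", {
  sim <- simulate_study(small_config())
  cfg <- sim$config
  expect_equal(nrow(sim$expr), cfg$n_genes)
  expect_equal(ncol(sim$expr) - 1, 2 * cfg$n_pairs)
  expect_equal(sort(sim$samples$sample), sort(names(sim$expr)[-1]))
  expect_true(all(table(sim$samples$pair) == 2))
  expect_setequal(unique(sim$samples$condition), c("tumor", "normal"))
  # truth invariants
  tr <- sim$truth
  expect_length(tr$de_genes, cfg$n_de)
  for (m in tr$modules) expect_true(all(m %in% tr$de_genes))
  expect_equal(anyDuplicated(unlist(tr$modules)), 0)
  expect_true(all(tr$planted_terms %in% seq_along(tr$modules)))
  # every planted term contains its module
  for (tid in names(tr$planted_terms)) {
    members <- sim$catalog$sets$gene[sim$catalog$sets$term == tid]
    expect_true(all(tr$modules[[tr$planted_terms[[tid]]]] %in% members))
  }
  expect_equal(length(tr$planted_terms),
               round(cfg$frac_planted * cfg$n_terms))
})

test_that("identical seeds give bit-identical studies; rate-zero edge cases hold", {
  a <- simulate_study(small_config())
  b <- simulate_study(small_config())
  expect_identical(a$expr, b$expr)
  expect_identical(a$catalog$sets, b$catalog$sets)
  expect_identical(a$truth, b$truth)
  # different seed changes the data
  c <- simulate_study(small_config(seed = 43L))
  expect_false(identical(a$expr, c$expr))
  # missing_rate = 0 leaves no missing markers
  clean <- simulate_expression(small_config(missing_rate = 0))
  expect_false(anyNA(clean$expr))
  # frac_planted = 0 plants nothing
  none <- simulate_study(small_config(frac_planted = 0))
  expect_length(none$truth$planted_terms, 0)
})

test_that("null simulation yields ~no DEG calls at FDR < 0.001", {
  sim <- simulate_expression(small_config(effect_size = 0,
                                          module_strength = 0,
                                          missing_rate = 0))
  degs <- filter_degs(call_degs(sim$expr, sim$samples))
  expect_lte(nrow(degs), 1)
})

test_that("planted within-module correlation exceeds off-module correlation", {
  sim <- simulate_expression(default_config(missing_rate = 0))
  rho <- abs(spearman_matrix(sim$expr, sim$truth$de_genes))
  diag(rho) <- NA
  mods <- sim$truth$modules
  in_mod <- unlist(lapply(mods, function(m) rho[m, m]))
  mod_genes <- unlist(mods)
  off <- rho[mod_genes, setdiff(sim$truth$de_genes, mod_genes)]
  expect_gt(mean(in_mod, na.rm = TRUE), mean(off, na.rm = TRUE))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(n_de = 1000, n_genes = 500), "n_de")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(module_strength = 1.5), "module_strength")
  expect_error(sim_config(term_size_range = c(30, 20)), "term_size_range")
  sim <- simulate_expression(small_config())
  big <- small_config(term_size_range = c(8, 1000))
  expect_error(simulate_gene_sets(sim$truth, big, sim$expr$gene),
               "term_size_range")
})

test_that("fixtures round-trip losslessly through the readers", {
  sim <- simulate_study(small_config())
  dir <- withr::local_tempdir()
  manifest <- write_fixture(sim, dir)
  expect_true(all(file.exists(manifest)))
  expr2 <- read_expression(manifest[["expression"]])
  expect_equal(as.data.frame(expr2), as.data.frame(sim$expr),
               tolerance = 1e-12)
  ss2 <- read_sample_sheet(manifest[["samples"]])
  expect_equal(as.data.frame(ss2), as.data.frame(sim$samples))
  cat2 <- read_gmt(manifest[["gene_sets"]])
  expect_equal(cat2$sets$term, sim$catalog$sets$term)
  expect_setequal(
    paste(cat2$sets$term, cat2$sets$gene),
    paste(sim$catalog$sets$term, sim$catalog$sets$gene))
  tr2 <- read_truth(manifest[["truth"]])
  expect_equal(tr2$de_genes, sim$truth$de_genes)
  expect_equal(tr2$modules, sim$truth$modules)
  expect_equal(tr2$planted_terms, sim$truth$planted_terms)
  # GMT line format contract
  first <- strsplit(readLines(manifest[["gene_sets"]], n = 1), "\t")[[1]]
  expect_gte(length(first), 3)
  # missing entries serialised as NA
  expect_true(any(grepl("\tNA", readLines(manifest[["expression"]]))))
})
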