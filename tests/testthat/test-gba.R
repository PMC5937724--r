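test_that("neighbor-voting scores evaluate both variants' formulas", {
  # 3 nodes, w12 = w13 = 0.5, w23 = 0, training {2}
  rho <- diag(3)
  rho[1, 2] <- rho[2, 1] <- 0.5
  rho[1, 3] <- rho[3, 1] <- 0.5
  dimnames(rho) <- list(c("n1", "n2", "n3"), c("n1", "n2", "n3"))
  net <- build_dcn(rho)
  ratio <- neighbor_voting_scores(net, "n2", "ratio")
  expect_equal(ratio$score[ratio$gene == "n1"], 1.0)  # 0.5 / 0.5
  degr <- neighbor_voting_scores(net, "n2", "degree")
  expect_equal(degr$score[degr$gene == "n1"], 0.5)    # 0.5 / 1.0
  # candidate with no weight to training genes scores 0 under both
  expect_equal(ratio$score[ratio$gene == "n3"], 0)
  expect_equal(degr$score[degr$gene == "n3"], 0)
  # zero ratio denominator (candidate connected only to training) tops the list
  rho2 <- diag(4)
  nm <- paste0("n", 1:4)
  dimnames(rho2) <- list(nm, nm)
  rho2["n1", "n2"] <- rho2["n2", "n1"] <- 0.8  # n1 touches training only
  rho2["n3", "n2"] <- rho2["n2", "n3"] <- 0.1
  rho2["n3", "n4"] <- rho2["n4", "n3"] <- 0.5
  top <- neighbor_voting_scores(build_dcn(rho2), "n2", "ratio")
  expect_equal(top$score[top$gene == "n3"], 0.2)  # 0.1 / 0.5
  expect_gt(top$score[top$gene == "n1"], max(top$score[top$gene != "n1"]))
  expect_error(neighbor_voting_scores(net, character(0)), "empty")
  expect_error(neighbor_voting_scores(net, "zz"), "zz")
})

test_that("ratio and degree variants rank candidates identically with positive denominators", {
  for (s in 1:25) {
    net <- random_dcn(10, seed = 100 + s)
    train <- paste0("n", 1:3)
    r <- neighbor_voting_scores(net, train, "ratio")
    d <- neighbor_voting_scores(net, train, "degree")
    expect_equal(order(r$score), order(d$score))
    # algebraic identity s_ratio = s_deg / (1 - s_deg)
    expect_equal(r$score, d$score / (1 - d$score), tolerance = 1e-10)
  }
})

test_that("auroc equals brute-force pair counting and spans its range", {
  expect_equal(auroc(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_equal(auroc(c(1, 1), c(1, 1, 1)), 0.5)
  expect_equal(auroc(c(3, 1), c(2, 0)), 0.75)
  expect_error(auroc(numeric(0), 1), "non-empty")
  for (s in 1:20) {
    sc <- withr::with_seed(s, list(p = sample(0:3, 5, TRUE),
                                   n = sample(0:3, 7, TRUE)))
    expect_equal(auroc(sc$p, sc$n), auroc_brute(sc$p, sc$n))
  }
})

test_that("cross-validated folds partition the annotated genes deterministically", {
  net <- random_dcn(20, seed = 9)
  term <- paste0("n", c(1, 3, 5, 7, 9, 11, 13))
  res <- cross_validated_auc(net, term, n_folds = 3, seed = 11)
  expect_true(res$evaluable)
  expect_length(res$fold_aucs, 3)
  expect_equal(res$mean_auc, mean(res$fold_aucs))
  expect_true(all(res$fold_aucs >= 0 & res$fold_aucs <= 1))
  # folds are disjoint and cover the annotated network genes
  expect_setequal(unlist(res$folds), term)
  expect_equal(sum(lengths(res$folds)), length(term))
  expect_equal(diff(range(lengths(res$folds))), 1)  # 7 = 3 + 2 + 2
  # determinism under the seed
  res2 <- cross_validated_auc(net, term, n_folds = 3, seed = 11)
  expect_identical(res[c("folds", "fold_aucs")],
                   res2[c("folds", "fold_aucs")])
  # annotated genes absent from the network are ignored
  res3 <- cross_validated_auc(net, c(term, "offnet1", "offnet2"),
                              n_folds = 3, seed = 11)
  expect_equal(res3$n_annotated, length(term))
  # too few annotated genes: skipped with a reason, never AUC 0
  skip_res <- cross_validated_auc(net, paste0("n", 1:2), n_folds = 3)
  expect_false(skip_res$evaluable)
  expect_match(skip_res$reason, "need >= 3")
  expect_null(skip_res$mean_auc)
})

test_that("perfect modules give AUC 1 and flat networks give AUC 0.5", {
  # block of 9 fully connected nodes, 9 isolated others
  w <- matrix(0, 18, 18)
  w[1:9, 1:9] <- 1
  diag(w) <- 1
  dimnames(w) <- list(paste0("n", 1:18), paste0("n", 1:18))
  net <- build_dcn(w)
  res <- cross_validated_auc(net, paste0("n", 1:9), n_folds = 3, seed = 2)
  expect_equal(res$fold_aucs, c(1, 1, 1))
  # all-equal weights: every candidate ties, AUC exactly 0.5
  w2 <- matrix(0.5, 12, 12)
  diag(w2) <- 1
  dimnames(w2) <- list(paste0("n", 1:12), paste0("n", 1:12))
  flat <- cross_validated_auc(build_dcn(w2), paste0("n", 1:6),
                              n_folds = 3, seed = 3)
  expect_equal(flat$fold_aucs, c(0.5, 0.5, 0.5))
})

test_that("multifunctionality scores follow the 1/(|T|(N-|T|)) sum", {
  # single term of 20 in a universe of 100
  cat1 <- go_catalog(
    tibble::tibble(term = "T", gene = paste0("g", 1:20)),
    universe = paste0("g", 1:100))
  mf <- multifunctionality_scores(cat1)
  expect_equal(mf$mf_score[mf$gene == "g1"], 1 / (20 * 80))  # 6.25e-4
  # unannotated universe genes score exactly 0
  expect_equal(mf$mf_score[mf$gene == "g99"], 0)
  expect_equal(nrow(mf), 100)
  # two terms of sizes 20 and 50: hand sum 1/1600 + 1/2500
  cat2 <- go_catalog(
    tibble::tibble(term = rep(c("A", "B"), c(20, 50)),
                   gene = c(paste0("g", 1:20), paste0("g", 1:50))),
    universe = paste0("g", 1:100))
  mf2 <- multifunctionality_scores(cat2)
  expect_equal(mf2$mf_score[mf2$gene == "g1"], 1 / 1600 + 1 / 2500)
  # additivity: dropping term B lowers members by exactly 1/(50*50)
  dropB <- multifunctionality_scores(
    go_catalog(cat2$sets[cat2$sets$term == "A", ],
               universe = cat2$universe))
  delta <- mf2$mf_score[match(paste0("g", 1:50), mf2$gene)] -
    dropB$mf_score[match(paste0("g", 1:50), dropB$gene)]
  expect_equal(delta, rep(1 / 2500, 50))
  # term as large as the universe is an error
  expect_error(multifunctionality_scores(cat1, universe_size = 20), "smaller")
})

test_that("the MF-ranking baseline AUC follows brute-force pair counting", {
  mf <- tibble::tibble(gene = paste0("g", 1:4), mf_score = c(4, 3, 2, 1))
  # members g1, g3: pairs (4>3),(4>1),(2<3),(2>1) -> 3/4
  expect_equal(mf_ranking_auc(mf, c("g1", "g3"), paste0("g", 1:4)), 0.75)
  # all-equal MF: 0.5
  flat <- tibble::tibble(gene = paste0("g", 1:4), mf_score = rep(1, 4))
  expect_equal(mf_ranking_auc(flat, c("g1", "g3"), paste0("g", 1:4)), 0.5)
  # members exactly the top-MF genes: 1.0
  expect_equal(mf_ranking_auc(mf, c("g1", "g2"), paste0("g", 1:4)), 1.0)
  # degenerate split: NA with warning
  expect_warning(out <- mf_ranking_auc(mf, paste0("g", 1:4),
                                       paste0("g", 1:4)), "degenerate")
  expect_true(is.na(out))
})

test_that("term classification applies strict 0.7/0.8 thresholds and sorts", {
  res <- tibble::tibble(term = c("a", "b", "c", "d"),
                        mean_auc = c(0.91648, 0.8, 0.7, 0.85))
  out <- classify_terms(res)
  expect_equal(as.character(out$label),
               c("optimal", "optimal", "good", "other"))
  expect_equal(out$term, c("a", "d", "b", "c"))  # AUC descending
  expect_equal(as.character(out$label[out$mean_auc == 0.8]), "good")
  expect_equal(as.character(out$label[out$mean_auc == 0.7]), "other")
})

test_that("a whole-catalog fit is deterministic and planted terms dominate", {
  sim <- simulate_study(default_config())
  expr <- quantile_normalize(impute_knn(sim$expr))
  degs <- filter_degs(call_degs(expr, sim$samples))
  net <- build_dcn(spearman_matrix(expr, degs$gene))
  inf <- filter_deg_overlap(filter_set_size(sim$catalog, 20, 1000),
                            degs$gene, min_overlap = 3)
  fit <- gba_predict(net, inf, seed = 1)
  fit2 <- gba_predict(net, inf, seed = 1)
  expect_identical(tidy(fit), tidy(fit2))
  ev <- tidy(fit)
  planted <- names(sim$truth$planted_terms)
  pl <- ev$mean_auc[ev$term %in% planted]
  bg_terms <- ev$term[!ev$term %in% planted]
  bg <- ev$mean_auc[ev$term %in% bg_terms]
  expect_gte(mean(pl) - mean(bg), 0.2)
  # module-free background terms are beaten by every planted term
  mod_genes <- unlist(sim$truth$modules)
  modfree <- vapply(bg_terms, function(t) {
    !any(sim$catalog$sets$gene[sim$catalog$sets$term == t] %in% mod_genes)
  }, logical(1))
  if (any(modfree)) {
    expect_gte(min(pl), max(bg[modfree]) + 0.2)
  }
  # glance summarises the same fit
  g <- glance(fit)
  expect_equal(g$n_terms, nrow(ev))
  expect_equal(g$max_auc, max(ev$mean_auc))
  expect_equal(g$n_optimal, sum(ev$label == "optimal"))
})
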