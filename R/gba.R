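#' Neighbor-voting scores for candidate genes
#'
#' Scores every network gene outside the training set for membership in
#' the function defined by the training set. With training set A and
#' candidate i:
#'
#' * `"ratio"` (default): s_i = sum_{j in A} w_ij / sum_{j not in A, j != i} w_ij
#'   — the guilt-by-association vote relative to genes outside the set;
#' * `"degree"`: s_i = sum_{j in A} w_ij / sum_{j != i} w_ij — the vote
#'   normalised by the candidate's total connectivity.
#'
#' The two variants rank candidates identically whenever every
#' denominator is positive (s_ratio = s_deg / (1 − s_deg), strictly
#' increasing). A candidate with zero weight to every training gene
#' scores 0 under both. A candidate connected *only* to training genes
#' makes the ratio denominator 0; it is assigned the maximum finite
#' candidate score plus one (top rank), since ranks are all the
#' downstream AUROC uses.
#'
#' @param network a [build_dcn()] object.
#' @param training character vector of training gene IDs (non-empty,
#'   inside the network).
#' @param variant `"ratio"` or `"degree"`.
#' @return Tibble `gene`, `score` for all non-training nodes.
#' @export
neighbor_voting_scores <- function(network, training,
                                   variant = c("ratio", "degree")) {
  variant <- match.arg(variant)
  stopifnot(inherits(network, "dcn"))
  training <- unique(training)
  if (length(training) == 0) abort("training set is empty")
  outside <- setdiff(training, network$nodes)
  if (length(outside)) {
    abort(sprintf("training genes not in network: %s",
                  paste(outside, collapse = ", ")))
  }
  cand <- setdiff(network$nodes, training)
  if (length(cand) == 0) abort("no candidate genes outside the training set")
  w <- network$weights
  num <- rowSums(w[cand, training, drop = FALSE])
  tot <- rowSums(w[cand, , drop = FALSE])  # diagonal is 0
  if (variant == "degree") {
    s <- ifelse(tot > 0, num / tot, 0)
  } else {
    denom <- tot - num
    s <- ifelse(denom > 0, num / denom, NA_real_)
    s[num == 0] <- 0  # isolated or training-free candidates
    if (anyNA(s)) {   # connected only to training genes: top rank
      top <- if (all(is.na(s))) 0 else max(s, na.rm = TRUE)
      s[is.na(s)] <- top + 1
    }
  }
  tibble(gene = cand, score = unname(s))
}

#' Area under the ROC curve from score lists
#'
#' Probability that a random positive outranks a random negative, ties
#' counted half — the midrank Mann–Whitney statistic:
#' `(#\{p > n\} + 0.5 #\{p = n\}) / (|pos| |neg|)`.
#'
#' @param pos,neg non-empty numeric score vectors for positives and
#'   negatives.
#' @return AUROC in `[0, 1]`.
#' @export
#' @examples
#' auroc(c(3, 1), c(2, 0))  # 0.75
auroc <- function(pos, neg) {
  np <- length(pos); nn <- length(neg)
  if (np == 0 || nn == 0) abort("pos and neg must both be non-empty")
  r <- rank(c(pos, neg))  # midranks
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Cross-validated AUROC of neighbor voting for one gene set
#'
#' The term's genes present in the network are split into `n_folds`
#' near-equal folds by a seeded shuffle (contiguous split; remainder
#' genes go one per leading fold). Each fold is held out in turn: the
#' remaining annotated genes form the training set, neighbor-voting
#' scores are computed for every non-training node, and the AUROC is
#' taken with the held-out genes as positives and the never-annotated
#' network genes as negatives. Genes annotated to the term but absent
#' from the network are ignored.
#'
#' @param network a [build_dcn()] object.
#' @param term_genes character vector: the term's annotated genes.
#' @param n_folds number of folds (default 3).
#' @param seed integer seed for the fold shuffle.
#' @param variant passed to [neighbor_voting_scores()].
#' @return A list with `evaluable` (logical); when evaluable:
#'   `fold_aucs`, `mean_auc`, `n_annotated`, `gene_scores` (tibble
#'   `gene`, `score`, `annotated`: held-out score for annotated genes,
#'   mean across folds otherwise); otherwise a `reason` string. Never
#'   reports an inevaluable term as AUC 0.
#' @export
cross_validated_auc <- function(network, term_genes, n_folds = 3,
                                seed = 1L, variant = c("ratio", "degree")) {
  variant <- match.arg(variant)
  stopifnot(inherits(network, "dcn"), n_folds >= 2)
  ann <- intersect(network$nodes, unique(term_genes))
  if (length(ann) < n_folds) {
    return(list(evaluable = FALSE,
                reason = sprintf("only %d annotated network gene(s); need >= %d",
                                 length(ann), n_folds),
                n_annotated = length(ann)))
  }
  negatives <- setdiff(network$nodes, unique(term_genes))
  if (length(negatives) == 0) {
    return(list(evaluable = FALSE, reason = "no unannotated network genes",
                n_annotated = length(ann)))
  }
  shuffled <- withr::with_seed(seed, sample(ann))
  base_size <- length(ann) %/% n_folds
  extras <- length(ann) %% n_folds
  sizes <- rep(base_size, n_folds) + (seq_len(n_folds) <= extras)
  folds <- split(shuffled, rep(seq_len(n_folds), times = sizes))
  held_score <- setNames(numeric(length(ann)), ann)
  neg_scores <- matrix(0, length(negatives), n_folds,
                       dimnames = list(negatives, NULL))
  fold_aucs <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    train <- setdiff(ann, folds[[f]])
    sc <- neighbor_voting_scores(network, train, variant)
    s <- setNames(sc$score, sc$gene)
    fold_aucs[f] <- auroc(s[folds[[f]]], s[negatives])
    held_score[folds[[f]]] <- s[folds[[f]]]
    neg_scores[, f] <- s[negatives]
  }
  gene_scores <- bind_rows(
    tibble(gene = ann, score = unname(held_score[ann]), annotated = TRUE),
    tibble(gene = negatives, score = unname(rowMeans(neg_scores)),
           annotated = FALSE)
  )
  list(evaluable = TRUE, fold_aucs = fold_aucs,
       mean_auc = mean(fold_aucs), n_annotated = length(ann),
       folds = folds, gene_scores = gene_scores)
}

#' Gene multifunctionality scores
#'
#' For each gene, the sum over its annotated terms T of
#' `1 / (|T| * (N − |T|))`, where `N` is the annotation universe size.
#' Genes in the universe with no annotation score exactly 0. High-MF
#' genes are the ones a single fixed ranking can place well for many
#' functions at once — the multifunctionality bias that inflates
#' guilt-by-association performance.
#'
#' @param catalog a [go_catalog()].
#' @param universe_size `N`; defaults to the catalog's universe size.
#'   Every term must be smaller than `N`.
#' @return Tibble `gene`, `mf_score`, sorted by score descending, one
#'   row per universe gene.
#' @export
multifunctionality_scores <- function(catalog, universe_size = NULL) {
  stopifnot(inherits(catalog, "go_catalog"))
  n_univ <- universe_size %||% length(catalog$universe)
  sizes <- table(catalog$sets$term)
  if (any(sizes >= n_univ)) {
    abort("every term must be smaller than the universe size N")
  }
  per_term <- 1 / (as.numeric(sizes) * (n_univ - as.numeric(sizes)))
  names(per_term) <- names(sizes)
  scores <- catalog$sets %>%
    mutate(w = per_term[.data$term]) %>%
    group_by(.data$gene) %>%
    summarise(mf_score = sum(.data$w), .groups = "drop")
  tibble(gene = catalog$universe) %>%
    left_join(scores, by = "gene") %>%
    mutate(mf_score = dplyr::coalesce(.data$mf_score, 0)) %>%
    arrange(desc(.data$mf_score), .data$gene)
}

#' AUROC of the multifunctionality ranking for one term
#'
#' How well the single gene ranking by MF score "predicts" a term's
#' members among the network genes — the multifunctionality baseline
#' against which neighbor-voting AUCs should be compared.
#'
#' @param mf tibble from [multifunctionality_scores()].
#' @param term_genes the term's annotated genes.
#' @param network_nodes gene IDs to rank (genes missing from `mf` score
#'   0).
#' @return AUROC, or `NA` with a warning if the term has no member or no
#'   non-member among the nodes.
#' @export
mf_ranking_auc <- function(mf, term_genes, network_nodes) {
  s <- setNames(mf$mf_score, mf$gene)[network_nodes]
  s[is.na(s)] <- 0
  is_pos <- network_nodes %in% term_genes
  if (!any(is_pos) || all(is_pos)) {
    warn("degenerate positive/negative split; MF ranking AUC skipped")
    return(NA_real_)
  }
  auroc(s[is_pos], s[!is_pos])
}

#' Classify terms by cross-validated AUC
#'
#' Strict thresholds: `optimal` if `mean_auc > optimal`, `good` if
#' `good < mean_auc <= optimal`, else `other`. A term at exactly 0.8 is
#' good, not optimal; at exactly 0.7, other.
#'
#' @param results data frame with a `mean_auc` column (e.g.
#'   `tidy()` of a [gba_predict()] fit).
#' @param good,optimal strict AUC thresholds (`good < optimal`).
#' @return The input with a `label` factor, sorted by `mean_auc`
#'   descending.
#' @export
classify_terms <- function(results, good = 0.7, optimal = 0.8) {
  stopifnot(is.data.frame(results), "mean_auc" %in% names(results),
            nrow(results) > 0, good < optimal)
  results %>%
    mutate(label = factor(case_when(
      .data$mean_auc > optimal ~ "optimal",
      .data$mean_auc > good ~ "good",
      TRUE ~ "other"
    ), levels = c("optimal", "good", "other"))) %>%
    arrange(desc(.data$mean_auc))
}

#' Guilt-by-association prediction over a whole catalog
#'
#' Runs [cross_validated_auc()] for every term of the catalog on the
#' co-expression network, classifies terms at the AUC thresholds, and
#' attaches multifunctionality scores and the per-term MF-ranking
#' baseline AUC. Each term's fold shuffle is seeded deterministically
#' from `seed` and the term's position, so a fixed seed reproduces the
#' fit exactly.
#'
#' @param network a [build_dcn()] object (nodes = DEGs).
#' @param catalog a [go_catalog()] (typically size- and overlap-filtered).
#' @param n_folds,seed,variant see [cross_validated_auc()].
#' @param good,optimal see [classify_terms()].
#' @param mf_universe_size `N` for the MF formula; defaults to the
#'   catalog universe size.
#' @return Object of class `gba_fit`: list with `terms` (per-term
#'   tibble: `term`, `name`, `n_annotated`, `fold_aucs` list-column,
#'   `mean_auc`, `mf_auc`, `label`, AUC-descending), `skipped` (tibble
#'   `term`, `reason`), `mf` (gene MF table), and `params`.
#' @export
gba_predict <- function(network, catalog, n_folds = 3, seed = 1L,
                        variant = c("ratio", "degree"), good = 0.7,
                        optimal = 0.8, mf_universe_size = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(network, "dcn"), inherits(catalog, "go_catalog"))
  mf <- multifunctionality_scores(catalog, mf_universe_size)
  info <- tidy(catalog)
  sets <- split(catalog$sets$gene, catalog$sets$term)
  term_ids <- info$term
  rows <- vector("list", length(term_ids))
  skipped <- list()
  for (i in seq_along(term_ids)) {
    tid <- term_ids[i]
    res <- cross_validated_auc(network, sets[[tid]], n_folds = n_folds,
                               seed = seed + i, variant = variant)
    if (!res$evaluable) {
      skipped[[tid]] <- tibble(term = tid, reason = res$reason)
      next
    }
    rows[[i]] <- tibble(
      term = tid, name = info$name[i], n_annotated = res$n_annotated,
      fold_aucs = list(res$fold_aucs), mean_auc = res$mean_auc,
      mf_auc = suppressWarnings(
        mf_ranking_auc(mf, sets[[tid]], network$nodes))
    )
  }
  terms <- bind_rows(rows)
  if (nrow(terms) > 0) terms <- classify_terms(terms, good, optimal)
  structure(list(
    terms = terms, skipped = bind_rows(skipped), mf = mf,
    params = list(n_folds = n_folds, seed = seed, variant = variant,
                  good = good, optimal = optimal,
                  n_nodes = length(network$nodes))
  ), class = "gba_fit")
}

#' @export
print.gba_fit <- function(x, ...) {
  cat(sprintf("<gba_fit> %d terms scored (%d skipped) on %d network genes\n",
              nrow(x$terms), nrow(x$skipped), x$params$n_nodes))
  if (nrow(x$terms)) {
    cat(sprintf("  labels: %s\n",
                paste(sprintf("%s=%d", levels(x$terms$label),
                              table(x$terms$label)), collapse = ", ")))
    best <- x$terms[1, ]
    cat(sprintf("  best: %s (mean AUC %.5f)\n", best$term, best$mean_auc))
  }
  invisible(x)
}

#' Tidy and summarise a guilt-by-association fit
#'
#' `tidy()` returns one row per scored term with the fold AUCs spread
#' into `fold1_auc`, `fold2_auc`, ... columns; `glance()` returns a
#' one-row model summary.
#'
#' @param x a `gba_fit`.
#' @param ... unused.
#' @export
tidy.gba_fit <- function(x, ...) {
  if (nrow(x$terms) == 0) return(x$terms)
  folds <- do.call(rbind, x$terms$fold_aucs)
  colnames(folds) <- sprintf("fold%d_auc", seq_len(ncol(folds)))
  bind_cols(select(x$terms, -"fold_aucs"), as_tibble(folds)) %>%
    select("term", "name", "n_annotated", dplyr::starts_with("fold"),
           "mean_auc", "mf_auc", "label")
}

#' @rdname tidy.gba_fit
#' @export
glance.gba_fit <- function(x, ...) {
  tibble(
    n_terms = nrow(x$terms), n_skipped = nrow(x$skipped),
    n_optimal = sum(x$terms$label == "optimal"),
    n_good = sum(x$terms$label == "good"),
    max_auc = if (nrow(x$terms)) max(x$terms$mean_auc) else NA_real_,
    mean_auc = if (nrow(x$terms)) mean(x$terms$mean_auc) else NA_real_,
    n_folds = x$params$n_folds, variant = x$params$variant,
    seed = x$params$seed
  )
}
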