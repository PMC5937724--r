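#' Paired t-test differential expression
#'
#' For each gene, forms the per-pair log2 difference d_i = tumour_i −
#' normal_i and tests mean(d) = 0: `logFC = mean(d)`, `t =
#' mean(d)/(sd(d)/sqrt(n))` with the sample (n−1) standard deviation, and
#' a two-sided p-value from the t distribution on n−1 degrees of freedom.
#' With `moderated = TRUE` the per-gene variances are shrunk toward a
#' pooled prior (empirical-Bayes moderated t, via limma on a
#' pair-blocked design); `logFC` is identical under both.
#'
#' Genes whose paired differences have zero variance are reported with
#' `t = ±Inf, p = 0` when `logFC != 0`, and `t = 0, p = 1` when all
#' differences are zero (a warning gives the count).
#'
#' @param expr tibble: first column `gene`, then sample columns (imputed
#'   and normalised).
#' @param samples sample sheet: columns `sample`, `pair`, `condition`
#'   (`tumor`/`normal`); every pair must occur exactly twice, once per
#'   condition.
#' @param moderated use the empirical-Bayes moderated t instead of the
#'   ordinary paired t.
#' @return Tibble: `gene`, `logFC`, `t`, `df`, `p_value`.
#' @export
paired_t_test <- function(expr, samples, moderated = FALSE) {
  x <- as_expr_matrix(expr)
  if (anyNA(x)) abort("expression matrix contains missing values; impute first")
  samples <- as_tibble(samples)
  samples <- samples[samples$sample %in% colnames(x), ]
  counts <- table(samples$pair, samples$condition)
  if (!all(dim(counts) == c(length(unique(samples$pair)), 2)) ||
      !all(counts == 1)) {
    abort("unpaired design: every pair needs exactly one tumor and one normal sample")
  }
  pairs <- sort(unique(samples$pair))
  n <- length(pairs)
  if (n < 2) abort("need at least 2 complete pairs")
  tum <- samples$sample[match(paste(pairs, "tumor"),
                              paste(samples$pair, samples$condition))]
  nor <- samples$sample[match(paste(pairs, "normal"),
                              paste(samples$pair, samples$condition))]
  d <- x[, tum, drop = FALSE] - x[, nor, drop = FALSE]
  logfc <- rowMeans(d)
  if (moderated) {
    ord <- c(tum, nor)
    design <- stats::model.matrix(
      ~ 0 + factor(rep(pairs, 2)) + rep(c(1, 0), each = n))
    colnames(design) <- c(pairs, "tumor")
    fit <- limma::eBayes(limma::lmFit(x[, ord, drop = FALSE], design))
    i <- match(rownames(x), rownames(fit$coefficients))
    return(tibble(gene = rownames(x),
                  logFC = unname(fit$coefficients[i, "tumor"]),
                  t = unname(fit$t[i, "tumor"]),
                  df = unname(fit$df.total[i]),
                  p_value = unname(fit$p.value[i, "tumor"])))
  }
  s <- apply(d, 1, sd)
  tstat <- logfc / (s / sqrt(n))
  p <- 2 * pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  zero_var <- s == 0
  if (any(zero_var)) {
    warn(sprintf("%d gene(s) with zero variance of paired differences",
                 sum(zero_var)))
    tstat[zero_var] <- sign(logfc[zero_var]) * Inf
    p[zero_var] <- ifelse(logfc[zero_var] != 0, 0, 1)
    tstat[zero_var & logfc == 0] <- 0
  }
  tibble(gene = rownames(x), logFC = unname(logfc), t = unname(tstat),
         df = n - 1, p_value = unname(p))
}

#' Benjamini–Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment: with p-values sorted ascending,
#' q_(i) = min over j >= i of min(1, p_(j) * m / j), returned in the
#' input order. Monotone and permutation-invariant.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values (FDR) in the original order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    abort("p-values must be numeric in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' `call_degs()` runs the paired test, appends the BH FDR and a `passes`
#' flag for the joint criterion `fdr < fdr_max` and `|logFC| >
#' min_abs_logfc` (both strict). `filter_degs()` subsets any table with
#' an `fdr` column and either a signed `logFC` or an `abs_logFC` column
#' to the passing records, sorted by FDR ascending.
#'
#' @inheritParams paired_t_test
#' @param fdr_max strict FDR upper bound (default 0.001).
#' @param min_abs_logfc strict |logFC| lower bound (default 2, log2
#'   units).
#' @return `call_degs()`: the full per-gene tibble with `fdr` and
#'   `passes`; `filter_degs()`: the passing rows sorted by `fdr`.
#' @export
call_degs <- function(expr, samples, fdr_max = 0.001, min_abs_logfc = 2,
                      moderated = FALSE) {
  paired_t_test(expr, samples, moderated = moderated) %>%
    mutate(fdr = bh_adjust(.data$p_value),
           passes = .data$fdr < fdr_max & abs(.data$logFC) > min_abs_logfc)
}

#' @rdname call_degs
#' @param records data frame with columns `fdr` and `logFC` (signed) or
#'   `abs_logFC`.
#' @export
filter_degs <- function(records, fdr_max = 0.001, min_abs_logfc = 2) {
  stopifnot("fdr" %in% names(records))
  alf <- if ("logFC" %in% names(records)) abs(records$logFC)
         else if ("abs_logFC" %in% names(records)) records$abs_logFC
         else abort("need a logFC or abs_logFC column")
  as_tibble(records[records$fdr < fdr_max & alf > min_abs_logfc, ]) %>%
    arrange(.data$fdr)
}
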