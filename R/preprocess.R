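#' Impute missing expression values by k nearest neighbours
#'
#' Each missing entry of gene *g* at sample *s* is replaced by the mean of
#' the values at *s* of the `k` nearest genes (root-mean-square Euclidean
#' distance over the samples observed in both rows) among genes observed
#' at *s*. Observed entries are never altered. Entries equal to 0 are
#' treated as missing by default, the usual convention for absent signal
#' in log2 microarray intensities.
#'
#' @param expr tibble: first column `gene`, then numeric sample columns.
#' @param k number of neighbours (default 10, the standard choice for
#'   expression-array kNN imputation).
#' @param zero_as_missing convert exact zeros to `NA` before imputing.
#' @return The imputed tibble; no missing values remain.
#' @export
impute_knn <- function(expr, k = 10, zero_as_missing = TRUE) {
  stopifnot(k >= 1)
  x <- as_expr_matrix(expr)
  if (zero_as_missing) x[x == 0] <- NA_real_
  miss <- is.na(x)
  if (!any(miss)) return(expr_as_tibble(x, names(expr)[1]))
  all_missing <- rownames(x)[rowSums(!miss) == 0]
  if (length(all_missing)) {
    abort(sprintf("gene(s) with no observed values: %s",
                  paste(all_missing, collapse = ", ")))
  }
  out <- x
  fallback <- character(0)
  for (g in which(rowSums(miss) > 0)) {
    xg <- x[g, ]
    # RMS distance over shared observed samples, comparable across
    # neighbours with different missingness patterns
    shared <- sweep(!miss, 2, !miss[g, ], "&")
    d2 <- rowSums((x - matrix(xg, nrow(x), ncol(x), byrow = TRUE))^2 *
                    shared, na.rm = TRUE)
    n_sh <- rowSums(shared)
    d <- ifelse(n_sh > 0, sqrt(d2 / n_sh), Inf)
    d[g] <- Inf
    ord <- order(d)  # stable: ties broken by row index
    for (s in which(miss[g, ])) {
      cand <- ord[!miss[ord, s] & is.finite(d[ord])]
      if (length(cand) == 0) {
        out[g, s] <- mean(xg, na.rm = TRUE)
        fallback <- c(fallback, rownames(x)[g])
      } else {
        nn <- cand[seq_len(min(k, length(cand)))]
        out[g, s] <- mean(x[nn, s])
      }
    }
  }
  if (length(fallback)) {
    warn(sprintf("no neighbour observed for %d entr%s; used row means (genes: %s)",
                 length(fallback), if (length(fallback) == 1) "y" else "ies",
                 paste(unique(fallback), collapse = ", ")))
  }
  expr_as_tibble(out, names(expr)[1])
}

#' Quantile-normalise an expression matrix
#'
#' Forces every sample column to the same value distribution: each
#' column's sorted values are replaced by the across-column mean of sorted
#' values, reassigned in the column's original rank order (ties receive
#' the mean of the reference values at the tied ranks). Idempotent, and a
#' no-op on a single column.
#'
#' @param expr tibble: first column `gene`, then numeric sample columns,
#'   no missing values.
#' @return The normalised tibble.
#' @export
quantile_normalize <- function(expr) {
  x <- as_expr_matrix(expr)
  if (anyNA(x)) {
    abort("quantile_normalize requires a complete matrix; impute first")
  }
  xn <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(xn) <- dimnames(x)
  expr_as_tibble(xn, names(expr)[1])
}

#' Collapse probe-level rows to gene symbols
#'
#' Maps row IDs through a probe-to-gene table and merges probes sharing a
#' gene symbol. Probes absent from the map are dropped (with a message
#' giving the count). The merge is order-independent for `"mean"` and
#' `"median"`; `"maxmean"` keeps the single probe with the highest mean
#' expression.
#'
#' @param expr tibble: first column = probe IDs, then sample columns.
#' @param probe_map data frame with columns `probe`, `gene`.
#' @param method collapse rule: `"mean"` (default), `"median"` or
#'   `"maxmean"`.
#' @return Tibble with first column `gene` (unique symbols).
#' @export
collapse_probes <- function(expr, probe_map, method = c("mean", "median",
                                                        "maxmean")) {
  method <- match.arg(method)
  stopifnot(all(c("probe", "gene") %in% names(probe_map)))
  x <- as_expr_matrix(expr)
  pm <- probe_map[probe_map$probe %in% rownames(x), ]
  if (nrow(pm) == 0) abort("probe map shares no probes with the matrix")
  dropped <- nrow(x) - length(unique(pm$probe))
  if (dropped > 0) {
    inform(sprintf("dropping %d unmapped probe(s)", dropped))
  }
  x <- x[pm$probe, , drop = FALSE]
  groups <- split(seq_len(nrow(pm)), pm$gene)
  collapsed <- t(vapply(groups, function(rows) {
    sub <- x[rows, , drop = FALSE]
    switch(method,
      mean = colMeans(sub),
      median = apply(sub, 2, stats::median),
      maxmean = sub[which.max(rowMeans(sub)), ]
    )
  }, numeric(ncol(x))))
  rownames(collapsed) <- names(groups)
  expr_as_tibble(collapsed[order(rownames(collapsed)), , drop = FALSE])
}
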