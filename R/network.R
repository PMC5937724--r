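#' Spearman correlation matrix over selected genes
#'
#' Rank (midrank for ties) correlation of expression profiles across all
#' samples pooled — the co-expression measure underlying the network.
#' A gene with constant expression has no defined correlation; its
#' entries are set to 0 with a warning (diagonal stays 1).
#'
#' @param expr tibble: first column `gene`, then sample columns (>= 3
#'   samples).
#' @param genes gene IDs to correlate; default all rows.
#' @return Symmetric correlation matrix in `[-1, 1]`, unit diagonal.
#' @export
spearman_matrix <- function(expr, genes = NULL) {
  x <- as_expr_matrix(expr)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(x))
    if (length(missing)) {
      abort(sprintf("genes not in matrix: %s", paste(missing, collapse = ", ")))
    }
    x <- x[genes, , drop = FALSE]
  }
  if (ncol(x) < 3) abort("need at least 3 samples for rank correlation")
  rho <- suppressWarnings(cor(t(x), method = "spearman"))
  if (anyNA(rho)) {
    warn("constant expression vector(s): undefined correlations set to 0")
    rho[is.na(rho)] <- 0
    diag(rho) <- 1
  }
  rho
}

#' Build the differential co-expression network
#'
#' Nodes are the differentially expressed genes; the weight of edge
#' (i, j) is `|rho_ij|`, the absolute Spearman correlation of the two
#' expression profiles. With `min_weight = 0` the network is the complete
#' weighted graph; with `min_weight > 0` edges below the threshold are
#' zeroed (nodes are kept even if isolated).
#'
#' @param corr symmetric correlation matrix with unit diagonal (from
#'   [spearman_matrix()]).
#' @param min_weight minimum retained edge weight (0 = keep all).
#' @return An object of class `dcn`: list with `weights` (symmetric
#'   matrix, zero diagonal, entries in `[0, 1]`), `nodes`, `min_weight`.
#' @export
build_dcn <- function(corr, min_weight = 0) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (max(abs(corr - t(corr))) > 1e-8) abort("correlation matrix not symmetric")
  w <- abs(corr)
  diag(w) <- 0
  if (min_weight > 0) w[w < min_weight] <- 0
  structure(list(weights = w, nodes = rownames(corr),
                 min_weight = min_weight), class = "dcn")
}

#' @export
print.dcn <- function(x, ...) {
  cat(sprintf("<dcn> %d nodes, %d edges (min_weight = %g)\n",
              length(x$nodes), nrow(dcn_edges(x)), x$min_weight))
  invisible(x)
}

#' Edge list of a co-expression network
#'
#' One row per unordered node pair with non-zero (or, when `min_weight =
#' 0`, any) weight; `gene_a < gene_b` lexicographically. Suitable for
#' import into network visualisation tools.
#'
#' @param network a [build_dcn()] object.
#' @return Tibble: `gene_a`, `gene_b`, `weight`.
#' @export
dcn_edges <- function(network) {
  stopifnot(inherits(network, "dcn"))
  w <- network$weights
  nodes <- network$nodes
  idx <- which(upper.tri(w), arr.ind = TRUE)
  out <- tibble(
    gene_a = pmin(nodes[idx[, 1]], nodes[idx[, 2]]),
    gene_b = pmax(nodes[idx[, 1]], nodes[idx[, 2]]),
    weight = w[idx]
  )
  if (network$min_weight > 0) {
    out <- out[out$weight >= network$min_weight, ]
  }
  arrange(out, .data$gene_a, .data$gene_b)
}

#' @rdname dcn_edges
#' @param x a `dcn`.
#' @param ... unused.
#' @export
tidy.dcn <- function(x, ...) dcn_edges(x)

#' Weight-bin summary of network edges
#'
#' Counts retained edges per weight bin. The first bin is closed at its
#' lower edge; subsequent bins are lower-exclusive / upper-inclusive, so
#' the default edges reproduce the bins 0.4–0.5, >0.5–0.6, ..., >0.9–1.0.
#' Percentages are 100 * count / (edges inside the bins), reported to two
#' decimals; edges below the first or above the last edge are reported as
#' separate `underflow` / `overflow` rows with `NA` percentage.
#'
#' @param network a `dcn`, or a numeric vector of edge weights.
#' @param bin_edges ascending numeric bin boundaries.
#' @return Tibble: `bin` (label), `lower`, `upper`, `count`, `percent`.
#' @export
weight_histogram <- function(network, bin_edges = seq(0.4, 1, by = 0.1)) {
  if (inherits(network, "dcn")) {
    e <- dcn_edges(network)
    w <- e$weight
    if (network$min_weight > 0) w <- w[w >= network$min_weight]
  } else {
    w <- as.numeric(network)
  }
  stopifnot(length(bin_edges) >= 2, !is.unsorted(bin_edges, strictly = TRUE))
  k <- length(bin_edges) - 1
  lab <- c(sprintf("%g-%g", bin_edges[1], bin_edges[2]),
           if (k > 1) sprintf(">%g-%g", bin_edges[-c(1, k + 1)],
                              bin_edges[-(1:2)]))
  counts <- vapply(seq_len(k), function(i) {
    if (i == 1) sum(w >= bin_edges[1] & w <= bin_edges[2])
    else sum(w > bin_edges[i] & w <= bin_edges[i + 1])
  }, integer(1))
  total <- sum(counts)
  if (total == 0) {
    warn("no edges fall inside the bins; percentages reported as 0")
    pct <- rep(0, k)
  } else {
    pct <- round(100 * counts / total, 2)
  }
  out <- tibble(bin = lab, lower = bin_edges[-(k + 1)],
                upper = bin_edges[-1], count = counts, percent = pct)
  under <- sum(w < bin_edges[1])
  over <- sum(w > bin_edges[k + 1])
  if (under > 0 || over > 0) {
    out <- bind_rows(out, tibble(
      bin = c("underflow", "overflow"),
      lower = c(-Inf, bin_edges[k + 1]), upper = c(bin_edges[1], Inf),
      count = c(under, over), percent = NA_real_))
    out <- out[out$count > 0 | !out$bin %in% c("underflow", "overflow"), ]
  }
  out
}
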