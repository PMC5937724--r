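#' Gene-set catalogs
#'
#' A `go_catalog` holds named gene sets (GO-style terms) as a long
#' membership table plus the annotation universe. Memberships are sets:
#' duplicates collapse on construction.
#'
#' @param sets data frame with columns `term`, `gene` and optionally
#'   `name` (term description).
#' @param universe character vector of gene IDs; defaults to the union of
#'   all member genes. The universe is what the multifunctionality score's
#'   `N` refers to, so filters keep it fixed unless told otherwise.
#' @return An object of class `go_catalog` with elements `sets` (tibble:
#'   `term`, `name`, `gene`) and `universe`.
#' @export
#' @examples
#' cat <- go_catalog(data.frame(term = c("A", "A", "B"),
#'                              gene = c("g1", "g2", "g2")))
#' n_terms(cat)
go_catalog <- function(sets, universe = NULL) {
  stopifnot(is.data.frame(sets), all(c("term", "gene") %in% names(sets)))
  if (!"name" %in% names(sets)) sets$name <- ""
  sets <- as_tibble(sets)[, c("term", "name", "gene")] %>%
    distinct(.data$term, .data$gene, .keep_all = TRUE)
  if (nrow(sets) == 0) abort("catalog has no memberships")
  members <- unique(sets$gene)
  universe <- if (is.null(universe)) members else unique(universe)
  if (!all(members %in% universe)) {
    abort("every annotated gene must be in the universe")
  }
  structure(list(sets = sets, universe = universe), class = "go_catalog")
}

#' @rdname go_catalog
#' @param x a `go_catalog`.
#' @export
n_terms <- function(x) length(unique(x$sets$term))

#' @export
print.go_catalog <- function(x, ...) {
  cat(sprintf("<go_catalog> %d terms, %d annotated genes, universe %d\n",
              n_terms(x), length(unique(x$sets$gene)), length(x$universe)))
  invisible(x)
}

#' Per-term summary of a catalog
#'
#' @param x a `go_catalog`.
#' @param ... unused.
#' @return Tibble with one row per term: `term`, `name`, `size`, and
#'   `n_degs` if a DEG-overlap filter has annotated it.
#' @export
tidy.go_catalog <- function(x, ...) {
  out <- x$sets %>%
    group_by(.data$term, .data$name) %>%
    summarise(size = dplyr::n(), .groups = "drop") %>%
    arrange(.data$term)
  if (!is.null(attr(x, "deg_overlap"))) {
    out <- left_join(out, attr(x, "deg_overlap"), by = "term")
  }
  out
}

#' Read and write gene-set files
#'
#' `read_gmt()` parses the tab-separated GMT dialect (`term ID<TAB>
#' description<TAB>gene1<TAB>gene2...`, one set per line).
#' `read_gene_pairs()` reads a two-column TSV with header `gene`, `term`
#' (either column order). `write_gmt()` writes the GMT dialect back.
#'
#' @param path file path.
#' @return A [go_catalog()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("empty gene-set file: %s", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3)
  if (length(bad)) {
    abort(sprintf("malformed GMT line %d in %s: need id, description and >=1 gene",
                  bad[1], path))
  }
  sets <- purrr::map_dfr(parts, function(p) {
    tibble(term = p[1], name = p[2], gene = unique(p[-(1:2)]))
  })
  go_catalog(sets)
}

#' @rdname read_gmt
#' @export
read_gene_pairs <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("gene", "term") %in% names(tab))) {
    abort(sprintf("two-column gene-set file %s must have columns gene, term",
                  path))
  }
  if (nrow(tab) == 0) abort(sprintf("empty gene-set file: %s", path))
  go_catalog(tab[, c("term", "gene")])
}

#' @rdname read_gmt
#' @param catalog a [go_catalog()].
#' @export
write_gmt <- function(catalog, path) {
  stopifnot(inherits(catalog, "go_catalog"))
  by_term <- split(catalog$sets$gene, catalog$sets$term)
  nm <- catalog$sets %>% distinct(.data$term, .data$name)
  names_of <- setNames(nm$name, nm$term)
  lines <- vapply(names(by_term), function(tid) {
    paste(c(tid, names_of[[tid]], by_term[[tid]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Filter terms by annotation size
#'
#' Keeps terms whose gene-set size lies in `[min_size, max_size]`
#' (inclusive at both ends: a 20-gene and a 1000-gene term both pass the
#' default 20--1000 window). The surviving terms are the "seed" terms.
#'
#' @param catalog a [go_catalog()].
#' @param min_size,max_size inclusive size bounds.
#' @param recompute_universe if `TRUE`, shrink the universe to the genes
#'   annotated by the retained terms; default keeps the original universe
#'   (so the multifunctionality `N` is unchanged by filtering).
#' @return A filtered [go_catalog()].
#' @export
filter_set_size <- function(catalog, min_size = 20, max_size = 1000,
                            recompute_universe = FALSE) {
  stopifnot(inherits(catalog, "go_catalog"), min_size <= max_size)
  sizes <- table(catalog$sets$term)
  keep <- names(sizes)[sizes >= min_size & sizes <= max_size]
  sets <- catalog$sets[catalog$sets$term %in% keep, ]
  if (nrow(sets) == 0) {
    warn("no terms pass the size filter")
    sets <- catalog$sets[0, ]
  }
  out <- structure(list(
    sets = sets,
    universe = if (recompute_universe) unique(sets$gene) else
      catalog$universe
  ), class = "go_catalog")
  attr(out, "deg_overlap") <- attr(catalog, "deg_overlap")
  out
}

#' Filter terms by overlap with the differentially expressed genes
#'
#' Keeps terms annotating at least `min_overlap` of the supplied DEG IDs
#' (inclusive). Retained terms carry their overlap count, available from
#' [tidy.go_catalog()] as `n_degs`. The survivors are the "informative"
#' terms actually scored by the guilt-by-association step.
#'
#' @param catalog a [go_catalog()].
#' @param degs character vector of DEG IDs (non-empty).
#' @param min_overlap minimum DEG overlap, inclusive.
#' @return A filtered [go_catalog()] with a `deg_overlap` attribute.
#' @export
filter_deg_overlap <- function(catalog, degs, min_overlap = 20) {
  stopifnot(inherits(catalog, "go_catalog"))
  if (length(degs) == 0) abort("degs must be non-empty")
  if (min_overlap > length(degs)) {
    warn("min_overlap exceeds the number of DEGs: every term will be removed")
  }
  ov <- catalog$sets %>%
    group_by(.data$term) %>%
    summarise(n_degs = sum(.data$gene %in% degs), .groups = "drop")
  keep <- ov$term[ov$n_degs >= min_overlap]
  sets <- catalog$sets[catalog$sets$term %in% keep, ]
  out <- structure(list(sets = sets, universe = catalog$universe),
                   class = "go_catalog")
  attr(out, "deg_overlap") <- ov[ov$term %in% keep, ]
  out
}
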