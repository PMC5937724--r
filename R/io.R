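#' Read expression, sample-sheet and probe-map tables
#'
#' The expression TSV has a first column `gene` (or probe IDs before
#' collapse) and one numeric column per sample; missing values are `NA`.
#' The sample sheet has columns `sample`, `pair`, `condition` with
#' `condition` in `{tumor, normal}`. The probe map has columns `probe`,
#' `gene`.
#'
#' @param path file path.
#' @param zero_as_missing treat entries equal to 0 as missing (the usual
#'   convention for absent probe signal on the log2 scale). Default `TRUE`.
#' @return A tibble.
#' @export
read_expression <- function(path, zero_as_missing = TRUE) {
  expr <- readr::read_tsv(path, progress = FALSE,
                          col_types = readr::cols(
                            gene = readr::col_character(),
                            .default = readr::col_double()))
  if (names(expr)[1] != "gene") {
    abort("expression table must have a first column named 'gene'")
  }
  if (zero_as_missing) {
    expr <- dplyr::mutate(expr, dplyr::across(
      -1, ~ dplyr::if_else(.x == 0, NA_real_, .x)))
  }
  expr
}

#' @rdname read_expression
#' @export
read_sample_sheet <- function(path) {
  ss <- readr::read_tsv(path, progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  need <- c("sample", "pair", "condition")
  if (!all(need %in% names(ss))) {
    abort("sample sheet must have columns sample, pair, condition")
  }
  if (!all(ss$condition %in% c("tumor", "normal"))) {
    abort("condition must be 'tumor' or 'normal'")
  }
  ss[, need]
}

#' @rdname read_expression
#' @export
read_probe_map <- function(path) {
  pm <- readr::read_tsv(path, progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  if (!all(c("probe", "gene") %in% names(pm))) {
    abort("probe map must have columns probe, gene")
  }
  pm[, c("probe", "gene")]
}
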