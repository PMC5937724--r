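# Shared fixtures and independent oracles for the test suite.

# Small, fast simulation used by most module tests.
small_config <- function(seed = 42L, ...) {
  defaults <- list(n_genes = 120, n_pairs = 8, n_de = 20, effect_size = 3,
                   module_sizes = c(6, 6), module_strength = 0.9,
                   noise_sd = 0.5, missing_rate = 0.02, n_terms = 12,
                   term_size_range = c(8, 20), frac_planted = 0.25,
                   seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# The default study conditions (paper-scale paired design).
default_config <- function(seed = 1L, ...) sim_config(seed = seed, ...)

# Independent AUROC oracle: exhaustive pair counting.
auroc_brute <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

# Tiny expression tibble from a plain matrix.
expr_tbl <- function(m, genes = NULL) {
  if (is.null(rownames(m))) {
    rownames(m) <- genes %||% paste0("g", seq_len(nrow(m)))
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  tibble::as_tibble(cbind(
    tibble::tibble(gene = rownames(m)),
    tibble::as_tibble(m, .name_repair = "minimal")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Paired sample sheet for columns named <pair>_T / <pair>_N.
paired_sheet <- function(pairs) {
  tibble::tibble(
    sample = c(rbind(paste0(pairs, "_T"), paste0(pairs, "_N"))),
    pair = rep(pairs, each = 2),
    condition = rep(c("tumor", "normal"), length(pairs))
  )
}

# Complete random weighted network on n nodes, weights in (lo, hi).
random_dcn <- function(n, seed, lo = 0.1, hi = 1) {
  withr::with_seed(seed, {
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- runif(n * (n - 1) / 2, lo, hi)
    w <- w + t(w)
    rho <- w
    diag(rho) <- 1
    dimnames(rho) <- list(paste0("n", 1:n), paste0("n", 1:n))
    build_dcn(rho)
  })
}

extdata <- function(f) system.file("extdata", f, package = "gbanet")
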