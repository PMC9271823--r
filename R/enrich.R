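## Hypergeometric over-representation of gene lists against a GMT
## collection, with BH correction.

#' Hypergeometric over-representation analysis
#'
#' Each set is intersected with the universe; the p-value is the exact
#' upper-tail hypergeometric probability `P(X >= k)` of drawing `k` or more
#' set genes in a query of size `n` from a universe of size `N` containing
#' `K` set genes. BH adjustment runs across the sets with overlap at least
#' `min_overlap`; results are sorted by p-value.
#'
#' @param query Character vector of query genes (genes outside the universe
#'   are dropped with a warning).
#' @param universe Character vector of background genes.
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param min_overlap Minimum overlap for a set to be tested.
#' @return Data frame: `set`, `k` (overlap), `K` (set size in universe),
#'   `n` (query size), `N` (universe size), `p_value`, `p_adj`.
#' @export
run_ora <- function(query, universe, sets, min_overlap = 2) {
  universe <- unique(universe)
  .assert(length(universe) > 0, "empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query genes outside the universe dropped")
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    K <- length(s)
    k <- length(intersect(query, s))
    data.frame(set = nm, k = k, K = K, n = n, N = N,
               p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$k >= min_overlap, , drop = FALSE]
  if (nrow(out)) {
    out$p_adj <- p.adjust(out$p_value, "BH")
    out <- out[order(out$p_value), , drop = FALSE]
  } else out$p_adj <- numeric(0)
  rownames(out) <- NULL
  out
}

#' Build an enrichment query from marker records
#'
#' Genes of the given cluster with strictly positive `avg_logFC` and
#' `p_adj` strictly below `p_cut`.
#'
#' @param markers Marker table from [find_markers()].
#' @param cluster Cluster (or cell-type) identifier.
#' @param p_cut Adjusted p-value cutoff.
#' @return Character vector of gene identifiers (possibly empty, with a
#'   warning).
#' @export
build_deg_query <- function(markers, cluster, p_cut = 0.01) {
  .assert(nrow(markers) > 0, "empty marker table")
  sel <- markers$cluster == cluster & markers$avg_logFC > 0 &
    markers$p_adj < p_cut
  out <- markers$gene[sel]
  if (length(out) == 0) warning("no DEG passes the cuts for cluster ", cluster)
  out
}

#' Generate a synthetic gene-set collection
#'
#' Random sets drawn from a universe, plus one set enriched in a supplied
#' gene list; used to exercise the over-representation machinery.
#'
#' @param universe Character vector of genes.
#' @param n_sets Number of random sets.
#' @param set_size Size of each random set.
#' @param enriched Optional genes forming a planted "true" set (named
#'   `planted_program`).
#' @param seed Integer seed.
#' @return Named list of gene sets.
#' @export
simulate_gene_sets <- function(universe, n_sets = 20, set_size = 50,
                               enriched = NULL, seed = 1L) {
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i)
    sample(universe, min(set_size, length(universe))))
  names(sets) <- sprintf("random_set_%02d", seq_len(n_sets))
  if (!is.null(enriched) && length(enriched)) {
    sets$planted_program <- unique(c(
      enriched, sample(universe, min(set_size, length(universe)))))
  }
  sets
}
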