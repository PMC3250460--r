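# Hypergeometric over-representation of gene sets (GMT collections).

#' Gene-set over-representation analysis
#'
#' For each set, p = P(X >= k) with X ~ Hypergeometric(N = |universe|,
#' K = set size within the universe, n = query size); BH adjustment across
#' all tested sets.  Query genes outside the universe are dropped and
#' counted; sets with no member in the universe are excluded.
#'
#' @param query_genes character vector of query gene ids.
#' @param gene_sets named list of character vectors (see [read_gmt()]).
#' @param universe character vector of all testable gene ids.
#' @param fdr FDR threshold for the `significant` flag.
#' @return data.frame sorted by p with columns `set`, `K`, `n`, `k`, `p`,
#'   `q`, `significant`, `overlap_genes`; attribute `n_query_dropped`.
#' @export
enrich <- function(query_genes, gene_sets, universe, fdr = 0.05) {
  if (!length(query_genes)) stop("empty query")
  if (!length(gene_sets)) stop("empty gene-set collection")
  universe <- unique(as.character(universe))
  query <- unique(as.character(query_genes))
  dropped <- sum(!(query %in% universe))
  query <- intersect(query, universe)
  if (!length(query)) stop("no query gene is in the universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(gene_sets[[nm]], universe)
    K <- length(members)
    if (K == 0) return(NULL)
    ov <- intersect(query, members)
    k <- length(ov)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, K = K, n = n, k = k, p = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("no gene set overlaps the universe")
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$q < fdr
  res <- res[order(res$p, res$set), c("set", "K", "n", "k", "p", "q",
                                      "significant", "overlap_genes")]
  rownames(res) <- NULL
  attr(res, "n_query_dropped") <- dropped
  res
}
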