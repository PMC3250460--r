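# Cross-dataset reproducibility of differential gene lists: POG overlap,
# direction consistency under an exact binomial null, solely-detected
# direction recovery, and comparison of hypermethylated proportions.

#' Exact one-sided binomial tail for direction agreement
#'
#' P(X >= n_consistent) for X ~ Binomial(k, 1/2): the chance that at least
#' this many of k shared genes agree in direction if agreement were a coin
#' flip.  Computed by `pbinom` (log-space internally), exact for all k.
#'
#' @param n_consistent number of agreeing genes.
#' @param k number of shared genes.
#' @return list with `p` (may underflow to 0 for extreme k) and `log10_p`.
#' @export
binomial_direction_p <- function(n_consistent, k) {
  if (k == 0) return(list(p = NA_real_, log10_p = NA_real_))
  if (n_consistent > k) stop("n_consistent cannot exceed k")
  p <- stats::pbinom(n_consistent - 1, k, 0.5, lower.tail = FALSE)
  lp <- stats::pbinom(n_consistent - 1, k, 0.5, lower.tail = FALSE,
                      log.p = TRUE) / log(10)
  list(p = p, log10_p = lp)
}

#' Percentage of overlapping genes (POG) between two significant lists
#'
#' For lists of lengths L1 and L2 sharing k genes, POG12 = k/L1 and
#' POG21 = k/L2.  When directions are supplied, the direction consistency
#' of the shared genes and its exact binomial p value (null probability
#' 1/2) are included.
#'
#' @param list1,list2 character vectors of gene ids (each unique within
#'   its list), or data.frames with columns `gene_id` and `direction`.
#' @return an `overlap_report` list with fields `L1`, `L2`, `k`, `pog12`,
#'   `pog21`, `shared_genes`, and (with directions) `n_consistent`,
#'   `consistency`, `binomial_p`, `binomial_log10_p`.  POG from an empty
#'   list is `NA` (not applicable); `k` is always computed.
#' @export
pog <- function(list1, list2) {
  get_ids <- function(x) if (is.data.frame(x)) as.character(x$gene_id)
                         else as.character(x)
  ids1 <- get_ids(list1); ids2 <- get_ids(list2)
  if (anyDuplicated(ids1) || anyDuplicated(ids2))
    stop("gene ids must be unique within each list")
  shared <- intersect(ids1, ids2)
  L1 <- length(ids1); L2 <- length(ids2); k <- length(shared)
  rep <- list(L1 = L1, L2 = L2, k = k,
              pog12 = if (L1 > 0) k / L1 else NA_real_,
              pog21 = if (L2 > 0) k / L2 else NA_real_,
              shared_genes = shared)
  if (is.data.frame(list1) && is.data.frame(list2) &&
      !is.null(list1$direction) && !is.null(list2$direction) && k > 0) {
    d1 <- list1$direction[match(shared, ids1)]
    d2 <- list2$direction[match(shared, ids2)]
    cons <- direction_consistency(d1, d2)
    rep <- c(rep, cons)
  }
  structure(rep, class = "overlap_report")
}

#' Direction consistency of shared genes with an exact binomial null
#'
#' @param directions1,directions2 direction labels of the same shared
#'   genes in the two datasets (equal length, aligned).
#' @return list with `n_consistent`, `consistency`, `binomial_p`,
#'   `binomial_log10_p`; consistency is `NA` (not applicable) when there
#'   are no shared genes.
#' @export
direction_consistency <- function(directions1, directions2) {
  if (length(directions1) != length(directions2))
    stop("direction vectors must align")
  k <- length(directions1)
  if (k == 0)
    return(list(n_consistent = 0L, consistency = NA_real_,
                binomial_p = NA_real_, binomial_log10_p = NA_real_))
  if (any(is.na(directions1)) || any(is.na(directions2)))
    stop("every shared gene needs a direction in both lists")
  n_cons <- sum(directions1 == directions2)
  bp <- binomial_direction_p(n_cons, k)
  list(n_consistent = n_cons, consistency = n_cons / k,
       binomial_p = bp$p, binomial_log10_p = bp$log10_p)
}

#' Direction recovery of genes detected in only one dataset
#'
#' Genes significant solely in dataset A are looked up in dataset B's
#' full, unthresholded results; the fraction whose effect sign in B
#' matches their direction in A is reported with an exact binomial p.
#' Genes absent from B, or with exactly zero effect in B, are excluded
#' and counted.
#'
#' @param a_only data.frame of A-only significant genes with `gene_id`
#'   and `direction`.
#' @param full_b data.frame of B's full results with `gene_id` and
#'   `effect` (sign defines B's direction) and optionally `direction`.
#' @param positive_direction the direction label meaning a positive
#'   effect (`"hyper"` for methylation, `"up"` for expression).
#' @return list with `n_solely`, `n_evaluated`, `n_excluded`,
#'   `n_consistent`, `consistency`, `binomial_p`, `binomial_log10_p`.
#' @export
solely_detected_consistency <- function(a_only, full_b,
                                        positive_direction = c("hyper", "up")) {
  idx <- match(a_only$gene_id, full_b$gene_id)
  eff_b <- full_b$effect[idx]
  usable <- !is.na(eff_b) & eff_b != 0
  n_solely <- nrow(a_only)
  n_excl <- sum(!usable)
  if (!any(usable))
    return(list(n_solely = n_solely, n_evaluated = 0L, n_excluded = n_excl,
                n_consistent = 0L, consistency = NA_real_,
                binomial_p = NA_real_, binomial_log10_p = NA_real_))
  dir_a_pos <- a_only$direction[usable] %in% positive_direction
  cons <- dir_a_pos == (eff_b[usable] > 0)
  n_cons <- sum(cons)
  k <- sum(usable)
  bp <- binomial_direction_p(n_cons, k)
  list(n_solely = n_solely, n_evaluated = k, n_excluded = n_excl,
       n_consistent = n_cons, consistency = n_cons / k,
       binomial_p = bp$p, binomial_log10_p = bp$log10_p)
}

#' Full overlap report between two differential result tables
#'
#' Combines [pog()] on the significant lists, shared-gene direction
#' consistency, and both solely-detected sections (A-only genes checked
#' in B and vice versa).
#'
#' @param results1,results2 full differential result data.frames with
#'   `gene_id`, `direction`, `effect`, `significant`.
#' @return `overlap_report` list with the overlap fields plus
#'   `solely_1` and `solely_2` sections.
#' @export
overlap_report <- function(results1, results2) {
  sig1 <- results1[results1$significant, , drop = FALSE]
  sig2 <- results2[results2$significant, , drop = FALSE]
  rep <- pog(sig1, sig2)
  only1 <- sig1[!(sig1$gene_id %in% sig2$gene_id), , drop = FALSE]
  only2 <- sig2[!(sig2$gene_id %in% sig1$gene_id), , drop = FALSE]
  rep$solely_1 <- solely_detected_consistency(only1, results2)
  rep$solely_2 <- solely_detected_consistency(only2, results1)
  rep
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("Overlap: L1=%d L2=%d k=%d  POG12=%s POG21=%s\n",
              x$L1, x$L2, x$k, fmt_pct(x$pog12), fmt_pct(x$pog21)))
  if (!is.null(x$consistency))
    cat(sprintf("Shared-gene direction consistency: %d/%d = %s (binomial p = %.3g)\n",
                x$n_consistent, x$k, fmt_pct(x$consistency), x$binomial_p))
  for (nm in c("solely_1", "solely_2")) {
    s <- x[[nm]]
    if (!is.null(s) && s$n_evaluated > 0)
      cat(sprintf("%s: %d/%d same sign in the other dataset = %s (binomial p = %.3g)\n",
                  nm, s$n_consistent, s$n_evaluated, fmt_pct(s$consistency),
                  s$binomial_p))
  }
  invisible(x)
}

# percentages shown with one decimal; raw counts always retained in the
# report objects themselves
fmt_pct <- function(x) if (is.na(x)) "NA" else sprintf("%.1f%%", 100 * x)

#' Compare proportions of hypermethylated genes between two lists
#'
#' Pearson chi-squared test (no continuity correction by default) on the
#' 2x2 table of hyper vs non-hyper counts in two gene lists.
#'
#' @param hyper_a,total_a hypermethylated and total counts in list A.
#' @param hyper_b,total_b counts in list B.
#' @param correct apply Yates continuity correction.
#' @return list with `statistic`, `p`, and the 2x2 `table`.
#' @export
compare_hyper_proportions <- function(hyper_a, total_a, hyper_b, total_b,
                                      correct = FALSE) {
  if (total_a <= 0 || total_b <= 0) stop("totals must be positive")
  if (hyper_a > total_a || hyper_b > total_b)
    stop("hyper count cannot exceed total")
  tab <- matrix(c(hyper_a, total_a - hyper_a,
                  hyper_b, total_b - hyper_b),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("hyper", "other")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate 2x2 table (zero margin)")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), p = unname(ht$p.value), table = tab)
}
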