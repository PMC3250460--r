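# Batch-effect assessment: per-probe one-way ANOVA on batch (or
# laboratory) labels, clustering-based batch purity, and the demonstration
# that comparing tumour batches against one normal set corrupts DM calls.

# Vectorised one-way ANOVA over matrix rows for a factor g.
anova_rows <- function(x, g) {
  g <- factor(g)
  ng <- table(g)
  k <- nlevels(g)
  n <- ncol(x)
  grand <- rowMeans(x)
  gm <- vapply(levels(g), function(l) rowMeans(x[, g == l, drop = FALSE]),
               numeric(nrow(x)))
  gm <- matrix(gm, nrow = nrow(x))   # keep matrix shape for 1-probe input
  ssb <- as.vector((gm - grand)^2 %*% as.vector(ng))
  sst <- rowSums((x - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  dfb <- k - 1
  dfw <- n - k
  f <- (ssb / dfb) / (ssw / dfw)
  p <- stats::pf(f, dfb, dfw, lower.tail = FALSE)
  # zero within-group variance but real between-group separation:
  # infinite F, p -> 0; no variance at all: handled upstream (skipped)
  degen <- ssw == 0 & ssb > 0
  f[degen] <- Inf
  p[degen] <- 0
  exact_null <- ssb == 0
  f[exact_null] <- 0
  p[exact_null] <- 1
  list(f = f, p = p)
}

#' Per-probe batch-effect ANOVA
#'
#' Tests each probe's Beta values for association with a categorical label
#' (experimental batch or collection laboratory) by one-way ANOVA; p
#' values are BH-adjusted across the tested probes, and probes with
#' adjusted q below `fdr` are flagged susceptible to batch effects.
#' Probes with missing values in the used samples, or with zero total
#' variance, are skipped and counted.
#'
#' @param beta Beta matrix, probes x samples.
#' @param sheet sample sheet covering the columns.
#' @param label which sheet column supplies the grouping:
#'   `"batch"` (default) or `"laboratory"`.
#' @param fdr susceptibility threshold on BH-adjusted q (default 0.05).
#' @return a `batch_assessment` list: `table` (probe_id, F, p, q,
#'   susceptible), `susceptible_fraction`, `n_tested`, `n_skipped`,
#'   `label`, `fdr`.
#' @export
probe_batch_anova <- function(beta, sheet, label = c("batch", "laboratory"),
                              fdr = 0.05) {
  label <- match.arg(label)
  sheet <- as.data.frame(sheet)
  validate_sample_sheet(sheet)
  sheet <- sheet[match(colnames(beta), sheet$sample_id), , drop = FALSE]
  if (any(is.na(sheet$sample_id)))
    stop("sample sheet does not cover all matrix columns")
  g <- sheet[[label]]
  if (is.null(g)) stop("sample sheet has no '", label, "' column")
  tab <- table(g)
  if (length(tab) < 2) stop("need >= 2 ", label, " groups")
  small <- names(tab)[tab < 2]
  if (length(small))
    stop("group(s) with < 2 samples: ", paste(small, collapse = ", "))
  complete <- stats::complete.cases(beta)
  x <- beta[complete, , drop = FALSE]
  rv <- rowSums((x - rowMeans(x))^2)
  testable <- rv > 0
  if (!any(testable)) stop("all probes are constant; nothing to test")
  x <- x[testable, , drop = FALSE]
  res <- anova_rows(x, g)
  q <- stats::p.adjust(res$p, method = "BH")
  out <- data.frame(probe_id = rownames(x), F = res$f, p = res$p, q = q,
                    susceptible = q < fdr, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(list(table = out,
                 susceptible_fraction = mean(out$susceptible),
                 n_tested = nrow(out),
                 n_skipped = sum(!complete) + sum(!testable),
                 label = label, fdr = fdr),
            class = "batch_assessment")
}

#' @export
print.batch_assessment <- function(x, ...) {
  cat(sprintf(
    "Batch assessment on '%s': %d probes tested (%d skipped)\n%s susceptible at FDR < %g\n",
    x$label, x$n_tested, x$n_skipped, fmt_pct(x$susceptible_fraction), x$fdr))
  invisible(x)
}

#' Hierarchical-clustering batch purity
#'
#' Clusters samples by the Euclidean distance between their Beta profiles
#' (average linkage by default), cuts the tree into as many clusters as
#' there are batches, and reports whether the partition reproduces the
#' batch labels exactly, plus the adjusted Rand index between partition
#' and labels.
#'
#' @param beta Beta matrix, probes x samples.
#' @param sheet sample sheet covering the columns.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return list with `perfect_split` (logical), `agreement` (adjusted
#'   Rand index in `[-1, 1]`), `clusters`, `batches`, `hclust`; with a
#'   single batch both scores are `NA` (not applicable).
#' @export
batch_purity_clustering <- function(beta, sheet, linkage = "average") {
  sheet <- as.data.frame(sheet)
  validate_sample_sheet(sheet)
  sheet <- sheet[match(colnames(beta), sheet$sample_id), , drop = FALSE]
  if (ncol(beta) < 2) stop("need >= 2 samples to cluster")
  batches <- sheet$batch
  hc <- stats::hclust(stats::dist(t(beta)), method = linkage)
  nb <- length(unique(batches))
  if (nb < 2)
    return(list(perfect_split = NA, agreement = NA_real_,
                clusters = NULL, batches = batches, hclust = hc))
  cl <- stats::cutree(hc, k = nb)
  cross <- table(cl, batches)
  perfect <- all(rowSums(cross > 0) == 1) && all(colSums(cross > 0) == 1)
  ari <- mclust::adjustedRandIndex(cl, batches)
  list(perfect_split = perfect, agreement = ari,
       clusters = cl, batches = batches, hclust = hc)
}

#' Corruption of DM calls by comparing tumour batches to one normal set
#'
#' Calls DM features for tumour batch A vs the shared normals and for
#' tumour batch B vs the same normals (unpaired Welch tests), then scores
#' the direction consistency of the features significant in both
#' comparisons.  With strong opposing batch offsets and no true signal,
#' consistency collapses far below the no-batch-effect regime.
#'
#' @param beta Beta matrix covering all samples involved.
#' @param tumour_a,tumour_b,normal character vectors of sample ids
#'   (mutually disjoint).
#' @param fdr FDR threshold for each DM call (default 0.05).
#' @param annotation optional probe annotation for gene-level calls.
#' @return list with `k` (shared significant features), `n_consistent`,
#'   `consistency` (`NA` when k = 0), `binomial_p`, and the two result
#'   tables.
#' @export
batch_vs_batch_dm_corruption <- function(beta, tumour_a, tumour_b, normal,
                                         fdr = 0.05, annotation = NULL) {
  ids <- list(tumour_a, tumour_b, normal)
  if (length(unique(unlist(ids))) != length(unlist(ids)))
    stop("tumour_a, tumour_b and normal must be disjoint sample sets")
  run <- function(tum) {
    cols <- c(tum, normal)
    sheet <- data.frame(sample_id = cols,
                        group = rep(c("tumour", "normal"),
                                    c(length(tum), length(normal))),
                        batch = "pooled", stringsAsFactors = FALSE)
    dm_ttest(beta[, cols, drop = FALSE], sheet, fdr = fdr,
             annotation = annotation)
  }
  ra <- run(tumour_a)
  rb <- run(tumour_b)
  idcol <- if ("gene_id" %in% names(ra)) "gene_id" else "id"
  sa <- ra[ra$significant, , drop = FALSE]
  sb <- rb[rb$significant, , drop = FALSE]
  shared <- intersect(sa[[idcol]], sb[[idcol]])
  cons <- direction_consistency(sa$direction[match(shared, sa[[idcol]])],
                                sb$direction[match(shared, sb[[idcol]])])
  c(list(k = length(shared)), cons[c("n_consistent", "consistency",
                                     "binomial_p")],
    list(results_a = ra, results_b = rb))
}
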