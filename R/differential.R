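# Differential methylation / expression calling.
#
# Per-feature tests are vectorised over the matrix rows; BH adjustment is
# applied across all tested features of a run.

# Vectorised two-sample Welch t over matrix rows.
welch_rows <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  # identical groups: zero variance and zero difference => no evidence
  degen <- se2 == 0
  p[degen & (m1 == m2)] <- 1
  p[degen & (m1 != m2)] <- 0
  t[degen] <- ifelse(m1[degen] == m2[degen], 0,
                     sign(m1[degen] - m2[degen]) * Inf)
  list(statistic = t, p = p, effect = m1 - m2)
}

# Vectorised paired t over matrix rows of differences.
paired_rows <- function(d) {
  n <- ncol(d)
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  p <- 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE)
  degen <- s == 0
  p[degen & m == 0] <- 1
  p[degen & m != 0] <- 0
  t[degen] <- ifelse(m[degen] == 0, 0, sign(m[degen]) * Inf)
  list(statistic = t, p = p, effect = m)
}

#' Call differentially methylated features with a t-test
#'
#' Tests each row of the Beta matrix for a tumour vs normal difference
#' (Welch two-sample t by default; paired t on patient-matched differences
#' when `paired = TRUE`), adjusts p values across all tested features with
#' the Benjamini-Hochberg procedure, and attaches the effect size
#' \eqn{\Delta\beta = \bar\beta_{tumour} - \bar\beta_{normal}} and the
#' direction (`hyper` if \eqn{\Delta\beta > 0}, `hypo` if < 0, `none` if
#' exactly 0).  Features with any missing value in the used samples are
#' dropped (count in attribute `n_dropped_missing`).
#'
#' If `annotation` is supplied, probe-level results are collapsed to gene
#' level by minimum-p representative (see [collapse_probes_to_genes()]).
#'
#' @param beta Beta matrix, probes x samples.
#' @param sheet sample sheet covering the matrix columns.
#' @param fdr FDR threshold for the `significant` flag (default 0.05).
#' @param paired use the patient-matched paired t-test.
#' @param annotation optional probe to gene annotation for collapsing.
#' @return data.frame with columns `id`, `statistic`, `p`, `q`,
#'   `direction`, `effect`, `significant` (gene-level with `gene_id` when
#'   collapsed).
#' @export
dm_ttest <- function(beta, sheet, fdr = 0.05, paired = FALSE,
                     annotation = NULL) {
  sheet <- as.data.frame(sheet)
  validate_sample_sheet(sheet, require_pairing = paired)
  sheet <- sheet[match(colnames(beta), sheet$sample_id), , drop = FALSE]
  if (any(is.na(sheet$sample_id)))
    stop("sample sheet does not cover all matrix columns")
  keep <- stats::complete.cases(beta)
  n_dropped <- sum(!keep)
  x <- beta[keep, , drop = FALSE]
  tum <- x[, sheet$group == "tumour", drop = FALSE]
  nor <- x[, sheet$group == "normal", drop = FALSE]
  if (paired) {
    if (ncol(tum) < 2) stop("paired test requires >= 2 complete pairs")
    pid_t <- sheet$patient_id[sheet$group == "tumour"]
    pid_n <- sheet$patient_id[sheet$group == "normal"]
    nor <- nor[, match(pid_t, pid_n), drop = FALSE]
    res <- paired_rows(tum - nor)
  } else {
    if (ncol(tum) < 2 || ncol(nor) < 2)
      stop("each group needs >= 2 samples for the unpaired test")
    res <- welch_rows(tum, nor)
  }
  q <- stats::p.adjust(res$p, method = "BH")
  out <- data.frame(
    id = rownames(x), statistic = res$statistic, p = res$p, q = q,
    direction = ifelse(res$effect > 0, "hyper",
                       ifelse(res$effect < 0, "hypo", "none")),
    effect = res$effect, significant = q < fdr,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped_missing") <- n_dropped
  if (!is.null(annotation))
    out <- collapse_probes_to_genes(out, annotation)
  out
}

# SAM d statistic: d = (m1 - m2) / (s + s0) with Tusher's pooled standard
# error s.  `grp1` indexes group-1 columns.
sam_d <- function(x, grp1, s0) {
  x1 <- x[, grp1, drop = FALSE]
  x2 <- x[, -grp1, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  list(d = (m1 - m2) / (s + s0), s = s, diff = m1 - m2)
}

# Tusher's fudge factor: the percentile of s minimising the coefficient of
# variation of d's spread across windows of s.  Falls back to median(s)
# when the search degenerates (e.g. near-constant s).
choose_s0 <- function(x, grp1) {
  base <- sam_d(x, grp1, s0 = 0)
  s <- base$s
  if (stats::sd(s) < .Machine$double.eps^0.5 || length(s) < 20)
    return(stats::median(s))
  s_alpha <- stats::quantile(s, probs = seq(0, 1, by = 0.05), names = FALSE)
  qs <- stats::quantile(s, probs = seq(0, 1, by = 0.01), names = FALSE)
  bin <- cut(s, breaks = unique(qs), include.lowest = TRUE)
  cvs <- vapply(s_alpha, function(s0) {
    d <- base$diff / (base$s + s0)
    mads <- tapply(d, bin, stats::mad)
    mads <- mads[is.finite(mads) & mads > 0]
    if (length(mads) < 2) return(NA_real_)
    stats::sd(mads) / mean(mads)
  }, 0.0)
  if (all(is.na(cvs))) return(stats::median(s))
  s_alpha[which.min(cvs)]
}

# Label permutations as a matrix of group-1 column indices: all distinct
# assignments when enumerable, otherwise a uniform random sample (the
# observed assignment gets no special place, so strong signal does not
# contaminate the null reference).
sam_permutations <- function(n, n1, n_perm) {
  n_all <- choose(n, n1)
  if (n_all <= n_perm) {
    if (n_all < n_perm)
      warning("only ", n_all, " distinct permutations exist; enumerating all")
    return(t(utils::combn(n, n1)))
  }
  perms <- matrix(0L, n_perm, n1)
  for (i in seq_len(n_perm)) perms[i, ] <- sort(sample.int(n, n1))
  perms
}

#' Significance Analysis of Microarrays (SAM) for two groups
#'
#' Computes the SAM regularised t-like statistic
#' \eqn{d = (\bar x_1 - \bar x_2)/(s + s_0)} per gene, with the fudge
#' constant \eqn{s_0} chosen by coefficient-of-variation minimisation over
#' percentiles of s, and estimates FDR by permuting group labels.  For the
#' requested FDR level, the symmetric threshold \eqn{\Delta} is the
#' smallest value whose estimated FDR is at or below the level; genes
#' whose ordered d departs from the permutation-expected order statistic
#' by more than \eqn{\Delta} (beyond the resulting cut points) are called
#' significant.  Each gene's `q` is the estimated FDR of the symmetric
#' |d| cut placed at that gene.
#'
#' The estimated FDR of a cut is a location summary, across permutations,
#' of the number of permuted d values outside the cuts, divided by the
#' number of observed calls.  The default summary is the mean (Tusher's
#' original estimator, which stays calibrated when counts are small);
#' `fdr_summary` selects the median or 90th-percentile variants.
#'
#' @param expr log2-scale expression matrix, genes x samples.
#' @param sheet sample sheet (`tumour` is group 1).
#' @param fdr target FDR level (default 0.01, the headline DE threshold).
#' @param n_permutations requested number of label permutations; all
#'   distinct assignments are enumerated when fewer exist.
#' @param seed integer seed controlling permutation sampling.
#' @param s0 optional fixed fudge constant (chosen automatically if NULL).
#' @param fdr_summary summary of the permutation false-call counts:
#'   `"mean"` (default), `"median"`, or `"p90"`.
#' @return data.frame with `id`, `statistic` (d), `q` (estimated FDR at
#'   the gene's |d|), `direction` (`up`/`down`), `effect` (log2 fold
#'   change), `significant`; attributes `s0`, `delta`, `n_permutations`,
#'   `estimated_fdr`.
#' @export
sam_de <- function(expr, sheet, fdr = 0.01, n_permutations = 200,
                   seed = 1L, s0 = NULL,
                   fdr_summary = c("mean", "median", "p90")) {
  fdr_summary <- match.arg(fdr_summary)
  summarise_false <- switch(fdr_summary,
    mean = mean,
    median = stats::median,
    p90 = function(x) stats::quantile(x, 0.9, names = FALSE))
  sheet <- as.data.frame(sheet)
  validate_sample_sheet(sheet)
  sheet <- sheet[match(colnames(expr), sheet$sample_id), , drop = FALSE]
  if (any(is.na(sheet$sample_id)))
    stop("sample sheet does not cover all matrix columns")
  ord <- order(sheet$group == "tumour", decreasing = TRUE)
  x <- expr[, ord, drop = FALSE]
  n1 <- sum(sheet$group == "tumour")
  n2 <- ncol(x) - n1
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 samples")
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]

  set.seed(seed)
  grp1 <- seq_len(n1)
  if (is.null(s0)) s0 <- choose_s0(x, grp1)
  obs <- sam_d(x, grp1, s0)
  perms <- sam_permutations(ncol(x), n1, n_permutations)
  n_perm <- nrow(perms)
  perm_d <- vapply(seq_len(n_perm),
                   function(i) sort(sam_d(x, perms[i, ], s0)$d),
                   numeric(nrow(x)))
  dbar <- rowMeans(perm_d)            # expected order statistics
  d_sorted <- sort(obs$d)

  # permutation columns are sorted ascending, so tail counts reduce to
  # findInterval lookups:  #{d* >= c} = G - findInterval(c, col, left.open)
  n_genes <- nrow(x)
  count_ge <- function(cut)     # per-permutation count of d* >= cut
    vapply(seq_len(n_perm), function(j)
      n_genes - findInterval(cut, perm_d[, j], left.open = TRUE), 0L)
  count_le <- function(cut)
    vapply(seq_len(n_perm), function(j)
      findInterval(cut, perm_d[, j]), 0L)

  # cut points and estimated FDR for a given Delta
  eval_delta <- function(delta) {
    above <- which(d_sorted - dbar > delta)
    below <- which(d_sorted - dbar < -delta)
    cutup <- if (length(above)) min(d_sorted[above]) else Inf
    cutlow <- if (length(below)) max(d_sorted[below]) else -Inf
    n_called <- sum(obs$d >= cutup) + sum(obs$d <= cutlow)
    false_counts <- if (is.finite(cutup)) count_ge(cutup) else 0L
    false_counts <- false_counts +
      if (is.finite(cutlow)) count_le(cutlow) else 0L
    est_fdr <- if (n_called == 0) 0 else
      min(1, summarise_false(false_counts) / n_called)
    list(cutup = cutup, cutlow = cutlow, n_called = n_called,
         est_fdr = est_fdr)
  }
  # candidate Deltas: the observed departures from the expected order
  # statistics, thinned to at most 256 quantile points for tractability
  gaps <- sort(unique(abs(d_sorted - dbar)))
  if (length(gaps) > 256)
    gaps <- unique(stats::quantile(gaps, probs = seq(0, 1, length.out = 256),
                                   names = FALSE, type = 1))
  delta <- Inf; chosen <- eval_delta(Inf)
  for (g in gaps) {   # smallest candidate Delta with estimated FDR <= target
    cand <- eval_delta(g)
    if (cand$est_fdr <= fdr) { delta <- g; chosen <- cand; break }
  }
  sig <- obs$d >= chosen$cutup | obs$d <= chosen$cutlow

  # per-gene q: estimated FDR of the symmetric |d| cut at the gene,
  # made monotone non-increasing in |d|
  abs_d <- abs(obs$d)
  ord_q <- order(abs_d, decreasing = TRUE)
  sorted_abs <- abs_d[ord_q]
  n_obs_ge <- vapply(sorted_abs, function(v) sum(abs_d >= v), 0L)
  perm_abs <- apply(abs(perm_d), 2, sort)   # ascending per permutation
  false_counts <- vapply(seq_len(n_perm), function(j)
    n_genes - findInterval(sorted_abs, perm_abs[, j], left.open = TRUE),
    integer(n_genes))
  false_counts <- matrix(false_counts, nrow = n_genes)
  med_false <- apply(false_counts, 1, summarise_false)
  q_raw <- pmin(1, med_false / n_obs_ge)
  q <- numeric(length(abs_d))
  q[ord_q] <- cummax(q_raw)   # weaker |d| can never have smaller q

  out <- data.frame(
    id = rownames(x), statistic = obs$d, p = NA_real_, q = q,
    direction = ifelse(obs$diff > 0, "up",
                       ifelse(obs$diff < 0, "down", "none")),
    effect = obs$diff, significant = sig, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "s0") <- s0
  attr(out, "delta") <- delta
  attr(out, "n_permutations") <- n_perm
  attr(out, "estimated_fdr") <- chosen$est_fdr
  attr(out, "fdr_summary") <- fdr_summary
  attr(out, "n_dropped_missing") <- sum(!keep)
  out
}

#' Filter differential results by effect size
#'
#' Restricts a result table to features with `|Delta beta| >=`
#' `min_abs_delta_beta` (methylation) or linear fold change `>=`
#' `min_fold_change`, i.e. `|log2FC| >= log2(min_fold_change)`
#' (expression).  Both bounds are inclusive.
#'
#' @param results differential result data.frame with an `effect` column.
#' @param min_abs_delta_beta minimum absolute Beta difference, or NULL.
#' @param min_fold_change minimum linear fold change (>= 1), or NULL.
#' @return the filtered data.frame.
#' @export
apply_effect_filters <- function(results, min_abs_delta_beta = NULL,
                                 min_fold_change = NULL) {
  if (!is.null(min_abs_delta_beta)) {
    if (min_abs_delta_beta < 0) stop("negative Delta-beta threshold")
    results <- results[abs(results$effect) >= min_abs_delta_beta, ,
                       drop = FALSE]
  }
  if (!is.null(min_fold_change)) {
    if (min_fold_change < 0) stop("negative fold-change threshold")
    if (min_fold_change > 0)
      results <- results[abs(results$effect) >= log2(min_fold_change), ,
                         drop = FALSE]
  }
  results
}
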