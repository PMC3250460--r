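# Concordance between promoter methylation change and expression change.
#
# A hypermethylated gene whose expression is significantly down-regulated
# (or a hypomethylated gene up-regulated) counts as concordant.  Excess
# concordance is scored with a one-sided upper-tail hypergeometric test
# over the universe of genes measured on both platforms.

#' Concordance between differential methylation and expression
#'
#' The universe N is the set of genes with both a methylation and an
#' expression test (post-collapse, before significance).  Optional effect
#' filters are applied first: DM genes must satisfy
#' `|Delta beta| >= delta_beta_min`, DE genes `|log2FC| >= log2(fc_min)`.
#' The concordance rate for hypermethylation is the fraction of
#' down-regulated genes among hypermethylated genes with differential
#' expression, with p value
#' \eqn{P(X \ge x_{down})}, \eqn{X \sim} Hypergeometric drawing
#' `k_hyper_de` genes from N of which `n_down` are down-regulated;
#' symmetric fields for hypomethylated/up-regulated genes.
#'
#' @param dm gene-level methylation results (`gene_id`, `direction`,
#'   `effect`, `significant`).
#' @param de gene-level expression results (same columns; `direction`
#'   in `up`/`down`).
#' @param delta_beta_min minimum |Delta beta| for DM genes (default 0).
#' @param fc_min minimum linear fold change for DE genes (default 1).
#' @return a `concordance_report` list: `N`, `n_down`, `n_up`,
#'   `k_hyper_de`, `x_down`, `rate_hyper`, `p_hyper`, `k_hypo_de`,
#'   `x_up`, `rate_hypo`, `p_hypo`, and the thresholds applied.  Rates
#'   are `NA` (not applicable) with no p value when the corresponding
#'   k is 0.
#' @export
concordance_analysis <- function(dm, de, delta_beta_min = 0, fc_min = 1) {
  if (delta_beta_min < 0 || fc_min < 0) stop("negative threshold")
  universe <- intersect(dm$gene_id, de$gene_id)
  if (!length(universe)) stop("empty universe: no gene tested on both platforms")
  dm <- dm[match(universe, dm$gene_id), , drop = FALSE]
  de <- de[match(universe, de$gene_id), , drop = FALSE]

  dm_sig <- dm$significant & abs(dm$effect) >= delta_beta_min
  de_sig <- de$significant &
    (fc_min <= 1 | abs(de$effect) >= log2(max(fc_min, 1)))

  N <- length(universe)
  n_down <- sum(de_sig & de$direction == "down")
  n_up <- sum(de_sig & de$direction == "up")

  tail_p <- function(x, K, k) {
    # P(X >= x), X ~ Hypergeom(N, K, k)
    if (k == 0) return(NA_real_)
    stats::phyper(x - 1, K, N - K, k, lower.tail = FALSE)
  }
  hyper_de <- dm_sig & dm$direction == "hyper" & de_sig
  k_hyper <- sum(hyper_de)
  x_down <- sum(hyper_de & de$direction == "down")
  hypo_de <- dm_sig & dm$direction == "hypo" & de_sig
  k_hypo <- sum(hypo_de)
  x_up <- sum(hypo_de & de$direction == "up")

  structure(list(
    N = N, n_down = n_down, n_up = n_up,
    k_hyper_de = k_hyper, x_down = x_down,
    rate_hyper = if (k_hyper > 0) x_down / k_hyper else NA_real_,
    p_hyper = tail_p(x_down, n_down, k_hyper),
    k_hypo_de = k_hypo, x_up = x_up,
    rate_hypo = if (k_hypo > 0) x_up / k_hypo else NA_real_,
    p_hypo = tail_p(x_up, n_up, k_hypo),
    delta_beta_min = delta_beta_min, fc_min = fc_min),
    class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Universe N=%d (down=%d, up=%d); filters: |dB|>=%g, FC>=%g\n",
              x$N, x$n_down, x$n_up, x$delta_beta_min, x$fc_min))
  cat(sprintf("hyper->down: %d/%d = %s (hypergeometric p = %.3g)\n",
              x$x_down, x$k_hyper_de, fmt_pct(x$rate_hyper), x$p_hyper))
  cat(sprintf("hypo->up:    %d/%d = %s (hypergeometric p = %.3g)\n",
              x$x_up, x$k_hypo_de, fmt_pct(x$rate_hypo), x$p_hypo))
  invisible(x)
}

#' Concordance over a grid of effect-size thresholds
#'
#' One [concordance_analysis()] per (Delta beta, fold change) grid point;
#' results are tabulated, no inference across grid points is made.
#'
#' @param dm,de as in [concordance_analysis()].
#' @param delta_beta_grid numeric vector of |Delta beta| thresholds.
#' @param fc_grid numeric vector of linear fold-change thresholds.
#' @return data.frame with one row per grid point and the report's counts
#'   and rates as columns.
#' @export
concordance_by_threshold_sweep <- function(dm, de,
                                           delta_beta_grid = c(0, 0.15, 0.3),
                                           fc_grid = c(1, 2)) {
  if (!length(delta_beta_grid) || !length(fc_grid)) stop("empty grid")
  grid <- expand.grid(delta_beta_min = delta_beta_grid, fc_min = fc_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    r <- concordance_analysis(dm, de, grid$delta_beta_min[i], grid$fc_min[i])
    as.data.frame(r[c("delta_beta_min", "fc_min", "N", "n_down", "n_up",
                      "k_hyper_de", "x_down", "rate_hyper", "p_hyper",
                      "k_hypo_de", "x_up", "rate_hypo", "p_hypo")])
  })
  do.call(rbind, rows)
}
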