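#' Configuration for synthetic paired tumour/normal cohorts
#'
#' The generator emulates promoter-array methylation cohorts in which each
#' patient contributes one tumour and one normal sample processed in the
#' same experimental batch, plus matched log2-scale expression cohorts
#' whose regulation directions are partially coupled to the methylation
#' directions.
#'
#' All systematic effects act on the logit of the Beta value, so Beta stays
#' in (0, 1).  `delta_beta_effect` is the target mean |Delta beta| of true
#' differentially methylated (DM) probes on the Beta scale; it is applied
#' as the equivalent logit offset of each probe's baseline.
#'
#' @param n_probes number of methylation probes.
#' @param n_genes number of genes; defaults to `n_probes / probes_per_gene`.
#' @param probes_per_gene probes mapping to each gene (1 = HM27-like).
#' @param n_pairs_per_batch integer vector, tumour/normal pairs per batch.
#' @param n_batches number of batches; defaults to
#'   `length(n_pairs_per_batch)`.
#' @param frac_dm fraction of probes that are truly DM.
#' @param frac_hyper_among_dm fraction of true-DM probes hypermethylated.
#' @param delta_beta_effect target mean |Delta beta| of true-DM probes.
#' @param batch_sd standard deviation of per-batch additive logit offsets.
#' @param noise_sd within-group logit-scale noise standard deviation.
#' @param concordance_hyper probability a true-hyper gene is truly
#'   down-regulated (else up-regulated).
#' @param concordance_hypo probability a true-hypo gene is truly
#'   up-regulated (else down-regulated).
#' @param frac_de_background fraction of non-DM genes that are DE anyway.
#' @param lfc_effect mean |log2 fold change| of true DE genes.
#' @param expr_noise_sd log2-scale expression noise standard deviation.
#' @param seed integer random seed; all generation is reproducible from it.
#' @return a `simulation_config` list, validated.
#' @export
simulation_config <- function(n_probes = 2000,
                              n_genes = NULL,
                              probes_per_gene = 1,
                              n_pairs_per_batch = c(30, 30),
                              n_batches = NULL,
                              frac_dm = 0.1,
                              frac_hyper_among_dm = 0.5,
                              delta_beta_effect = 0.3,
                              batch_sd = 0.5,
                              noise_sd = 0.5,
                              concordance_hyper = 0.9,
                              concordance_hypo = 0.6,
                              frac_de_background = 0.05,
                              lfc_effect = 2,
                              expr_noise_sd = 0.5,
                              seed = 1L) {
  if (is.null(n_batches)) n_batches <- length(n_pairs_per_batch)
  if (length(n_pairs_per_batch) == 1L && n_batches > 1L)
    n_pairs_per_batch <- rep(n_pairs_per_batch, n_batches)
  if (is.null(n_genes)) n_genes <- ceiling(n_probes / probes_per_gene)
  cfg <- list(n_probes = as.integer(n_probes), n_genes = as.integer(n_genes),
              probes_per_gene = as.integer(probes_per_gene),
              n_pairs_per_batch = as.integer(n_pairs_per_batch),
              n_batches = as.integer(n_batches),
              frac_dm = frac_dm, frac_hyper_among_dm = frac_hyper_among_dm,
              delta_beta_effect = delta_beta_effect, batch_sd = batch_sd,
              noise_sd = noise_sd, concordance_hyper = concordance_hyper,
              concordance_hypo = concordance_hypo,
              frac_de_background = frac_de_background,
              lfc_effect = lfc_effect, expr_noise_sd = expr_noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk_frac <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop("configuration error: '", field, "' must be a fraction in [0,1]")
  }
  chk_nonneg <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop("configuration error: '", field, "' must be non-negative")
  }
  chk_count <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 1))
      stop("configuration error: '", field, "' must be a positive count")
  }
  for (f in c("frac_dm", "frac_hyper_among_dm", "concordance_hyper",
              "concordance_hypo", "frac_de_background")) chk_frac(f)
  for (f in c("delta_beta_effect", "batch_sd", "noise_sd", "lfc_effect",
              "expr_noise_sd")) chk_nonneg(f)
  for (f in c("n_probes", "n_genes", "probes_per_gene", "n_pairs_per_batch",
              "n_batches")) chk_count(f)
  if (length(cfg$n_pairs_per_batch) != cfg$n_batches)
    stop("configuration error: 'n_pairs_per_batch' length must equal 'n_batches'")
  if (cfg$delta_beta_effect >= 1)
    stop("configuration error: 'delta_beta_effect' must be < 1")
  invisible(cfg)
}

logit <- function(p) log(p / (1 - p))

# Baseline Beta: mixture of a low (~0.1) unmethylated mode and a high
# (~0.8) methylated mode, mimicking CpG-island bimodality.
draw_baseline_beta <- function(n, p_low = 0.6,
                               low_mode = 0.1, high_mode = 0.8,
                               spread = 0.5) {
  low <- stats::runif(n) < p_low
  centre <- ifelse(low, logit(low_mode), logit(high_mode))
  stats::plogis(centre + stats::rnorm(n, 0, spread))
}

# Logit offset that moves a baseline Beta by +/- delta on the Beta scale,
# clamped away from the boundaries.
logit_shift_for_delta <- function(base, delta, dir_sign, eps = 0.02) {
  target <- pmin(pmax(base + dir_sign * delta, eps), 1 - eps)
  logit(target) - logit(base)
}

new_truth <- function(cfg) {
  probe_id <- sprintf("p%05d", seq_len(cfg$n_probes))
  gene_id <- sprintf("g%05d",
                     rep(seq_len(cfg$n_genes),
                         each = cfg$probes_per_gene)[seq_len(cfg$n_probes)])
  n_dm <- round(cfg$frac_dm * cfg$n_probes)
  n_hyper <- round(cfg$frac_hyper_among_dm * n_dm)
  is_dm <- rep(FALSE, cfg$n_probes)
  dm_idx <- if (n_dm > 0) sample.int(cfg$n_probes, n_dm) else integer(0)
  is_dm[dm_idx] <- TRUE
  direction <- rep("none", cfg$n_probes)
  if (n_dm > 0) {
    hyper_idx <- dm_idx[seq_len(n_hyper)]
    direction[dm_idx] <- "hypo"
    direction[hyper_idx] <- "hyper"
  }
  baseline <- draw_baseline_beta(cfg$n_probes)
  # keep true-DM baselines away from the clamp so the intended shift lands
  if (n_dm > 0) {
    lo <- 0.05 + cfg$delta_beta_effect
    sq <- function(b) pmin(pmax(b, 0.1), 0.9)
    hyp <- direction == "hyper"
    baseline[hyp] <- pmin(sq(baseline[hyp]), 0.95 - cfg$delta_beta_effect)
    hpo <- direction == "hypo"
    baseline[hpo] <- pmax(sq(baseline[hpo]), lo)
  }
  probes <- data.frame(probe_id = probe_id, gene_id = gene_id,
                       baseline_beta = baseline, is_dm = is_dm,
                       direction = direction, stringsAsFactors = FALSE)
  structure(list(probes = probes, config = cfg), class = "simulation_truth")
}

#' Generate a paired tumour/normal methylation cohort
#'
#' Produces a Beta-value matrix (probes x samples), a sample sheet, and a
#' ground-truth object.  Each patient contributes one tumour and one normal
#' sample sharing a `patient_id` and batch; every sample in batch b carries
#' an additive logit offset drawn N(0, `batch_sd`^2); tumour samples of
#' true-DM probes are shifted so the tumour - normal mean Beta difference
#' targets `delta_beta_effect` with the truth's sign.
#'
#' @param config a [simulation_config()].
#' @param truth optionally, a truth object from a previous call with the
#'   same config (used to draw replicate datasets from one truth).
#' @param dataset_label label stored in the sample sheet's batch names.
#' @return list with elements `beta` (matrix), `sheet` (data.frame),
#'   `truth` (simulation_truth), `annotation` (probe to gene data.frame).
#' @export
generate_methylation_cohort <- function(config, truth = NULL,
                                        dataset_label = "d1") {
  validate_config(config)
  if (is.null(truth)) {
    set.seed(config$seed)
    truth <- new_truth(config)
  } else if (!inherits(truth, "simulation_truth") ||
             truth$config$n_probes != config$n_probes) {
    stop("truth was not produced with a compatible config")
  }
  cfg <- config
  n_pairs <- sum(cfg$n_pairs_per_batch)
  batch_of_pair <- rep(seq_len(cfg$n_batches), cfg$n_pairs_per_batch)
  batch_lab <- sprintf("%s_b%d", dataset_label, batch_of_pair)
  patient <- sprintf("%s_pt%03d", dataset_label, seq_len(n_pairs))
  sheet <- data.frame(
    sample_id = c(paste0(patient, "_T"), paste0(patient, "_N")),
    group = rep(c("tumour", "normal"), each = n_pairs),
    batch = rep(batch_lab, 2),
    laboratory = "lab1",
    patient_id = rep(patient, 2),
    stringsAsFactors = FALSE)

  batch_offsets <- stats::rnorm(cfg$n_batches, 0, cfg$batch_sd)
  pr <- truth$probes
  dir_sign <- ifelse(pr$direction == "hyper", 1,
                     ifelse(pr$direction == "hypo", -1, 0))
  shift <- ifelse(pr$is_dm,
                  logit_shift_for_delta(pr$baseline_beta,
                                        cfg$delta_beta_effect, dir_sign),
                  0)
  base_logit <- logit(pr$baseline_beta)
  n_samples <- 2L * n_pairs
  lin <- matrix(base_logit, cfg$n_probes, n_samples)
  is_tum <- sheet$group == "tumour"
  lin[, is_tum] <- lin[, is_tum] + shift
  off <- batch_offsets[batch_of_pair[match(sheet$patient_id, patient)]]
  lin <- sweep(lin, 2, off, "+")
  if (cfg$noise_sd > 0)
    lin <- lin + matrix(stats::rnorm(length(lin), 0, cfg$noise_sd),
                        nrow(lin), ncol(lin))
  beta <- stats::plogis(lin)
  dimnames(beta) <- list(pr$probe_id, sheet$sample_id)
  truth$batch_offsets <- stats::setNames(batch_offsets, unique(batch_lab))
  annotation <- pr[, c("probe_id", "gene_id")]
  list(beta = beta, sheet = sheet, truth = truth, annotation = annotation)
}

#' Generate an expression cohort coupled to a methylation truth
#'
#' Draws a log2-scale gene-by-sample expression matrix for an independent
#' set of tumour/normal pairs.  Gene-level methylation direction is taken
#' from the truth's probes (a gene is hyper/hypo if any of its probes is);
#' a true-hyper gene is truly down-regulated with probability
#' `concordance_hyper` (otherwise up-regulated), a true-hypo gene
#' up-regulated with probability `concordance_hypo`; a fraction
#' `frac_de_background` of non-DM genes is DE with random direction.
#' If `lfc_effect` is 0 no gene is truly DE.
#'
#' @param config a [simulation_config()].
#' @param truth truth object from [generate_methylation_cohort()]; gains a
#'   `genes` ground-truth table in the returned copy.
#' @param n_per_group samples per expression group (default 20).
#' @param dataset_label prefix for sample ids.
#' @return list with `expr` (matrix), `sheet`, and the augmented `truth`.
#' @export
generate_expression_cohort <- function(config, truth,
                                       n_per_group = 20,
                                       dataset_label = "e1") {
  validate_config(config)
  if (!inherits(truth, "simulation_truth"))
    stop("truth must come from generate_methylation_cohort")
  set.seed(config$seed + 7919L)   # offset keeps the draw independent of the
                                  # methylation cohort's stream
  gene_ids <- unique(truth$probes$gene_id)
  if (length(gene_ids) != config$n_genes)
    stop("gene universe of truth does not match config")
  pr <- truth$probes
  gdir <- vapply(split(pr$direction, pr$gene_id), function(d) {
    u <- unique(d[d != "none"])
    if (length(u) == 1) u else if (length(u) > 1) u[1] else "none"
  }, "")[gene_ids]

  de_dir <- rep(0L, length(gene_ids))    # +1 up, -1 down
  hyp <- gdir == "hyper"; hpo <- gdir == "hypo"; bg <- gdir == "none"
  de_dir[hyp] <- ifelse(stats::runif(sum(hyp)) < config$concordance_hyper,
                        -1L, 1L)
  de_dir[hpo] <- ifelse(stats::runif(sum(hpo)) < config$concordance_hypo,
                        1L, -1L)
  bg_de <- bg & stats::runif(length(gene_ids)) < config$frac_de_background
  de_dir[bg_de] <- ifelse(stats::runif(sum(bg_de)) < 0.5, 1L, -1L)
  lfc <- de_dir * config$lfc_effect
  is_de <- lfc != 0

  n <- as.integer(n_per_group)
  sheet <- data.frame(
    sample_id = c(sprintf("%s_T%03d", dataset_label, seq_len(n)),
                  sprintf("%s_N%03d", dataset_label, seq_len(n))),
    group = rep(c("tumour", "normal"), each = n),
    batch = paste0(dataset_label, "_b1"),
    laboratory = "lab1",
    stringsAsFactors = FALSE)
  baseline <- stats::rnorm(length(gene_ids), 8, 2)
  expr <- matrix(baseline, length(gene_ids), 2L * n)
  expr[, seq_len(n)] <- expr[, seq_len(n)] + lfc
  expr <- expr + matrix(stats::rnorm(length(expr), 0, config$expr_noise_sd),
                        nrow(expr), ncol(expr))
  dimnames(expr) <- list(gene_ids, sheet$sample_id)
  truth$genes <- data.frame(
    gene_id = gene_ids, meth_direction = gdir, is_de = is_de,
    de_direction = ifelse(de_dir > 0, "up", ifelse(de_dir < 0, "down", "none")),
    log2fc = lfc, stringsAsFactors = FALSE)
  list(expr = expr, sheet = sheet, truth = truth)
}

#' Generate two replicate methylation datasets sharing one truth
#'
#' Emulates treating a cancer's two largest experimental batches as
#' independent datasets: both cohorts are drawn from the same probe-level
#' truth with independent noise and independent batch offsets.
#'
#' @param config a [simulation_config()] with `n_batches >= 2`; dataset i
#'   uses `n_pairs_per_batch[i]` pairs in a single batch.
#' @return list with `d1`, `d2` (each as returned by
#'   [generate_methylation_cohort()]), sharing one `truth`, and the shared
#'   `annotation`.
#' @export
generate_two_batch_replicates <- function(config) {
  validate_config(config)
  if (config$n_batches < 2)
    stop("configuration error: 'n_batches' must be >= 2 for replicates")
  set.seed(config$seed)
  truth <- new_truth(config)
  one <- function(i, lab) {
    cfg <- config
    cfg$n_batches <- 1L
    cfg$n_pairs_per_batch <- config$n_pairs_per_batch[i]
    generate_methylation_cohort(cfg, truth = truth, dataset_label = lab)
  }
  d1 <- one(1L, "d1")
  d2 <- one(2L, "d2")
  list(d1 = d1, d2 = d2, truth = truth, annotation = d1$annotation)
}

#' Emit raw (M, U) signal pairs consistent with a Beta matrix
#'
#' Inverts the Beta computation for testing the signal path: for a chosen
#' total intensity c, `U = c * (1 - beta') and M = c * beta'` where
#' `beta' = beta * (c + 100) / c`, so that `M / (U + M + 100)` returns the
#' input Beta exactly (requires `beta < c / (c + 100)`).
#'
#' @param beta Beta matrix in `[0, 1)`.
#' @param total total signal intensity c (default 5000).
#' @return list of matrices `M` and `U`.
#' @export
beta_to_signals <- function(beta, total = 5000) {
  if (any(beta >= total / (total + 100)))
    stop("total intensity too small to represent the largest Beta")
  beta_prime <- beta * (total + 100) / total
  M <- total * beta_prime
  U <- total - M
  list(M = M, U = U)
}
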