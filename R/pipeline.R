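# End-to-end orchestration: batch QC -> DM per dataset -> reproducibility
# -> DE per dataset -> reproducibility -> concordance -> enrichment.

#' Configuration for a full pipeline run
#'
#' @param beta_paths character vector (length 1 or 2) of Beta matrix TSVs;
#'   two paths enable the reproducibility stage.
#' @param expr_paths character vector (length 0-2) of expression TSVs.
#' @param sheet_paths,expr_sheet_paths sample sheet TSVs aligned with the
#'   matrices above.
#' @param annotation_path probe-to-gene annotation TSV.
#' @param gmt_path optional GMT file for the enrichment stage.
#' @param fdr_batch,fdr_dm,fdr_de FDR thresholds (defaults 0.05, 0.05,
#'   0.01).
#' @param delta_beta_grid,fc_grid effect-size grids for the concordance
#'   sweep.
#' @param paired use patient-matched paired t-tests for DM calling.
#' @param n_permutations SAM label permutations.
#' @param seed top-level seed; all randomness (SAM permutations) flows
#'   from it.
#' @param outdir output directory for report TSVs and the manifest.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(beta_paths, sheet_paths, annotation_path,
                            expr_paths = character(0),
                            expr_sheet_paths = character(0),
                            gmt_path = NULL,
                            fdr_batch = 0.05, fdr_dm = 0.05, fdr_de = 0.01,
                            delta_beta_grid = c(0, 0.15, 0.3),
                            fc_grid = c(1, 2),
                            paired = TRUE, n_permutations = 200,
                            seed = 1L, outdir = "methrepro_run") {
  for (thr in c(fdr_batch, fdr_dm, fdr_de))
    if (!is.numeric(thr) || thr <= 0 || thr >= 1)
      stop("FDR thresholds must lie in (0, 1)")
  cfg <- list(beta_paths = beta_paths, sheet_paths = sheet_paths,
              annotation_path = annotation_path, expr_paths = expr_paths,
              expr_sheet_paths = expr_sheet_paths, gmt_path = gmt_path,
              fdr_batch = fdr_batch, fdr_dm = fdr_dm, fdr_de = fdr_de,
              delta_beta_grid = delta_beta_grid, fc_grid = fc_grid,
              paired = paired, n_permutations = n_permutations,
              seed = as.integer(seed), outdir = outdir)
  class(cfg) <- "pipeline_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full cross-study analysis
#'
#' Executes every stage the inputs allow: per-dataset batch QC
#' ([probe_batch_anova()]), DM calling ([dm_ttest()], gene-collapsed),
#' DM reproducibility ([overlap_report()]) when two methylation datasets
#' are given, DE calling ([sam_de()]) and DE reproducibility when
#' expression data are given, concordance sweep
#' ([concordance_by_threshold_sweep()]) when both platforms are present,
#' and GMT enrichment of the hyper- and hypomethylated lists when a GMT
#' file is given.  Writes one TSV per stage plus `manifest.txt` and
#' `summary.tsv` into `config$outdir`, and returns the report bundle
#' invisibly.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with elements `batch_qc`, `dm`, `dm_overlap`,
#'   `de`, `de_overlap`, `concordance`, `enrichment`, `summary`.
#' @export
run_full_analysis <- function(config) {
  for (p in c(config$beta_paths, config$sheet_paths, config$annotation_path,
              config$expr_paths, config$expr_sheet_paths, config$gmt_path))
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  ann <- stage("read annotation", read_annotation(config$annotation_path))
  n_meth <- length(config$beta_paths)

  out <- list(batch_qc = list(), dm = list(), de = list())
  for (i in seq_len(n_meth)) {
    beta <- stage("read beta", read_matrix_tsv(config$beta_paths[i]))
    sheet <- stage("read sample sheet",
                   read_sample_sheet(config$sheet_paths[i]))
    qc <- if (length(unique(sheet$batch)) >= 2)
      stage("batch-qc", probe_batch_anova(beta, sheet,
                                          fdr = config$fdr_batch))
    else NULL
    out$batch_qc[[i]] <- qc
    dm <- stage("dm", dm_ttest(beta, sheet, fdr = config$fdr_dm,
                               paired = config$paired, annotation = ann))
    out$dm[[i]] <- dm
    write_results_tsv(dm, file.path(config$outdir,
                                    sprintf("dm_dataset%d.tsv", i)))
    if (!is.null(qc))
      write_results_tsv(qc$table,
                        file.path(config$outdir,
                                  sprintf("batch_qc_dataset%d.tsv", i)))
  }
  if (n_meth >= 2)
    out$dm_overlap <- stage("dm reproducibility",
                            overlap_report(out$dm[[1]], out$dm[[2]]))

  for (i in seq_along(config$expr_paths)) {
    expr <- stage("read expression", read_matrix_tsv(config$expr_paths[i]))
    esheet <- stage("read expression sample sheet",
                    read_sample_sheet(config$expr_sheet_paths[i]))
    de <- stage("de", sam_de(expr, esheet, fdr = config$fdr_de,
                             n_permutations = config$n_permutations,
                             seed = config$seed + i))
    de$gene_id <- de$id
    out$de[[i]] <- de
    write_results_tsv(de, file.path(config$outdir,
                                    sprintf("de_dataset%d.tsv", i)))
  }
  if (length(out$de) >= 2)
    out$de_overlap <- stage("de reproducibility",
                            overlap_report(out$de[[1]], out$de[[2]]))

  if (length(out$dm) && length(out$de)) {
    # reproducible DM set when two methylation datasets are supplied:
    # significant in both with consistent direction; else dataset 1
    dm_use <- if (n_meth >= 2) {
      s1 <- out$dm[[1]][out$dm[[1]]$significant, , drop = FALSE]
      s2 <- out$dm[[2]][out$dm[[2]]$significant, , drop = FALSE]
      shared <- intersect(s1$gene_id, s2$gene_id)
      same <- s1$direction[match(shared, s1$gene_id)] ==
        s2$direction[match(shared, s2$gene_id)]
      keep <- out$dm[[1]]$gene_id %in% shared[same]
      dm1 <- out$dm[[1]]
      dm1$significant <- dm1$significant & keep
      dm1
    } else out$dm[[1]]
    de_use <- if (length(out$de) >= 2) {
      s1 <- out$de[[1]][out$de[[1]]$significant, , drop = FALSE]
      s2 <- out$de[[2]][out$de[[2]]$significant, , drop = FALSE]
      shared <- intersect(s1$gene_id, s2$gene_id)
      same <- s1$direction[match(shared, s1$gene_id)] ==
        s2$direction[match(shared, s2$gene_id)]
      de1 <- out$de[[1]]
      de1$significant <- de1$significant &
        de1$gene_id %in% shared[same]
      de1
    } else out$de[[1]]
    out$concordance <- stage("concordance",
                             concordance_by_threshold_sweep(
                               dm_use, de_use,
                               config$delta_beta_grid, config$fc_grid))
    write_results_tsv(out$concordance,
                      file.path(config$outdir, "concordance.tsv"))
  }

  if (!is.null(config$gmt_path) && length(out$dm)) {
    sets <- stage("read gmt", read_gmt(config$gmt_path))
    dm1 <- out$dm[[1]]
    universe <- dm1$gene_id
    for (dirn in c("hyper", "hypo")) {
      qry <- dm1$gene_id[dm1$significant & dm1$direction == dirn]
      if (length(qry)) {
        er <- stage(paste0("enrichment ", dirn),
                    enrich(qry, sets, universe, fdr = 0.05))
        out$enrichment[[dirn]] <- er
        write_results_tsv(er, file.path(config$outdir,
                                        sprintf("enrichment_%s.tsv", dirn)))
      }
    }
  }

  out$summary <- pipeline_summary(out)
  write_results_tsv(out$summary, file.path(config$outdir, "summary.tsv"))
  writeLines(c(
    sprintf("methrepro %s",
            as.character(utils::packageVersion("methrepro"))),
    sprintf("seed: %d", config$seed),
    sprintf("fdr: batch=%g dm=%g de=%g", config$fdr_batch, config$fdr_dm,
            config$fdr_de),
    sprintf("paired: %s", config$paired),
    sprintf("permutations: %d", config$n_permutations),
    sprintf("inputs: %s",
            paste(c(config$beta_paths, config$expr_paths), collapse = " "))),
    file.path(config$outdir, "manifest.txt"))
  invisible(out)
}

# Summary table in the shape of the overlap/concordance tables: counts,
# POGs, consistency, concordance rates.
pipeline_summary <- function(out) {
  rows <- list()
  add <- function(metric, value)
    rows[[length(rows) + 1]] <<- data.frame(metric = metric, value = value,
                                            stringsAsFactors = FALSE)
  for (i in seq_along(out$dm))
    add(sprintf("dm_significant_genes_dataset%d", i),
        sum(out$dm[[i]]$significant))
  ov <- out$dm_overlap
  if (!is.null(ov)) {
    add("dm_L1", ov$L1); add("dm_L2", ov$L2); add("dm_overlap_k", ov$k)
    add("dm_pog12", ov$pog12); add("dm_pog21", ov$pog21)
    add("dm_direction_consistency", ov$consistency)
  }
  for (i in seq_along(out$de))
    add(sprintf("de_significant_genes_dataset%d", i),
        sum(out$de[[i]]$significant))
  ov <- out$de_overlap
  if (!is.null(ov)) {
    add("de_L1", ov$L1); add("de_L2", ov$L2); add("de_overlap_k", ov$k)
    add("de_pog12", ov$pog12); add("de_pog21", ov$pog21)
    add("de_direction_consistency", ov$consistency)
  }
  cc <- out$concordance
  if (!is.null(cc)) {
    base <- cc[cc$delta_beta_min == min(cc$delta_beta_min) &
                 cc$fc_min == min(cc$fc_min), , drop = FALSE][1, ]
    add("concordance_rate_hyper", base$rate_hyper)
    add("concordance_rate_hypo", base$rate_hypo)
  }
  do.call(rbind, rows)
}

#' Write a simulated study (methylation + expression + truth) to disk
#'
#' Convenience wrapper used by the command-line `simulate` subcommand:
#' generates two replicate methylation datasets and one expression cohort
#' from a single truth and writes every table in the TSV formats the
#' pipeline reads, plus `truth_probes.tsv` / `truth_genes.tsv`.
#'
#' @param config a [simulation_config()].
#' @param outdir output directory (created if needed).
#' @return (invisibly) named character vector of the written paths.
#' @export
write_simulated_study <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  reps <- generate_two_batch_replicates(config)
  ex <- generate_expression_cohort(config, reps$truth)
  paths <- c(
    beta1 = file.path(outdir, "beta_dataset1.tsv"),
    beta2 = file.path(outdir, "beta_dataset2.tsv"),
    sheet1 = file.path(outdir, "samples_dataset1.tsv"),
    sheet2 = file.path(outdir, "samples_dataset2.tsv"),
    expr = file.path(outdir, "expr_dataset1.tsv"),
    expr_sheet = file.path(outdir, "samples_expr1.tsv"),
    annotation = file.path(outdir, "annotation.tsv"),
    truth_probes = file.path(outdir, "truth_probes.tsv"),
    truth_genes = file.path(outdir, "truth_genes.tsv"))
  write_matrix_tsv(reps$d1$beta, paths["beta1"], id_col = "probe_id")
  write_matrix_tsv(reps$d2$beta, paths["beta2"], id_col = "probe_id")
  write_sample_sheet(reps$d1$sheet, paths["sheet1"])
  write_sample_sheet(reps$d2$sheet, paths["sheet2"])
  write_matrix_tsv(ex$expr, paths["expr"], id_col = "gene_id")
  write_sample_sheet(ex$sheet, paths["expr_sheet"])
  write_annotation(reps$annotation, paths["annotation"])
  utils::write.table(ex$truth$probes, paths["truth_probes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ex$truth$genes, paths["truth_genes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
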