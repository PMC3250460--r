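test_that("one-way ANOVA handles equal means and degenerate variance", {
  beta <- rbind(p1 = c(1, 2, 3, 1, 2, 3) / 10,
                p2 = c(0, 0, 0, 1, 1, 1) / 2,
                p3 = runif(6))
  colnames(beta) <- sprintf("s%d", 1:6)
  sheet <- data.frame(sample_id = colnames(beta),
                      group = "tumour",
                      batch = rep(c("A", "B"), each = 3))
  qc <- probe_batch_anova(beta, sheet)
  t1 <- qc$table[qc$table$probe_id == "p1", ]
  expect_equal(t1$F, 0)
  expect_equal(t1$p, 1)
  # zero within-group variance with separated means: F infinite, p -> 0
  t2 <- qc$table[qc$table$probe_id == "p2", ]
  expect_equal(t2$F, Inf)
  expect_equal(t2$p, 0)
  expect_true(all(qc$table$q >= qc$table$p))
  expect_equal(qc$susceptible_fraction,
               mean(qc$table$q < 0.05))
})

test_that("two-group ANOVA F equals the squared pooled-variance t", {
  set.seed(31)
  for (rep in 1:5) {
    x <- rand_matrix(40, 6, seed = 31 + rep)
    sheet <- data.frame(sample_id = colnames(x), group = "tumour",
                        batch = rep(c("A", "B"), each = 3))
    qc <- probe_batch_anova(x, sheet, fdr = 0.05)
    # independent oracle: equal-variance two-sample t via t.test
    t_oracle <- apply(x, 1, function(r)
      stats::t.test(r[1:3], r[4:6], var.equal = TRUE)$statistic)
    expect_equal(qc$table$F, unname(t_oracle^2), tolerance = 1e-10)
  }
})

test_that("permuting sample order changes no F, p or q", {
  x <- rand_matrix(30, 8, seed = 77, rfun = stats::runif)
  sheet <- data.frame(sample_id = colnames(x), group = "tumour",
                      batch = rep(c("A", "B"), each = 4))
  qc1 <- probe_batch_anova(x, sheet)
  perm <- c(5, 2, 8, 1, 4, 7, 3, 6)
  qc2 <- probe_batch_anova(x[, perm], sheet[perm, ])
  expect_equal(qc1$table, qc2$table)
})

test_that("null batches keep the susceptible fraction near the FDR level", {
  fracs <- vapply(1:50, function(s) {
    x <- rand_matrix(60, 10, seed = 1000 + s, rfun = stats::runif)
    sheet <- data.frame(sample_id = colnames(x), group = "tumour",
                        batch = rep(c("A", "B"), each = 5))
    probe_batch_anova(x, sheet, fdr = 0.05)$susceptible_fraction
  }, 0.0)
  expect_lte(mean(fracs), 0.05 + 2 * stats::sd(fracs) / sqrt(50))
})

test_that("ANOVA validates group sizes and constant matrices", {
  x <- rand_matrix(5, 3, seed = 1)
  sheet <- data.frame(sample_id = colnames(x), group = "tumour",
                      batch = c("A", "A", "B"))
  expect_error(probe_batch_anova(x, sheet), "< 2 samples.*B")
  xc <- matrix(0.5, 4, 4, dimnames = list(paste0("p", 1:4), paste0("s", 1:4)))
  sheetc <- data.frame(sample_id = colnames(xc), group = "tumour",
                       batch = rep(c("A", "B"), each = 2))
  expect_error(probe_batch_anova(xc, sheetc), "constant")
})

test_that("dominant batch effects cluster samples perfectly by batch", {
  cfg <- simulation_config(n_probes = 150, n_pairs_per_batch = c(8, 8),
                           batch_sd = 3, noise_sd = 0.2,
                           delta_beta_effect = 0, seed = 5)
  co <- generate_methylation_cohort(cfg)
  cl <- batch_purity_clustering(co$beta, co$sheet)
  expect_true(cl$perfect_split)
  expect_equal(cl$agreement, 1)
  # no batch signal: agreement near zero on average over seeds
  agr <- vapply(1:10, function(s) {
    cfg0 <- simulation_config(n_probes = 100, n_pairs_per_batch = c(6, 6),
                              batch_sd = 0, noise_sd = 0.5,
                              delta_beta_effect = 0, seed = 100 + s)
    co0 <- generate_methylation_cohort(cfg0)
    batch_purity_clustering(co0$beta, co0$sheet)$agreement
  }, 0.0)
  expect_lt(abs(mean(agr)), 0.2)
  # duplicated samples split across fake batches carry no signal
  x <- rand_matrix(50, 4, seed = 9, rfun = stats::runif)
  x <- cbind(x, x)
  colnames(x) <- sprintf("s%d", 1:8)
  sheet <- data.frame(sample_id = colnames(x), group = "tumour",
                      batch = rep(c("A", "B"), 4))
  expect_false(batch_purity_clustering(x, sheet)$perfect_split)
  # single batch: purity not applicable
  sheet$batch <- "A"
  expect_true(is.na(batch_purity_clustering(x, sheet)$perfect_split))
})

test_that("same-distribution tumour batches give consistent DM directions", {
  cfg <- simulation_config(n_probes = 300, n_pairs_per_batch = c(15, 15),
                           batch_sd = 0, seed = 13)
  reps <- generate_two_batch_replicates(cfg)
  beta <- cbind(reps$d1$beta, reps$d2$beta)
  tum_a <- reps$d1$sheet$sample_id[reps$d1$sheet$group == "tumour"]
  tum_b <- reps$d2$sheet$sample_id[reps$d2$sheet$group == "tumour"]
  normals <- reps$d1$sheet$sample_id[reps$d1$sheet$group == "normal"]
  res <- batch_vs_batch_dm_corruption(beta, tum_a, tum_b, normals)
  expect_gt(res$consistency, 0.95)
  # a comparison of a dataset with itself is perfectly consistent
  ra <- res$results_a
  shared <- ra$id[ra$significant]
  expect_equal(direction_consistency(ra$direction[ra$significant],
                                     ra$direction[ra$significant])$consistency,
               1)
  expect_error(batch_vs_batch_dm_corruption(beta, tum_a, tum_a, normals),
               "disjoint")
})

test_that("opposing batch offsets corrupt DM calls without true signal", {
  # two tumour batches pushed in opposite directions, no true DM signal:
  # both comparisons call many probes but their directions disagree
  set.seed(55)
  cfg <- simulation_config(n_probes = 400, n_pairs_per_batch = 20,
                           n_batches = 1, frac_dm = 0, batch_sd = 0,
                           noise_sd = 0.4, seed = 55)
  co <- generate_methylation_cohort(cfg)
  tum <- co$sheet$sample_id[co$sheet$group == "tumour"]
  nor <- co$sheet$sample_id[co$sheet$group == "normal"]
  beta <- co$beta
  offset <- 1.5
  lo <- function(b) stats::plogis(stats::qlogis(b))
  beta[, tum[1:10]] <- stats::plogis(stats::qlogis(beta[, tum[1:10]]) + offset)
  beta[, tum[11:20]] <- stats::plogis(stats::qlogis(beta[, tum[11:20]]) - offset)
  res <- batch_vs_batch_dm_corruption(beta, tum[1:10], tum[11:20], nor)
  expect_gt(res$k, 50)              # plenty of spurious DM calls
  expect_lt(res$consistency, 0.5)   # directions mostly opposite
})
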