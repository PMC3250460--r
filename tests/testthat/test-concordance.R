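make_results <- function(gene_id, direction, effect, significant) {
  data.frame(gene_id = gene_id, direction = direction, effect = effect,
             significant = significant, stringsAsFactors = FALSE)
}

test_that("concordance rate arithmetic reproduces the printed regime", {
  # 98 of 107 hypermethylated DE genes down-regulated -> 91.6%
  n <- 400
  genes <- sprintf("g%03d", 1:n)
  dm_dir <- c(rep("hyper", 107), rep("hypo", 50), rep("hyper", n - 157))
  dm_sig <- c(rep(TRUE, 157), rep(FALSE, n - 157))
  de_dir <- c(rep("down", 98), rep("up", 9), rep("down", 30), rep("up", 20),
              rep("down", n - 157))
  de_sig <- c(rep(TRUE, 157), rep(FALSE, n - 157))
  dm <- make_results(genes, dm_dir, ifelse(dm_dir == "hyper", 0.2, -0.2),
                     dm_sig)
  de <- make_results(genes, de_dir, ifelse(de_dir == "down", -1.5, 1.5),
                     de_sig)
  r <- concordance_analysis(dm, de)
  expect_equal(r$k_hyper_de, 107)
  expect_equal(r$x_down, 98)
  expect_equal(round(100 * r$rate_hyper, 1), 91.6)
  expect_lt(r$p_hyper, 1e-5)
})

test_that("degenerate counts give rate 0 with p = 1, or not-applicable", {
  genes <- letters[1:10]
  dm <- make_results(genes, c(rep("hyper", 5), rep("hypo", 5)),
                     c(rep(0.2, 5), rep(-0.2, 5)), TRUE)
  de <- make_results(genes, rep("up", 10), rep(1, 10), TRUE)
  r <- concordance_analysis(dm, de)
  expect_equal(r$rate_hyper, 0)       # x_down = 0 among 5 hyper DE genes
  expect_equal(r$p_hyper, 1)          # P(X >= 0) = 1
  de2 <- de; de2$significant <- FALSE
  r2 <- concordance_analysis(dm, de2)
  expect_true(is.na(r2$rate_hyper))
  expect_true(is.na(r2$p_hyper))
  expect_error(concordance_analysis(dm[0, ], de), "empty universe")
})

test_that("hypergeometric tails match brute-force enumeration for N <= 25", {
  for (N in c(10, 20, 25)) {
    for (K in c(3, 5, N %/% 2)) {
      for (n in c(2, 5, K)) {
        for (x in 0:min(K, n)) {
          expect_equal(
            stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE),
            brute_hyper_tail(x, N, K, n), tolerance = 1e-12,
            info = sprintf("N=%d K=%d n=%d x=%d", N, K, n, x))
        }
      }
    }
  }
  # the report's p uses exactly this tail
  genes <- sprintf("g%02d", 1:20)
  dm <- make_results(genes, c(rep("hyper", 5), rep("hypo", 15)),
                     c(rep(0.2, 5), rep(-0.2, 15)),
                     c(rep(TRUE, 5), rep(FALSE, 15)))
  de <- make_results(genes, c(rep("down", 4), "up",
                              rep("down", 6), rep("up", 9)),
                     rep(c(-1, 1, -1, 1), c(4, 1, 6, 9)), TRUE)
  r <- concordance_analysis(dm, de)
  expect_equal(r$N, 20)
  expect_equal(r$p_hyper,
               brute_hyper_tail(r$x_down, r$N, r$n_down, r$k_hyper_de),
               tolerance = 1e-12)
})

test_that("a global sign flip mirrors the hyper and hypo sections", {
  set.seed(12)
  genes <- sprintf("g%03d", 1:100)
  dm <- make_results(genes,
                     sample(c("hyper", "hypo"), 100, TRUE),
                     stats::runif(100, -0.4, 0.4),
                     stats::runif(100) < 0.5)
  dm$effect <- ifelse(dm$direction == "hyper", abs(dm$effect), -abs(dm$effect))
  de <- make_results(genes, sample(c("up", "down"), 100, TRUE),
                     stats::runif(100, -2, 2), stats::runif(100) < 0.5)
  de$effect <- ifelse(de$direction == "up", abs(de$effect), -abs(de$effect))
  r <- concordance_analysis(dm, de)
  flip_dm <- dm
  flip_dm$direction <- ifelse(dm$direction == "hyper", "hypo", "hyper")
  flip_dm$effect <- -dm$effect
  flip_de <- de
  flip_de$direction <- ifelse(de$direction == "up", "down", "up")
  flip_de$effect <- -de$effect
  rf <- concordance_analysis(flip_dm, flip_de)
  expect_equal(r$k_hyper_de, rf$k_hypo_de)
  expect_equal(r$x_down, rf$x_up)
  expect_equal(r$rate_hyper, rf$rate_hypo)
  expect_equal(r$p_hyper, rf$p_hypo)
})

test_that("the threshold sweep enumerates the grid and tightens filters", {
  cfg <- simulation_config(n_probes = 600, frac_dm = 0.2,
                           n_pairs_per_batch = 20, n_batches = 1,
                           concordance_hyper = 0.95, seed = 9)
  co <- generate_methylation_cohort(cfg)
  ex <- generate_expression_cohort(cfg, co$truth)
  dm <- dm_ttest(co$beta, co$sheet, paired = TRUE,
                 annotation = co$annotation)
  de <- sam_de(ex$expr, ex$sheet, fdr = 0.01, n_permutations = 80, seed = 2)
  de$gene_id <- de$id
  sweep <- concordance_by_threshold_sweep(dm, de,
                                          delta_beta_grid = c(0, 0.15, 0.3),
                                          fc_grid = c(1, 2))
  expect_equal(nrow(sweep), 6)
  # stricter Delta-beta cannot admit more hyper DE genes
  base <- sweep[sweep$fc_min == 1, ]
  expect_true(all(diff(base$k_hyper_de[order(base$delta_beta_min)]) <= 0))
  expect_error(concordance_by_threshold_sweep(dm, de, numeric(0), 1),
               "empty grid")
})

test_that("all-null data keep rates near the background down fraction", {
  rates <- vapply(1:10, function(s) {
    set.seed(s)
    genes <- sprintf("g%03d", 1:300)
    dm <- make_results(genes, sample(c("hyper", "hypo"), 300, TRUE),
                       stats::runif(300, -0.3, 0.3),
                       stats::runif(300) < 0.3)
    de_dir <- sample(c("up", "down"), 300, TRUE)
    de <- make_results(genes, de_dir, ifelse(de_dir == "up", 1, -1),
                       stats::runif(300) < 0.3)
    r <- concordance_analysis(dm, de)
    r$rate_hyper - r$n_down / (r$n_down + r$n_up)
  }, 0.0)
  expect_lt(abs(mean(rates)), 0.12)
})
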