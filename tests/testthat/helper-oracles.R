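# Independent brute-force oracles used to validate the package's
# statistics, plus small fixture builders.  Each oracle follows the
# definition directly, not the implementation under test.

# P(X >= x) for X ~ Binomial(k, 1/2) by term-wise enumeration.
brute_binomial_tail <- function(x, k) {
  sum(choose(k, x:k)) / 2^k
}

# P(X >= x) for X ~ Hypergeometric(N population, K successes, n draws)
# by enumeration of the probability mass.
brute_hyper_tail <- function(x, N, K, n) {
  xs <- max(0, x):min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# BH step-up from its definition: q_i = min_{j: p_(j) >= p_(i)} m p_(j) / j.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Exhaustive-permutation SAM for tiny two-group matrices: returns d for
# every label assignment plus the observed one, following the definition
# d = (m1 - m2) / (s + s0) with Tusher's pooled standard error.
brute_sam_all_perms <- function(x, n1, s0) {
  d_for <- function(idx1) {
    x1 <- x[, idx1, drop = FALSE]
    x2 <- x[, -idx1, drop = FALSE]
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
    s <- sqrt((1 / ncol(x1) + 1 / ncol(x2)) * ss / (ncol(x) - 2))
    (m1 - m2) / (s + s0)
  }
  perms <- utils::combn(ncol(x), n1)
  list(observed = d_for(seq_len(n1)),
       all = apply(perms, 2, d_for))
}

# Two-group sample sheet over the columns of a matrix.
two_group_sheet <- function(mat, n_tumour, paired = FALSE) {
  n <- ncol(mat)
  sheet <- data.frame(
    sample_id = colnames(mat),
    group = rep(c("tumour", "normal"), c(n_tumour, n - n_tumour)),
    batch = "b1", stringsAsFactors = FALSE)
  if (paired)
    sheet$patient_id <- rep(sprintf("pt%02d", seq_len(n_tumour)), 2)
  sheet
}

# Named random matrix fixture.
rand_matrix <- function(nrow, ncol, seed, rfun = stats::rnorm, ...) {
  set.seed(seed)
  matrix(rfun(nrow * ncol, ...), nrow,
         dimnames = list(sprintf("f%04d", seq_len(nrow)),
                         sprintf("s%03d", seq_len(ncol))))
}
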