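# Shared fixtures: random tables and naive single-formula oracles used to
# cross-check the packaged implementations.

random_count_table <- function(n_samples = 5, n_asvs = 30, lambda = 2,
                               seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(n_samples * n_asvs, lambda),
                nrow = n_samples,
                dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                                sprintf("a%03d", seq_len(n_asvs))))
    # guarantee no empty sample and no empty ASV column
    for (i in seq_len(n_samples)) {
      if (sum(m[i, ]) == 0) m[i, sample.int(n_asvs, 1)] <- 1L
    }
    m <- m[, colSums(m) > 0, drop = FALSE]
    count_table(m)
  })
}

random_abundance_row <- function(n_asvs = 40, seed = 1) {
  withr::with_seed(seed, {
    x <- stats::rlnorm(n_asvs, 0, 1.5)
    x / sum(x)
  })
}

# Naive, formula-at-a-time evaluations (independent of div_components).
naive_margalef <- function(row) (sum(row > 0) - 1) / log(sum(row))
naive_menhinick <- function(row) sum(row > 0) / sqrt(sum(row))
naive_goods <- function(row) 1 - sum(row == 1) / sum(row)
naive_hill <- function(p, q) {
  p <- p[p > 0]
  if (q == 1) exp(-sum(p * log(p))) else sum(p^q)^(1 / (1 - q))
}

# Expected richness by an independent route: per-ASV absence probability
# from the hypergeometric density (stats::dhyper), no log-space binomials.
naive_expected_richness <- function(row, m) {
  n <- sum(row)
  ni <- row[row > 0]
  sum(1 - stats::dhyper(0, ni, n - ni, m))
}

small_read_table <- function() {
  read_table(list(s1 = c("x", "x", "y"), s2 = c("y", "z", "z", "z")))
}
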