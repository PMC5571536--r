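# Independent oracles and small fixture builders shared across tests.

# Brute-force Benjamini-Hochberg step-up: literal application of
# q_(i) = min_{j >= i} (m * p_(j) / j), clipped to 1, stable in ties.
bh_bruteforce <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p)                      # stable sort
  ps <- p[ord]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Brute-force upper hypergeometric tail P(X >= k) by direct summation of
# binomial coefficients.
fisher_tail_bruteforce <- function(N, K, n, k) {
  kk <- seq(k, min(K, n))
  if (!length(kk) || k < 0) return(1)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Small expression matrix with t tissues x g groups x r replicates; values
# supplied or drawn from a callback(n_genes, sample_index).
tiny_matrix <- function(values, genes = NULL, samples = NULL,
                        tissues = NULL, groups = NULL) {
  genes <- genes %||% sprintf("g%d", seq_len(nrow(values)))
  samples <- samples %||% sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  md <- data.frame(sample_id = samples,
                   tissue = tissues %||% rep("T1", ncol(values)),
                   group = groups %||% rep("G1", ncol(values)),
                   stringsAsFactors = FALSE)
  expression_matrix(values, md)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a som_input directly from a profile matrix (rows centered here).
som_input_from <- function(profiles, gene_ids = NULL) {
  profiles <- profiles - rowMeans(profiles)
  structure(list(gene_ids = gene_ids %||%
                   sprintf("g%d", seq_len(nrow(profiles))),
                 condition_labels = sprintf("c%d", seq_len(ncol(profiles))),
                 profiles = unname(profiles)),
            class = "som_input")
}

# Three well-separated zero-sum archetypes of unit norm in 6 dimensions,
# `n_per` genes each with Gaussian coordinate noise.
archetype_profiles <- function(n_per = 50, noise_sd = 0.1, seed = 1) {
  arch <- rbind(c(1, -1, 0, 0, 0, 0),
                c(0, 0, 1, -1, 0, 0),
                c(0, 0, 0, 0, 1, -1)) / sqrt(2)
  labels <- rep(1:3, each = n_per)
  set.seed(seed)
  profiles <- arch[labels, ] +
    matrix(rnorm(6 * length(labels), 0, noise_sd), ncol = 6)
  list(input = som_input_from(profiles), labels = labels)
}

# Adjusted Rand index (for environments without mclust); tests prefer
# mclust::adjustedRandIndex when available.
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  nc2 <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / nc2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
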