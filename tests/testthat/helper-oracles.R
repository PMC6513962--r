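# Independent oracles and small dataset builders shared across tests.
# Oracles deliberately avoid the code paths they check.

# Naive per-pair Spearman via stats::cor on each pair of rows.
naive_spearman <- function(values) {
  g <- nrow(values)
  ids <- rownames(values)
  out <- list()
  k <- 0L
  for (i in seq_len(g - 1)) {
    for (j in (i + 1):g) {
      k <- k + 1L
      out[[k]] <- data.frame(
        gene_i = min(ids[i], ids[j]), gene_j = max(ids[i], ids[j]),
        r = stats::cor(values[i, ], values[j, ], method = "spearman")
      )
    }
  }
  res <- do.call(rbind, out)
  res[order(res$gene_i, res$gene_j), ]
}

# Direct step-up implementation of the Benjamini-Yekutieli adjustment.
by_stepup <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj <- pmin(1, m * cm * p[o] / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force hypergeometric upper tail P(X >= x) by enumeration.
hyper_tail_enum <- function(x, k, K, n) {
  support <- max(0, k - (n - K)):min(k, K)
  probs <- choose(K, support) * choose(n - K, k - support) / choose(n, k)
  sum(probs[support >= x])
}

# Two-gene-block spec: `n_pairs` disjoint pairs with the given latent
# correlations, plus optional independent background genes.
pair_block_spec <- function(n_pairs, rho_a, rho_b, n = c(200L, 200L),
                            n_background = 0L, seed = 1L, mean_sd = 2) {
  rho_a <- rep_len(rho_a, n_pairs)
  rho_b <- rep_len(rho_b, n_pairs)
  blocks <- lapply(seq_len(n_pairs), function(i) {
    block_spec(c(2 * i - 1, 2 * i), rho_a[i], rho_b[i])
  })
  sim_spec(2L * n_pairs + n_background, n, blocks = blocks,
           seed = seed, mean_sd = mean_sd)
}

# The planted (non-background) pairs of a dataset as a pair data frame.
truth_pairs <- function(dataset) {
  dataset$truth$pairs[, c("gene_i", "gene_j")]
}
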