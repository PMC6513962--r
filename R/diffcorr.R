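#' Fisher's variance-stabilizing z-transform
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`; an odd function mapping
#' (-1, 1) onto the real line, under which sample correlations are
#' approximately normal with variance `1 / (n - 3)`.
#'
#' @param r Correlation(s) with |r| < 1.
#' @return Transformed value(s).
#' @export
#' @examples
#' fisher_z(0.9) # ~1.472
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1 for Fisher's z", call. = FALSE)
  atanh(r)
}

#' Correlation-difference test between two conditions
#'
#' The pipeline's core statistic: both correlations are Fisher-transformed
#' and their difference standardized,
#' `Z = (atanh(r_A) - atanh(r_B)) / sqrt(1/(n_A - 3) + 1/(n_B - 3))`,
#' with a two-sided standard normal p-value. Swapping conditions negates Z
#' and leaves p unchanged.
#'
#' @param r_a,r_b Per-condition correlations, |r| < 1 (vectorized).
#' @param n_a,n_b Per-condition sample sizes, >= 4.
#' @return A tibble with columns `Z` and `p`.
#' @export
#' @examples
#' dce_test(0.8, 103, 0.2, 103) # Z ~ 6.34
dce_test <- function(r_a, n_a, r_b, n_b) {
  if (any(c(n_a, n_b) <= 3)) {
    stop("n must be >= 4 (difference variance undefined otherwise)", call. = FALSE)
  }
  z <- (fisher_z(r_a) - fisher_z(r_b)) / sqrt(1 / (n_a - 3) + 1 / (n_b - 3))
  tibble::tibble(Z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up adjustment valid under arbitrary dependence:
#' `p_adj(i) = min over j >= i of min(1, m * c(m) * p_(j) / j)` with
#' `c(m) = sum_{k=1..m} 1/k`, applied jointly over the full tested family.
#'
#' @param p Numeric vector of raw p-values in \\[0, 1\\].
#' @return Adjusted p-values, order-preserving and >= the raw values.
#' @export
by_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BY")
}

#' Classify how a pair's co-expression changed
#'
#' Decision tree over the per-condition co-expression calls at `alpha_co`:
#' significant only in A -> `A_only`; only in B -> `B_only`; in both with
#' the same sign -> `increased` / `decreased` by |r|; in both with opposite
#' signs -> `reversed_neg_to_pos` / `reversed_pos_to_neg` (named for the
#' B-to-A direction of change); otherwise `neither`. The classes partition
#' any input set.
#'
#' @param r_a,r_b Per-condition correlations (vectorized).
#' @param p_a,p_b Per-condition co-expression p-values.
#' @param alpha_co Co-expression significance cutoff (default 0.01).
#' @return Factor with levels `A_only`, `B_only`, `increased`, `decreased`,
#'   `reversed_neg_to_pos`, `reversed_pos_to_neg`, `neither`.
#' @export
classify_pair <- function(r_a, p_a, r_b, p_b, alpha_co = 0.01) {
  sig_a <- p_a < alpha_co
  sig_b <- p_b < alpha_co
  both <- sig_a & sig_b
  same <- sign(r_a) == sign(r_b)
  tied <- both & same & abs(r_a) == abs(r_b)
  if (any(tied)) {
    warning(sum(tied), " pair(s) significant in both conditions with |r_A| = |r_B|; ",
            "classed 'neither'", call. = FALSE)
  }
  cls <- dplyr::case_when(
    sig_a & !sig_b ~ "A_only",
    sig_b & !sig_a ~ "B_only",
    tied ~ "neither",
    both & same & abs(r_a) > abs(r_b) ~ "increased",
    both & same ~ "decreased",
    both & r_b < 0 ~ "reversed_neg_to_pos",
    both ~ "reversed_pos_to_neg",
    .default = "neither"
  )
  factor(cls, levels = dce_classes())
}

dce_classes <- function() {
  c("A_only", "B_only", "increased", "decreased",
    "reversed_neg_to_pos", "reversed_pos_to_neg", "neither")
}

#' Differential co-expression table for two conditions
#'
#' Joins the two per-condition pair tables on the canonical pair key, runs
#' [dce_test()] on every shared pair, adjusts the full family with
#' [by_adjust()], and classifies each change with [classify_pair()]. This is
#' the pipeline's main verb.
#'
#' @param pairs_a,pairs_b Per-condition tables from [coexpression_table()]
#'   (columns `gene_i`, `gene_j`, `r`, `n`, `p`).
#' @param alpha_co Co-expression cutoff fed to [classify_pair()].
#' @return A `dce_tbl` tibble: `gene_i`, `gene_j`, `r_a`, `r_b`, `n_a`,
#'   `n_b`, `p_a`, `p_b`, `Z`, `p`, `p_adj`, `class`.
#' @export
dce_table <- function(pairs_a, pairs_b, alpha_co = 0.01) {
  joined <- dplyr::inner_join(
    pairs_a, pairs_b,
    by = c("gene_i", "gene_j"), suffix = c("_a", "_b")
  )
  if (nrow(joined) == 0) stop("no shared pairs between the two tables", call. = FALSE)
  if (nrow(joined) < max(nrow(pairs_a), nrow(pairs_b))) {
    warning("pair universes differ; using the ", nrow(joined), " shared pairs",
            call. = FALSE)
  }
  test <- dce_test(joined$r_a, joined$n_a, joined$r_b, joined$n_b)
  out <- dplyr::mutate(
    joined,
    Z = test$Z, p = test$p, p_adj = by_adjust(test$p),
    class = classify_pair(.data$r_a, .data$p_a, .data$r_b, .data$p_b,
                          alpha_co = alpha_co)
  )
  class(out) <- c("dce_tbl", class(out))
  out
}

#' Summarize change classes among significant pairs
#'
#' Counts the change classes among pairs with `p_adj < cutoff` and reports
#' the strengthened-to-weakened ratio
#' `(A_only + increased) / (B_only + decreased)` -- the headline summary of
#' whether co-expression is globally gained or lost in condition A.
#'
#' @param dce A [dce_table()] result.
#' @param cutoff Adjusted-p cutoff defining the significant set (default 0.01).
#' @return A `change_summary`: list with `counts` (tibble `class`, `n`,
#'   `fraction`), `total`, and `ratio` (`Inf` when nothing weakened).
#' @export
change_summary <- function(dce, cutoff = 0.01) {
  sig <- dce[dce$p_adj < cutoff, ]
  if (nrow(sig) == 0) stop("no pairs significant at p_adj < ", cutoff, call. = FALSE)
  counts <- tibble::tibble(class = factor(dce_classes(), levels = dce_classes())) |>
    dplyr::left_join(dplyr::count(sig, .data$class), by = "class") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  fraction = .data$n / nrow(sig))
  num <- sum(counts$n[counts$class %in% c("A_only", "increased")])
  den <- sum(counts$n[counts$class %in% c("B_only", "decreased")])
  ratio <- if (den == 0) Inf else num / den
  if (is.infinite(ratio)) {
    warning("no weakened pairs; strengthened/weakened ratio is infinite", call. = FALSE)
  }
  structure(list(counts = counts, total = nrow(sig), ratio = ratio),
            class = "change_summary")
}

#' @export
print.change_summary <- function(x, ...) {
  cat("<change_summary> ", x$total, " significant pairs; strengthened/weakened = ",
      format(x$ratio, digits = 3), "\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Half-sample stability of tracked correlations
#'
#' For each tracked pair, repeatedly draws floor(n/2) samples without
#' replacement and records the mean and sd of the recomputed Spearman
#' correlation: a direct measure of how stable each observed correlation is
#' under sample selection.
#'
#' @param values Gene-by-sample matrix for one condition (>= 8 samples).
#' @param pairs Data frame of tracked pairs (`gene_i`, `gene_j`).
#' @param rounds Number of resampling rounds (default 100, >= 2).
#' @param seed Integer seed.
#' @return A tibble `gene_i`, `gene_j`, `mean_r`, `sd_r`, `rounds`.
#' @export
half_sample_stability <- function(values, pairs, rounds = 100L, seed = 1L) {
  values <- check_matrix(values, min_samples = 8)
  if (rounds < 2) stop("rounds must be >= 2", call. = FALSE)
  pairs <- canonical_pair(pairs$gene_i, pairs$gene_j)
  genes <- unique(c(pairs$gene_i, pairs$gene_j))
  sub <- values[genes, , drop = FALSE]
  n <- ncol(sub)
  half <- floor(n / 2)
  set.seed(seed)
  draws <- matrix(NA_real_, nrow = nrow(pairs), ncol = rounds)
  for (t in seq_len(rounds)) {
    cols <- sample.int(n, half)
    u <- rank_rows_scaled(sub[, cols, drop = FALSE])
    draws[, t] <- rowSums(u[pairs$gene_i, , drop = FALSE] *
                            u[pairs$gene_j, , drop = FALSE])
  }
  tibble::tibble(
    gene_i = pairs$gene_i, gene_j = pairs$gene_j,
    mean_r = rowMeans(draws),
    sd_r = apply(draws, 1, stats::sd),
    rounds = as.integer(rounds)
  )
}

#' Permutation null for tracked correlations
#'
#' Per round, every gene's sample labels are permuted independently (so each
#' pair sees a wrong sample mapping and all pair structure is destroyed) and
#' the tracked correlations recomputed; reports the per-pair null mean and
#' the 2.5% / 97.5% / 99.5% null quantiles, giving a confidence range for
#' each observed correlation.
#'
#' @inheritParams half_sample_stability
#' @return A tibble `gene_i`, `gene_j`, `null_mean`, `q025`, `q975`, `q995`,
#'   `rounds`.
#' @export
shuffle_null <- function(values, pairs, rounds = 100L, seed = 1L) {
  values <- check_matrix(values, min_samples = 8)
  if (rounds < 2) stop("rounds must be >= 2", call. = FALSE)
  pairs <- canonical_pair(pairs$gene_i, pairs$gene_j)
  genes <- unique(c(pairs$gene_i, pairs$gene_j))
  u0 <- rank_rows_scaled(values[genes, , drop = FALSE])
  n <- ncol(u0)
  set.seed(seed)
  draws <- matrix(NA_real_, nrow = nrow(pairs), ncol = rounds)
  for (t in seq_len(rounds)) {
    u <- t(apply(u0, 1, function(row) row[sample.int(n)]))
    rownames(u) <- rownames(u0)
    draws[, t] <- rowSums(u[pairs$gene_i, , drop = FALSE] *
                            u[pairs$gene_j, , drop = FALSE])
  }
  qs <- t(apply(draws, 1, stats::quantile, probs = c(0.025, 0.975, 0.995)))
  tibble::tibble(
    gene_i = pairs$gene_i, gene_j = pairs$gene_j,
    null_mean = rowMeans(draws),
    q025 = qs[, 1], q975 = qs[, 2], q995 = qs[, 3],
    rounds = as.integer(rounds)
  )
}
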