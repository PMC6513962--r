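#' All-pairs Spearman correlation, computed blockwise
#'
#' Ranks each gene once (average ranks for ties) and accumulates blocked
#' cross-products of the scaled rank matrix, so memory stays
#' O(block^2 + genes x samples) while matching the naive per-pair Spearman
#' to near machine precision. Pairs are emitted once each under the
#' canonical lexicographic key (`gene_i < gene_j`), in deterministic order.
#'
#' @param values Numeric gene-by-sample matrix (>= 4 samples, no constant
#'   genes -- see [filter_genes()]).
#' @param block_size Genes per block (default 500).
#' @return A tibble with columns `gene_i`, `gene_j`, `r`, `n`.
#' @export
#' @examples
#' m <- matrix(rnorm(5 * 30), 5, dimnames = list(letters[1:5], NULL))
#' spearman_all_pairs(m)
spearman_all_pairs <- function(values, block_size = 500L) {
  values <- check_matrix(values, min_samples = 4)
  values <- values[order(rownames(values)), , drop = FALSE]
  u <- rank_rows_scaled(values)
  g <- nrow(u)
  n <- ncol(u)
  ids <- rownames(u)
  starts <- seq(1L, g, by = block_size)
  out <- vector("list", length(starts) * (length(starts) + 1L) / 2L)
  k <- 0L
  for (bi in seq_along(starts)) {
    i0 <- starts[bi]
    i1 <- min(i0 + block_size - 1L, g)
    ui <- u[i0:i1, , drop = FALSE]
    for (bj in bi:length(starts)) {
      j0 <- starts[bj]
      j1 <- min(j0 + block_size - 1L, g)
      rr <- tcrossprod(ui, u[j0:j1, , drop = FALSE])
      if (bi == bj) {
        idx <- which(upper.tri(rr), arr.ind = TRUE)
      } else {
        idx <- as.matrix(expand.grid(row = seq_len(nrow(rr)),
                                     col = seq_len(ncol(rr))))
      }
      k <- k + 1L
      out[[k]] <- tibble::tibble(
        gene_i = ids[i0 + idx[, 1] - 1L],
        gene_j = ids[j0 + idx[, 2] - 1L],
        r = rr[idx]
      )
    }
  }
  res <- dplyr::arrange(dplyr::bind_rows(out[seq_len(k)]), .data$gene_i, .data$gene_j)
  res$n <- n
  res
}

#' Spearman correlation for a given list of gene pairs
#'
#' Same statistic as [spearman_all_pairs()] restricted to the supplied
#' pairs; avoids materializing all G(G-1)/2 pairs when only planted or
#' selected pairs are of interest.
#'
#' @param values Numeric gene-by-sample matrix.
#' @param pairs Data frame with columns `gene_i`, `gene_j`.
#' @return A tibble `gene_i`, `gene_j`, `r`, `n` in canonical pair order of
#'   the input rows.
#' @export
spearman_pairs <- function(values, pairs) {
  values <- check_matrix(values, min_samples = 4)
  pairs <- canonical_pair(pairs$gene_i, pairs$gene_j)
  genes <- unique(c(pairs$gene_i, pairs$gene_j))
  missing <- setdiff(genes, rownames(values))
  if (length(missing)) {
    stop("pairs refer to genes absent from the matrix: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  u <- rank_rows_scaled(values[genes, , drop = FALSE])
  r <- rowSums(u[pairs$gene_i, , drop = FALSE] * u[pairs$gene_j, , drop = FALSE])
  tibble::tibble(gene_i = pairs$gene_i, gene_j = pairs$gene_j,
                 r = unname(r), n = ncol(values))
}

#' Per-pair co-expression p-value
#'
#' Two-sided significance of a single correlation. Default transforms r with
#' Fisher's z (`z = atanh(r) * sqrt(n - 3)`, standard normal tail), for
#' internal consistency with the correlation-difference statistic; the exact
#' t-test (`t = r * sqrt((n-2)/(1-r^2))` on n-2 df) is available.
#'
#' @param r Correlation(s) in \\[-1, 1\\].
#' @param n Sample size(s), >= 4.
#' @param method `"fisher_z"` (default) or `"t"`.
#' @return p-value(s) in \\[0, 1\\], monotone decreasing in |r| and in n.
#' @export
#' @examples
#' coexpression_pvalue(0.5, 103) # ~4e-8
coexpression_pvalue <- function(r, n, method = c("fisher_z", "t")) {
  method <- match.arg(method)
  if (any(n < 4)) stop("n must be >= 4", call. = FALSE)
  if (any(abs(r) > 1)) stop("|r| must be <= 1", call. = FALSE)
  p <- rep(0, length(r))
  at_one <- abs(r) == 1
  if (any(at_one)) warning("|r| = 1 encountered; returning p = 0", call. = FALSE)
  ok <- !at_one
  if (any(ok)) {
    n2 <- rep_len(n, length(r))[ok]
    p[ok] <- switch(
      method,
      fisher_z = 2 * stats::pnorm(-abs(atanh(r[ok])) * sqrt(n2 - 3)),
      t = 2 * stats::pt(-abs(r[ok]) * sqrt((n2 - 2) / (1 - r[ok]^2)), df = n2 - 2)
    )
  }
  p
}

#' Per-condition co-expression pair table
#'
#' Convenience composition: [spearman_all_pairs()] plus
#' [coexpression_pvalue()], yielding the `gene_i, gene_j, r, n, p` table the
#' downstream differential analysis consumes.
#'
#' @inheritParams spearman_all_pairs
#' @inheritParams coexpression_pvalue
#' @return A tibble `gene_i`, `gene_j`, `r`, `n`, `p`.
#' @export
coexpression_table <- function(values, block_size = 500L,
                               method = c("fisher_z", "t")) {
  res <- spearman_all_pairs(values, block_size = block_size)
  res$p <- coexpression_pvalue(res$r, res$n, method = match.arg(method))
  res
}

#' Soft-threshold connectivity per gene
#'
#' The weighted-network degree: `k_g = sum over partners |r|^beta`, with
#' unsigned adjacency and self excluded. `beta = 6` is the conventional soft
#' power for unsigned co-expression networks.
#'
#' @param pairs Complete pair table for one condition (columns `gene_i`,
#'   `gene_j`, `r`) covering all G(G-1)/2 pairs of its gene universe.
#' @param beta Non-negative integer soft power (default 6).
#' @return A tibble `gene`, `k`, `beta`, sorted by gene.
#' @export
connectivity <- function(pairs, beta = 6L) {
  genes <- sort(unique(c(pairs$gene_i, pairs$gene_j)))
  expected <- choose(length(genes), 2)
  keys <- pair_key(pairs$gene_i, pairs$gene_j)
  if (anyDuplicated(keys)) stop("duplicate pairs in table", call. = FALSE)
  if (nrow(pairs) != expected) {
    stop("incomplete pair table: ", expected - nrow(pairs),
         " missing pair(s) over ", length(genes), " genes", call. = FALSE)
  }
  w <- abs(pairs$r)^beta
  k <- vapply(
    split(c(w, w), c(pairs$gene_i, pairs$gene_j)),
    sum, numeric(1)
  )
  tibble::tibble(gene = names(k), k = unname(k), beta = as.integer(beta)) |>
    dplyr::arrange(.data$gene)
}

#' Spearman correlation of two numeric vectors
#'
#' Shared kernel for trait association and correlation-of-correlations:
#' standard Spearman with average ranks, with explicit errors for the
#' degenerate inputs silently tolerated by [stats::cor()].
#'
#' @param u,v Equal-length numeric vectors, length >= 4, non-constant.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A single correlation.
#' @export
cor_vectors <- function(u, v, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(u) != length(v)) stop("u and v must have equal length", call. = FALSE)
  if (length(u) < 4) stop("need length >= 4", call. = FALSE)
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  stats::cor(u, v, method = method)
}
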