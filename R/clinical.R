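#' Per-gene correlation with a clinical trait
#'
#' Spearman (default) correlation of every gene's expression with a trait
#' across samples, using only samples with an observed trait value.
#'
#' @param values Gene-by-sample matrix.
#' @param trait Numeric trait vector, aligned with (or named by) the matrix
#'   columns; may contain `NA`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A tibble `gene`, `r`, `n`.
#' @export
trait_correlation <- function(values, trait, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  values <- check_matrix(values)
  if (!is.null(names(trait)) && all(colnames(values) %in% names(trait))) {
    trait <- trait[colnames(values)]
  }
  if (length(trait) != ncol(values)) {
    stop("trait must have one value per sample", call. = FALSE)
  }
  ok <- !is.na(trait)
  if (sum(ok) < 4) stop("need >= 4 samples with an observed trait", call. = FALSE)
  trait <- trait[ok]
  if (stats::sd(trait) == 0) stop("trait is constant", call. = FALSE)
  r <- drop(stats::cor(t(values[, ok, drop = FALSE]), trait, method = method))
  tibble::tibble(gene = rownames(values), r = unname(r), n = sum(ok))
}

#' First-order partial correlation from three pairwise correlations
#'
#' `r_xy.z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))`:
#' the correlation of x and y after removing the linear effect of z.
#' Equivalent to correlating the residuals of x and y each regressed on z.
#'
#' @param r_xy,r_xz,r_yz Pairwise correlations (vectorized); |r_xz| and
#'   |r_yz| must be < 1.
#' @return Partial correlation(s) in \\[-1, 1\\].
#' @export
#' @examples
#' partial_correlation(0.6, 0.5, 0.5) # ~0.467
partial_correlation <- function(r_xy, r_xz, r_yz) {
  if (any(abs(c(r_xz, r_yz)) >= 1)) {
    stop("conditioning correlations must have |r| < 1", call. = FALSE)
  }
  den <- sqrt((1 - r_xz^2) * (1 - r_yz^2))
  if (any(den < 1e-12)) stop("degenerate denominator in partial correlation", call. = FALSE)
  (r_xy - r_xz * r_yz) / den
}

#' Partial trait correlations for dysregulated gene pairs
#'
#' For each gene pair, computes both genes' marginal correlation with the
#' trait and both first-order partial correlations (each gene controlling
#' for its partner's expression), flagging where conditioning improved the
#' association (`|partial| > |marginal|`) -- the signature of combined-pair
#' effects on clinical outcome. Rank-based correlations by default,
#' consistent with the rest of the pipeline.
#'
#' @param pairs Data frame of gene pairs (`gene_i`, `gene_j`).
#' @param values Gene-by-sample matrix.
#' @param trait Numeric trait vector aligned with (or named by) the matrix
#'   columns; `NA` trait samples are dropped pairwise-complete.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A tibble with one row per pair: `gene_i`, `gene_j`, `r_pair`
#'   (gene-gene correlation), `r_i`, `r_j` (marginal trait correlations),
#'   `partial_i`, `partial_j`, `improved_i`, `improved_j`, `n`; sorted by
#'   descending max |partial|.
#' @export
pairwise_partial_table <- function(pairs, values, trait,
                                   method = c("spearman", "pearson")) {
  method <- match.arg(method)
  values <- check_matrix(values)
  if (!is.null(names(trait)) && all(colnames(values) %in% names(trait))) {
    trait <- trait[colnames(values)]
  }
  ok <- !is.na(trait)
  if (sum(ok) < 4) stop("need >= 4 samples with an observed trait", call. = FALSE)
  values <- values[, ok, drop = FALSE]
  trait <- trait[ok]
  pairs <- canonical_pair(pairs$gene_i, pairs$gene_j)
  genes <- unique(c(pairs$gene_i, pairs$gene_j))
  missing <- setdiff(genes, rownames(values))
  if (length(missing)) {
    stop("pairs refer to genes absent from the matrix: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  tr <- trait_correlation(values[genes, , drop = FALSE], trait, method = method)
  r_trait <- stats::setNames(tr$r, tr$gene)
  r_pair <- spearman_pairs(values, pairs)$r
  if (method == "pearson") {
    r_pair <- vapply(seq_len(nrow(pairs)), function(i) {
      stats::cor(values[pairs$gene_i[i], ], values[pairs$gene_j[i], ])
    }, numeric(1))
  }
  r_i <- unname(r_trait[pairs$gene_i])
  r_j <- unname(r_trait[pairs$gene_j])
  out <- tibble::tibble(
    gene_i = pairs$gene_i, gene_j = pairs$gene_j,
    r_pair = r_pair, r_i = r_i, r_j = r_j,
    partial_i = partial_correlation(r_i, r_pair, r_j),
    partial_j = partial_correlation(r_j, r_pair, r_i),
    n = length(trait)
  ) |>
    dplyr::mutate(
      improved_i = abs(.data$partial_i) > abs(.data$r_i),
      improved_j = abs(.data$partial_j) > abs(.data$r_j)
    ) |>
    dplyr::arrange(dplyr::desc(pmax(abs(.data$partial_i), abs(.data$partial_j))))
  class(out) <- c("clinical_assoc", class(out))
  out
}
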