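# Internal helpers shared across modules.

#' Derive a child seed for a named generation stage
#'
#' One global seed expands deterministically into independent per-stage seeds,
#' so adding a later stage (traits, batch effects, a second species) never
#' perturbs the draws of an earlier one. The derivation is fixed:
#' `(seed * 48271 + stage_code * 1009) mod (2^31 - 1)`.
#'
#' @param seed Integer global seed.
#' @param stage Stage name, one of `"means"`, `"cond_a"`, `"cond_b"`,
#'   `"traits"`, `"species"`, `"batch"`, `"subsample"`.
#' @return An integer seed.
#' @keywords internal
child_seed <- function(seed, stage) {
  codes <- c(means = 1, cond_a = 2, cond_b = 3, traits = 4,
             species = 5, batch = 6, subsample = 7)
  if (!stage %in% names(codes)) {
    stop("unknown seed stage: ", stage, call. = FALSE)
  }
  as.integer((as.numeric(seed) %% 2147483647 * 48271 +
                codes[[stage]] * 1009) %% 2147483647)
}

#' Canonical unordered pair keys
#'
#' Orders each gene pair lexicographically so that `gene_i < gene_j`; all
#' modules address pairs by this canonical key.
#'
#' @param gene_i,gene_j Character vectors of gene IDs.
#' @return A tibble with columns `gene_i`, `gene_j`.
#' @keywords internal
canonical_pair <- function(gene_i, gene_j) {
  if (any(gene_i == gene_j)) stop("self-pairs are not allowed", call. = FALSE)
  swap <- gene_i > gene_j
  tibble::tibble(
    gene_i = ifelse(swap, gene_j, gene_i),
    gene_j = ifelse(swap, gene_i, gene_j)
  )
}

pair_key <- function(gene_i, gene_j) {
  paste(pmin(gene_i, gene_j), pmax(gene_i, gene_j), sep = "\r")
}

check_matrix <- function(values, min_samples = 2, what = "values") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop(what, " must be a numeric gene-by-sample matrix", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%04d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%04d", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene IDs in ", what, call. = FALSE)
  }
  if (ncol(values) < min_samples) {
    stop(what, " needs at least ", min_samples, " samples", call. = FALSE)
  }
  values
}

# Row-wise ranks (average ties), then centred and scaled to unit sum of
# squares so that tcrossprod() of the result is the Spearman correlation.
rank_rows_scaled <- function(values) {
  rk <- t(apply(values, 1L, rank))
  rk <- rk - rowMeans(rk)
  ss <- sqrt(rowSums(rk^2))
  bad <- ss == 0
  if (any(bad)) {
    stop("constant gene(s) reached correlation step: ",
         paste(utils::head(rownames(values)[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  rk / ss
}
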