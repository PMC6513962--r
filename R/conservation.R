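#' Collapse microarray probes to genes
#'
#' For genes measured by multiple probes, keeps the probe with the maximum
#' mean expression across samples (ties broken by probe ID order); probes
#' with no gene mapping are dropped with a reported count.
#'
#' @param values Probe-by-sample matrix.
#' @param probe_map Data frame with columns `probe`, `gene`.
#' @return Gene-by-sample matrix.
#' @export
collapse_probes <- function(values, probe_map) {
  values <- check_matrix(values, min_samples = 1)
  probe_map <- tibble::as_tibble(as.data.frame(probe_map))
  names(probe_map)[1:2] <- c("probe", "gene")
  mapped <- rownames(values) %in% probe_map$probe
  if (any(!mapped)) {
    message("collapse_probes: dropping ", sum(!mapped), " unmapped probe(s)")
  }
  pm <- probe_map[probe_map$probe %in% rownames(values), ]
  pm$mean_expr <- rowMeans(values)[pm$probe]
  chosen <- pm |>
    dplyr::arrange(.data$gene, dplyr::desc(.data$mean_expr), .data$probe) |>
    dplyr::distinct(.data$gene, .keep_all = TRUE)
  out <- values[chosen$probe, , drop = FALSE]
  rownames(out) <- chosen$gene
  out[order(rownames(out)), , drop = FALSE]
}

#' Resolve a homolog map to one-to-one
#'
#' Many-to-many homolog records are greedily resolved by total mean
#' expression of the two mapped genes (highest first), keeping each gene on
#' each side at most once; deterministic.
#'
#' @param homologs Data frame with columns `id_a`, `id_b`.
#' @param expr_a,expr_b Expression matrices used for the mean-expression
#'   tie-break; pairs with either gene absent are dropped.
#' @return A tibble `id_a`, `id_b`, one-to-one.
#' @export
resolve_homologs <- function(homologs, expr_a, expr_b) {
  homologs <- tibble::as_tibble(as.data.frame(homologs))
  names(homologs)[1:2] <- c("id_a", "id_b")
  keep <- homologs$id_a %in% rownames(expr_a) & homologs$id_b %in% rownames(expr_b)
  h <- homologs[keep, ]
  if (!nrow(h)) stop("no homolog pairs present in both matrices", call. = FALSE)
  h$score <- rowMeans(expr_a)[h$id_a] + rowMeans(expr_b)[h$id_b]
  h <- dplyr::arrange(h, dplyr::desc(.data$score), .data$id_a, .data$id_b)
  used_a <- used_b <- character(0)
  keep_row <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    if (!(h$id_a[i] %in% used_a) && !(h$id_b[i] %in% used_b)) {
      keep_row[i] <- TRUE
      used_a <- c(used_a, h$id_a[i])
      used_b <- c(used_b, h$id_b[i])
    }
  }
  dplyr::arrange(h[keep_row, c("id_a", "id_b")], .data$id_a)
}

#' Cross-dataset expression-profile similarity
#'
#' Spearman correlation between every cross-dataset sample pair, computed
#' over the homologous gene vectors; large sample-pair sets are subsampled
#' (fixed seed) for tractability. The median summarizes how conserved the
#' expression profiles are.
#'
#' @param expr_a,expr_b Gene-by-sample matrices for the two datasets.
#' @param homologs One-to-one homolog map (`id_a`, `id_b`); see
#'   [resolve_homologs()].
#' @param max_pairs Maximum sample pairs evaluated (default 1e5).
#' @param seed Seed for the subsample.
#' @return A `profile_similarity`: list with `similarities` (numeric),
#'   `median`, `n_genes`, `n_pairs_total`.
#' @export
expression_profile_similarity <- function(expr_a, expr_b, homologs,
                                          max_pairs = 1e5, seed = 1L) {
  homologs <- tibble::as_tibble(as.data.frame(homologs))
  names(homologs)[1:2] <- c("id_a", "id_b")
  keep <- homologs$id_a %in% rownames(expr_a) & homologs$id_b %in% rownames(expr_b)
  if (!any(keep)) stop("no shared homolog pairs", call. = FALSE)
  h <- homologs[keep, ]
  if (nrow(h) < 4) stop("need >= 4 shared homologous genes", call. = FALSE)
  a <- expr_a[h$id_a, , drop = FALSE]
  b <- expr_b[h$id_b, , drop = FALSE]
  # rank each sample column over genes, then cross-correlate all column pairs
  ra <- apply(a, 2, rank)
  rb <- apply(b, 2, rank)
  ra <- scale(ra); rb <- scale(rb)
  sims <- crossprod(ra, rb) / (nrow(h) - 1)
  total <- length(sims)
  sims <- as.numeric(sims)
  if (total > max_pairs) {
    set.seed(child_seed(seed, "subsample"))
    sims <- sims[sample.int(total, max_pairs)]
  }
  structure(
    list(similarities = sims, median = stats::median(sims),
         n_genes = nrow(h), n_pairs_total = total),
    class = "profile_similarity"
  )
}

#' @export
print.profile_similarity <- function(x, ...) {
  cat("<profile_similarity> ", x$n_genes, " homologous genes; median r = ",
      format(x$median, digits = 3), " over ", length(x$similarities),
      " sample pairs\n", sep = "")
  invisible(x)
}

#' Cross-dataset co-expression conservation
#'
#' Aligns every shared unordered homolog pair across two pair tables and
#' reports: the Spearman correlation between the two correlation vectors
#' (correlation-of-correlations), the fraction of co-expressed pairs
#' (significant at `alpha` in at least one dataset, or both with
#' `scope = "both"`) whose correlations disagree in sign, and the fraction
#' of pairs with significant cross-dataset differential co-expression
#' (same [dce_test()] + [by_adjust()] machinery as the two-condition
#' analysis, at adjusted p < `alpha_dce`).
#'
#' @param pairs_a,pairs_b Per-dataset pair tables (`gene_i`, `gene_j`, `r`,
#'   `n`, `p`).
#' @param homologs One-to-one homolog map (`id_a`, `id_b`) from dataset A
#'   gene IDs to dataset B gene IDs; `NULL` when the IDs already match.
#' @param alpha Co-expression cutoff for the sign-inconsistency scope
#'   (default 0.01).
#' @param alpha_dce Adjusted-p cutoff for the cross-set DCE fraction
#'   (default 0.01).
#' @param scope `"either"` (default) or `"both"`: which pairs count as
#'   co-expressed for the sign-inconsistency fraction.
#' @return A `conservation_result`: list with `shared_pairs`, `r`
#'   (correlation-of-correlations), `sign_inconsistent_fraction`,
#'   `dce_fraction`, `n_coexpressed`.
#' @export
coexpression_conservation <- function(pairs_a, pairs_b, homologs = NULL,
                                      alpha = 0.01, alpha_dce = 0.01,
                                      scope = c("either", "both")) {
  scope <- match.arg(scope)
  b <- pairs_b
  if (!is.null(homologs)) {
    homologs <- tibble::as_tibble(as.data.frame(homologs))
    names(homologs)[1:2] <- c("id_a", "id_b")
    if (anyDuplicated(homologs$id_a) || anyDuplicated(homologs$id_b)) {
      stop("homolog map must be one-to-one; see resolve_homologs()", call. = FALSE)
    }
    to_a <- stats::setNames(homologs$id_a, homologs$id_b)
    keep <- b$gene_i %in% names(to_a) & b$gene_j %in% names(to_a)
    b <- b[keep, ]
    mapped <- canonical_pair(unname(to_a[b$gene_i]), unname(to_a[b$gene_j]))
    b$gene_i <- mapped$gene_i
    b$gene_j <- mapped$gene_j
  }
  joined <- dplyr::inner_join(pairs_a, b, by = c("gene_i", "gene_j"),
                              suffix = c("_a", "_b"))
  if (nrow(joined) < 10) {
    stop("fewer than 10 shared pairs; conservation statistic unstable", call. = FALSE)
  }
  r_cons <- cor_vectors(joined$r_a, joined$r_b, method = "spearman")
  coexpressed <- switch(scope,
                        either = joined$p_a < alpha | joined$p_b < alpha,
                        both = joined$p_a < alpha & joined$p_b < alpha)
  sign_frac <- if (any(coexpressed)) {
    mean(sign(joined$r_a[coexpressed]) != sign(joined$r_b[coexpressed]))
  } else NA_real_
  dce <- dce_test(pmin(pmax(joined$r_a, -1 + 1e-15), 1 - 1e-15), joined$n_a,
                  pmin(pmax(joined$r_b, -1 + 1e-15), 1 - 1e-15), joined$n_b)
  dce_frac <- mean(by_adjust(dce$p) < alpha_dce)
  structure(
    list(shared_pairs = nrow(joined), r = r_cons,
         sign_inconsistent_fraction = sign_frac,
         dce_fraction = dce_frac,
         n_coexpressed = sum(coexpressed)),
    class = "conservation_result"
  )
}

#' @export
print.conservation_result <- function(x, ...) {
  cat("<conservation_result> ", x$shared_pairs, " shared pairs; r = ",
      format(x$r, digits = 3), "; sign-inconsistent = ",
      format(x$sign_inconsistent_fraction, digits = 3), "; DCE fraction = ",
      format(x$dce_fraction, digits = 3), "\n", sep = "")
  invisible(x)
}
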