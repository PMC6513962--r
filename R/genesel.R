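#' Per-gene differential expression by Welch's t-test
#'
#' Two-sided Welch t-test per gene between the condition matrices, on log2
#' values (set `log2_transform = TRUE` for linear-scale input; values must
#' then be positive). Direction is the sign of mean(A) - mean(B).
#'
#' @param expr_a,expr_b Gene-by-sample matrices over the same gene universe,
#'   each with >= 2 samples.
#' @param log2_transform Log2-transform the input first (default `FALSE`,
#'   i.e. values are already on log scale).
#' @return A tibble `gene`, `t`, `p`, `direction` (`"up"` / `"down"`),
#'   `mean_a`, `mean_b`.
#' @export
de_test <- function(expr_a, expr_b, log2_transform = FALSE) {
  expr_a <- check_matrix(expr_a)
  expr_b <- check_matrix(expr_b)
  shared <- intersect(rownames(expr_a), rownames(expr_b))
  if (!length(shared)) stop("no shared genes", call. = FALSE)
  expr_a <- expr_a[shared, , drop = FALSE]
  expr_b <- expr_b[shared, , drop = FALSE]
  if (ncol(expr_a) < 2 || ncol(expr_b) < 2) {
    stop("each condition needs >= 2 samples", call. = FALSE)
  }
  if (log2_transform) {
    if (any(expr_a <= 0) || any(expr_b <= 0)) {
      stop("non-positive values; cannot log2-transform", call. = FALSE)
    }
    expr_a <- log2(expr_a)
    expr_b <- log2(expr_b)
  }
  n1 <- ncol(expr_a); n2 <- ncol(expr_b)
  m1 <- rowMeans(expr_a); m2 <- rowMeans(expr_b)
  v1 <- apply(expr_a, 1, stats::var); v2 <- apply(expr_b, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df = df)
  degen <- se2 == 0 & m1 == m2  # identical constant groups: no evidence
  t[degen] <- 0
  p[degen] <- 1
  tibble::tibble(
    gene = shared, t = unname(t), p = unname(p),
    direction = ifelse(m1 >= m2, "up", "down"),
    mean_a = unname(m1), mean_b = unname(m2)
  )
}

#' Cross-dataset consensus differential expression
#'
#' A gene is a consensus DEG when significant at `alpha` in at least
#' `min_datasets` of the supplied per-dataset DE tables; its direction is the
#' majority vote among the datasets where it is significant, and exact
#' direction ties are dropped with a warning.
#'
#' @param tables List of [de_test()]-shaped tibbles (`gene`, `p`,
#'   `direction`).
#' @param alpha Per-dataset significance cutoff (default 0.01).
#' @param min_datasets Minimum supporting datasets (default 2).
#' @return A tibble `gene`, `direction`, `n_sig`.
#' @export
consensus_de <- function(tables, alpha = 0.01, min_datasets = 2L) {
  if (!length(tables)) stop("need at least one DE table", call. = FALSE)
  universes <- lapply(tables, function(t) t$gene)
  shared <- Reduce(intersect, universes)
  if (any(lengths(universes) != length(shared))) {
    warning("inconsistent gene universes; restricting to the ", length(shared),
            "-gene intersection", call. = FALSE)
  }
  long <- dplyr::bind_rows(tables, .id = "dataset") |>
    dplyr::filter(.data$gene %in% shared, .data$p < alpha)
  votes <- long |>
    dplyr::count(.data$gene, .data$direction) |>
    tidyr::pivot_wider(names_from = "direction", values_from = "n",
                       values_fill = 0L)
  for (col in c("up", "down")) if (!col %in% names(votes)) votes[[col]] <- 0L
  votes <- dplyr::filter(votes, .data$up + .data$down >= min_datasets)
  tied <- votes$up == votes$down
  if (any(tied)) {
    warning(sum(tied), " gene(s) with tied direction votes dropped", call. = FALSE)
  }
  votes |>
    dplyr::filter(!tied) |>
    dplyr::transmute(
      gene = .data$gene,
      direction = ifelse(.data$up > .data$down, "up", "down"),
      n_sig = .data$up + .data$down
    ) |>
    dplyr::arrange(.data$gene)
}

#' Gene-set over-representation test
#'
#' One-sided hypergeometric upper tail: among `k` input genes, `x` carry the
#' annotation; the universe holds `n` genes of which `K` are annotated;
#' `p = P(X >= x)` for `X ~ Hypergeom(n, K, k)`. `mode = "literal"` instead
#' runs Fisher's exact test on the 2x2 matrix `c(x, k-x, K-x, n-k)` as some
#' legacy workflows construct it (the fourth cell is not the standard
#' contingency completion); kept for compatibility, not as the default.
#'
#' @param x Annotated genes among the input (vectorized).
#' @param k Input gene count.
#' @param K Annotated genes in the universe.
#' @param n Universe size.
#' @param mode `"standard"` (hypergeometric tail) or `"literal"`.
#' @return p-value(s) in (0, 1\\], decreasing in `x` at fixed `(k, K, n)`.
#' @export
#' @examples
#' enrichment_test(5, 10, 10, 100) # ~6.2e-5
enrichment_test <- function(x, k, K, n, mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  ok <- x >= 0 & k >= 0 & K >= 0 & x <= k & x <= K & k <= n & K <= n
  if (any(!ok)) stop("impossible counts: need 0 <= x <= min(k, K) <= n", call. = FALSE)
  if (mode == "standard") {
    stats::phyper(x - 1, K, n - K, k, lower.tail = FALSE)
  } else {
    mapply(function(x, k, K, n) {
      stats::fisher.test(matrix(c(x, k - x, K - x, n - k), ncol = 2, byrow = TRUE),
                         alternative = "greater")$p.value
    }, x, k, K, n)
  }
}

#' Per-gene DCE partner sets
#'
#' Restricts a [dce_table()] to `p_adj < cutoff` and returns each gene's
#' partner set and count (the degree in the differential co-expression
#' graph); symmetric by construction.
#'
#' @param dce A [dce_table()] result.
#' @param cutoff Adjusted-p cutoff (default 0.01).
#' @param universe Optional gene IDs to include with zero partners.
#' @return A tibble `gene`, `n_partners`, `partners` (list-column), sorted
#'   by gene.
#' @export
partner_table <- function(dce, cutoff = 0.01, universe = NULL) {
  sig <- dce[dce$p_adj < cutoff, c("gene_i", "gene_j")]
  edges <- tibble::tibble(
    gene = c(sig$gene_i, sig$gene_j),
    partner = c(sig$gene_j, sig$gene_i)
  )
  tab <- edges |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_partners = dplyr::n(),
                     partners = list(sort(.data$partner)))
  if (!is.null(universe)) {
    zero <- setdiff(universe, tab$gene)
    if (length(zero)) {
      tab <- dplyr::bind_rows(
        tab,
        tibble::tibble(gene = zero, n_partners = 0L,
                       partners = rep(list(character(0)), length(zero)))
      )
    }
  }
  dplyr::arrange(tab, .data$gene)
}

#' Per-gene summary table for dysregulated-gene selection
#'
#' Combines partner counts, differential expression, and gene-set membership
#' flags with hypergeometric enrichment of each gene's partner set against
#' the DEG, disease-gene and aging-gene sets, producing the survey table the
#' selection criteria read.
#'
#' @param dce A [dce_table()] result.
#' @param de A [de_test()] (or consensus) tibble with `gene`, `p`,
#'   `direction`.
#' @param ad_genes Character vector of disease-associated genes.
#' @param aging_genes,tf_genes Optional further annotation sets.
#' @param universe Gene universe for enrichment (default: all genes in
#'   `dce`).
#' @param cutoff_dce Adjusted-p cutoff defining partners (default 0.01).
#' @param alpha_de DE cutoff defining the DEG set (default 0.01).
#' @return A tibble with one row per gene holding `n_partners`, `de_p`,
#'   `de_direction`, membership flags `is_ad` / `is_aging` / `is_tf`, and
#'   partner-set enrichment p-values `p_enrich_deg`, `p_enrich_ad`,
#'   `p_enrich_aging`.
#' @export
gene_summary <- function(dce, de, ad_genes, aging_genes = character(0),
                         tf_genes = character(0), universe = NULL,
                         cutoff_dce = 0.01, alpha_de = 0.01) {
  universe <- universe %||% sort(unique(c(dce$gene_i, dce$gene_j)))
  n <- length(universe)
  partners <- partner_table(dce, cutoff = cutoff_dce, universe = universe)
  de <- de[de$gene %in% universe, ]
  deg_set <- de$gene[de$p < alpha_de]
  sets <- list(deg = intersect(deg_set, universe),
               ad = intersect(ad_genes, universe),
               aging = intersect(aging_genes, universe))
  enrich <- function(partner_list, set) {
    if (!length(set)) return(rep(NA_real_, length(partner_list)))
    x <- vapply(partner_list, function(p) length(intersect(p, set)), integer(1))
    k <- lengths(partner_list)
    p <- rep(NA_real_, length(k))
    pos <- k > 0
    p[pos] <- enrichment_test(x[pos], k[pos], length(set), n)
    p
  }
  partners |>
    dplyr::left_join(de[, c("gene", "p", "direction")], by = "gene") |>
    dplyr::rename(de_p = "p", de_direction = "direction") |>
    dplyr::mutate(
      de_direction = ifelse(is.na(.data$de_p) | .data$de_p >= alpha_de,
                            "none", .data$de_direction),
      is_ad = .data$gene %in% sets$ad,
      is_aging = .data$gene %in% sets$aging,
      is_tf = .data$gene %in% tf_genes,
      p_enrich_deg = enrich(.data$partners, sets$deg),
      p_enrich_ad = enrich(.data$partners, sets$ad),
      p_enrich_aging = enrich(.data$partners, sets$aging)
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_partners))
}

#' Select dysregulated hub genes
#'
#' Applies the selection criteria: a gene is selected when it has more than
#' `partner_threshold` DCE partners AND either (a) it is differentially
#' expressed at `alpha_de` and its partners are enriched with disease genes
#' at `alpha_enrich_ad`, or (b) it is itself a reported disease gene and its
#' partners are enriched with DEGs at `alpha_enrich_deg`.
#'
#' @param summary A [gene_summary()] tibble.
#' @param partner_threshold Strict partner-count threshold (default 50:
#'   "more than 50").
#' @param alpha_de DE cutoff (default 0.01).
#' @param alpha_enrich_deg Partner DEG-enrichment cutoff (default 0.01).
#' @param alpha_enrich_ad Partner disease-gene-enrichment cutoff
#'   (default 0.05).
#' @return The summary tibble with a logical `selected` column added;
#'   selected rows first, then by descending partner count.
#' @export
select_dysregulated <- function(summary, partner_threshold = 50L,
                                alpha_de = 0.01, alpha_enrich_deg = 0.01,
                                alpha_enrich_ad = 0.05) {
  need <- c("n_partners", "de_p", "is_ad", "p_enrich_deg", "p_enrich_ad")
  missing <- setdiff(need, names(summary))
  if (length(missing)) {
    stop("summary lacks required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  isf <- function(x) !is.na(x) & x
  summary |>
    dplyr::mutate(
      selected = .data$n_partners > partner_threshold &
        (isf(.data$de_p < alpha_de & .data$p_enrich_ad < alpha_enrich_ad) |
           isf(.data$is_ad & .data$p_enrich_deg < alpha_enrich_deg))
    ) |>
    dplyr::arrange(dplyr::desc(.data$selected), dplyr::desc(.data$n_partners))
}

#' Direction agreement between two DE direction maps
#'
#' Over the genes present in both maps, counts how many have the same
#' up/down direction -- e.g. disease DE direction versus an aging-trend
#' reference.
#'
#' @param directions,reference Named character vectors (gene -> `"up"` /
#'   `"down"`).
#' @return A list with `consistent`, `total`, and `fraction`.
#' @export
direction_consistency <- function(directions, reference) {
  if (!length(directions) || !length(reference)) {
    stop("both direction maps must be non-empty", call. = FALSE)
  }
  shared <- intersect(names(directions), names(reference))
  consistent <- sum(directions[shared] == reference[shared])
  list(consistent = consistent, total = length(shared),
       fraction = if (length(shared)) consistent / length(shared) else NA_real_)
}
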