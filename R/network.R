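#' Assemble the core dysregulation network
#'
#' Connects two selected genes whenever their co-expression correlation in
#' the designated condition exceeds `r_threshold` in absolute value, or
#' their differential co-expression is significant at `alpha_dce` (or both;
#' edges carry both type flags). Nodes left without any qualifying edge
#' ("islands") are removed and reported.
#'
#' @param selected Character vector of selected gene IDs.
#' @param dce A [dce_table()] result covering the selected genes.
#' @param condition Which condition's r defines co-expression edges:
#'   `"disease"` (condition A, the default) or `"max"` (larger |r| of the
#'   two).
#' @param r_threshold Co-expression edge threshold on |r| (default 0.3).
#' @param alpha_dce DCE edge cutoff on `p_adj` (default 0.01).
#' @return A `core_network`: list with `nodes` (tibble `gene`, `degree`),
#'   `edges` (tibble `gene_i`, `gene_j`, `r_a`, `r_b`, `coexpression`,
#'   `dce`, `class`), and `islands` (character).
#' @export
build_core_network <- function(selected, dce, condition = c("disease", "max"),
                               r_threshold = 0.3, alpha_dce = 0.01) {
  condition <- match.arg(condition)
  if (!length(selected)) stop("empty gene selection", call. = FALSE)
  selected <- unique(selected)
  cand <- dce[dce$gene_i %in% selected & dce$gene_j %in% selected, ]
  r_edge <- switch(condition,
                   disease = abs(cand$r_a),
                   max = pmax(abs(cand$r_a), abs(cand$r_b)))
  coex <- r_edge > r_threshold
  is_dce <- cand$p_adj < alpha_dce
  edges <- cand[coex | is_dce, ]
  edges <- tibble::tibble(
    gene_i = edges$gene_i, gene_j = edges$gene_j,
    r_a = edges$r_a, r_b = edges$r_b,
    coexpression = coex[coex | is_dce], dce = is_dce[coex | is_dce],
    class = edges$class
  )
  edges <- dplyr::arrange(edges, .data$gene_i, .data$gene_j)
  connected <- unique(c(edges$gene_i, edges$gene_j))
  islands <- sort(setdiff(selected, connected))
  deg <- table(factor(c(edges$gene_i, edges$gene_j), levels = sort(connected)))
  structure(
    list(
      nodes = tibble::tibble(gene = names(deg), degree = as.integer(deg)),
      edges = edges,
      islands = islands
    ),
    class = "core_network"
  )
}

#' @export
print.core_network <- function(x, ...) {
  cat("<core_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges (",
      sum(x$edges$coexpression), " co-expression, ", sum(x$edges$dce),
      " dce); ", length(x$islands), " island(s) removed\n", sep = "")
  invisible(x)
}

#' Annotate and summarize edge change directions
#'
#' Attaches each edge's change class (already carried from the DCE table)
#' and summarizes: how many DCE edges strengthened in the disease condition
#' (`increased` or disease-only), how many are disease-condition-specific,
#' and what fraction of co-expression edges have negative disease-state
#' correlation.
#'
#' @param network A [build_core_network()] result.
#' @return The network with an `edge_summary` list added: `n_dce`,
#'   `n_increased`, `n_condition_specific`, `negative_fraction`.
#' @export
annotate_edge_directions <- function(network) {
  stopifnot(inherits(network, "core_network"))
  e <- network$edges
  if (anyNA(e$class)) stop("edge(s) missing a change class", call. = FALSE)
  dce_e <- e[e$dce, ]
  coex_e <- e[e$coexpression, ]
  network$edge_summary <- list(
    n_dce = nrow(dce_e),
    n_increased = sum(dce_e$class %in% c("increased", "A_only")),
    n_condition_specific = sum(dce_e$class == "A_only"),
    negative_fraction = if (nrow(coex_e)) mean(coex_e$r_a < 0) else NA_real_
  )
  network
}

#' Extract one hub's dysregulation subnetwork
#'
#' The subnetwork is the hub plus its DCE partner set, with each member's
#' per-condition correlation to the hub and its change class.
#'
#' @param hub Gene ID.
#' @param dce A [dce_table()] result.
#' @param cutoff Adjusted-p cutoff defining partners (default 0.01).
#' @return A `subnetwork`: list with `hub` and `members` (tibble `gene`,
#'   `r_a`, `r_b`, `class`).
#' @export
extract_subnetwork <- function(hub, dce, cutoff = 0.01) {
  inc <- dce[(dce$gene_i == hub | dce$gene_j == hub) & dce$p_adj < cutoff, ]
  if (nrow(inc) == 0) stop("hub '", hub, "' has no DCE partners", call. = FALSE)
  members <- tibble::tibble(
    gene = ifelse(inc$gene_i == hub, inc$gene_j, inc$gene_i),
    r_a = inc$r_a, r_b = inc$r_b, class = inc$class
  )
  structure(list(hub = hub, members = dplyr::arrange(members, .data$gene)),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("<subnetwork> hub ", x$hub, " with ", nrow(x$members), " partner(s)\n",
      sep = "")
  invisible(x)
}

#' Gene-set enrichment of a subnetwork's members
#'
#' Hypergeometric over-representation of each gene set among the hub's
#' partner genes, against a stated universe.
#'
#' @param subnetwork An [extract_subnetwork()] result.
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector: the enrichment universe.
#' @return A tibble `set`, `x` (overlap), `k` (member count), `K` (set size
#'   in universe), `p`, sorted by `p`.
#' @export
subnetwork_enrichment <- function(subnetwork, gene_sets, universe) {
  stopifnot(inherits(subnetwork, "subnetwork"))
  members <- intersect(subnetwork$members$gene, universe)
  k <- length(members)
  res <- purrr::imap(gene_sets, function(genes, name) {
    genes <- intersect(genes, universe)
    x <- length(intersect(members, genes))
    K <- length(genes)
    p <- if (K) enrichment_test(x, k, K, length(universe)) else NA_real_
    tibble::tibble(set = name, x = x, k = k, K = K, p = p)
  })
  dplyr::arrange(dplyr::bind_rows(res), .data$p)
}

#' Rank transcription factors by co-expression with a target gene
#'
#' Pulls the target's correlation with each TF from a pair table and ranks:
#' the primary view sorts by signed r ascending (most negatively
#' co-expressed first, the repressor-candidate ordering); `rank_abs` gives
#' the |r|-descending view.
#'
#' @param target Gene ID.
#' @param tfs Character vector of TF gene IDs (the target itself is excluded
#'   with a warning if present).
#' @param pairs A pair table (`gene_i`, `gene_j`, `r`) containing the
#'   target's pairs.
#' @return A tibble `tf`, `r`, `rank_negative`, `rank_abs`, sorted by r.
#' @export
rank_tf_coexpression <- function(target, tfs, pairs) {
  if (target %in% tfs) {
    warning("target '", target, "' removed from the TF list", call. = FALSE)
    tfs <- setdiff(tfs, target)
  }
  inc <- pairs[pairs$gene_i == target | pairs$gene_j == target, ]
  other <- ifelse(inc$gene_i == target, inc$gene_j, inc$gene_i)
  keep <- other %in% tfs
  found <- tibble::tibble(tf = other[keep], r = inc$r[keep])
  missing <- setdiff(tfs, found$tf)
  if (length(missing)) {
    stop("pair table lacks target-TF pair(s): ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  }
  found |>
    dplyr::arrange(.data$r) |>
    dplyr::mutate(rank_negative = dplyr::row_number(),
                  rank_abs = dplyr::min_rank(-abs(.data$r)))
}

#' Convert a core network to an igraph object
#'
#' @param network A [build_core_network()] result.
#' @return An undirected [igraph::graph] with edge attributes.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "core_network"))
  igraph::graph_from_data_frame(
    d = data.frame(from = network$edges$gene_i, to = network$edges$gene_j,
                   r_a = network$edges$r_a, r_b = network$edges$r_b,
                   coexpression = network$edges$coexpression,
                   dce = network$edges$dce,
                   class = as.character(network$edges$class)),
    directed = FALSE,
    vertices = as.data.frame(network$nodes)
  )
}

#' Write a core network to GraphML and a flat edge list
#'
#' @param network A [build_core_network()] result.
#' @param graphml Path for the GraphML file (skipped if `NULL`).
#' @param edges_tsv Path for the edge-list TSV (skipped if `NULL`).
#' @return The network, invisibly.
#' @export
write_core_network <- function(network, graphml = NULL, edges_tsv = NULL) {
  if (!is.null(graphml)) {
    igraph::write_graph(as_igraph(network), graphml, format = "graphml")
  }
  if (!is.null(edges_tsv)) {
    readr::write_tsv(network$edges, edges_tsv)
  }
  invisible(network)
}
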