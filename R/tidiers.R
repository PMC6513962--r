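# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a change summary into per-class counts
#'
#' @param x A [change_summary()] result.
#' @param ... Unused.
#' @return A tibble `class`, `n`, `fraction`.
#' @export
tidy.change_summary <- function(x, ...) x$counts

#' One-row overview of a change summary
#'
#' @inheritParams tidy.change_summary
#' @return A tibble `total`, `strengthened_weakened_ratio`.
#' @export
glance.change_summary <- function(x, ...) {
  tibble::tibble(total = x$total, strengthened_weakened_ratio = x$ratio)
}

#' Tidy a core network into its edge table
#'
#' @param x A [build_core_network()] result.
#' @param ... Unused.
#' @return The edge tibble.
#' @export
tidy.core_network <- function(x, ...) x$edges

#' One-row overview of a core network
#'
#' @inheritParams tidy.core_network
#' @return A tibble with node/edge/island counts and (if
#'   [annotate_edge_directions()] has run) the direction summary.
#' @export
glance.core_network <- function(x, ...) {
  out <- tibble::tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    n_coexpression = sum(x$edges$coexpression), n_dce = sum(x$edges$dce),
    n_islands = length(x$islands)
  )
  if (!is.null(x$edge_summary)) {
    out <- dplyr::bind_cols(out, tibble::as_tibble(x$edge_summary))
  }
  out
}

#' Tidy a subnetwork into its member table
#'
#' @param x An [extract_subnetwork()] result.
#' @param ... Unused.
#' @return The member tibble with the hub attached as a column.
#' @export
tidy.subnetwork <- function(x, ...) {
  dplyr::mutate(x$members, hub = x$hub, .before = 1)
}

#' One-row overview of a conservation result
#'
#' @param x A [coexpression_conservation()] result.
#' @param ... Unused.
#' @return A tibble with the shared-pair count, correlation-of-correlations,
#'   sign-inconsistency and cross-set DCE fractions.
#' @export
glance.conservation_result <- function(x, ...) {
  tibble::tibble(
    shared_pairs = x$shared_pairs, r = x$r,
    sign_inconsistent_fraction = x$sign_inconsistent_fraction,
    dce_fraction = x$dce_fraction, n_coexpressed = x$n_coexpressed
  )
}

#' One-row overview of a profile-similarity result
#'
#' @param x An [expression_profile_similarity()] result.
#' @param ... Unused.
#' @return A tibble `n_genes`, `n_pairs_total`, `median_r`.
#' @export
glance.profile_similarity <- function(x, ...) {
  tibble::tibble(n_genes = x$n_genes, n_pairs_total = x$n_pairs_total,
                 median_r = x$median)
}

#' Plot per-condition correlations colored by change class
#'
#' Scatter of r (condition B) versus r (condition A) for pairs significant
#' at `cutoff`, colored by change class; the identity line marks no change.
#'
#' @param object A [dce_table()] result.
#' @param cutoff Adjusted-p cutoff (default 0.01).
#' @param max_points Random down-sample cap for plotting (default 20000).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dce_tbl <- function(object, cutoff = 0.01, max_points = 20000, ...) {
  sig <- object[object$p_adj < cutoff, ]
  if (nrow(sig) > max_points) sig <- dplyr::slice_sample(sig, n = max_points)
  ggplot2::ggplot(sig, ggplot2::aes(x = .data$r_b, y = .data$r_a,
                                    colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::coord_equal(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "Spearman r (condition B)", y = "Spearman r (condition A)",
                  colour = "change class",
                  title = "Differential co-expression of significant pairs") +
    ggplot2::theme_minimal()
}

#' Plot change-class counts
#'
#' @param object A [change_summary()] result.
#' @param ... Unused.
#' @return A ggplot bar chart.
#' @export
autoplot.change_summary <- function(object, ...) {
  ggplot2::ggplot(object$counts, ggplot2::aes(x = .data$class, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "significant pairs",
                  title = "Co-expression change classes",
                  subtitle = paste0("strengthened/weakened = ",
                                    format(object$ratio, digits = 3))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot the core dysregulation network
#'
#' Force-directed layout with edge type (co-expression / DCE / both) as
#' line type and node degree as point size.
#'
#' @param object A [build_core_network()] result.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.core_network <- function(object, seed = 1L, ...) {
  g <- as_igraph(object)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  pos <- stats::setNames(seq_len(nrow(nodes)), nodes$gene)
  edges <- dplyr::mutate(
    object$edges,
    x = nodes$x[pos[.data$gene_i]], y = nodes$y[pos[.data$gene_i]],
    xend = nodes$x[pos[.data$gene_j]], yend = nodes$y[pos[.data$gene_j]],
    type = dplyr::case_when(.data$coexpression & .data$dce ~ "both",
                            .data$dce ~ "dce", .default = "coexpression")
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$type),
      colour = "grey60", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$degree),
      colour = "steelblue"
    ) +
    ggplot2::scale_size_continuous(range = c(1, 5)) +
    ggplot2::labs(title = "Core dysregulation network", linetype = "edge type") +
    ggplot2::theme_void()
}
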