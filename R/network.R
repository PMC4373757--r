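#' Build the significant-gene interaction network
#'
#' Restricts a STRING-style edge table to interactions between genes called
#' significant by the DE stage, keeping edges at or above a confidence
#' cutoff. Nodes with no surviving interaction partner are dropped, and
#' every retained node is annotated with its log2 fold change, adjusted p,
#' degree and connected component.
#'
#' The combined-score scale is auto-detected: tables whose maximum score
#' exceeds 1 are taken to be on the STRING 0-999 integer scale (default
#' cutoff 400, medium confidence); otherwise scores are probabilities on
#' 0-1 (default cutoff 0.4). Symbol matching is case-insensitive. Duplicate
#' edges are collapsed keeping the maximum score; self-loops are removed.
#'
#' @param de A `paired_de` object or gene-level tibble with columns `gene`,
#'   `log2fc`, `p_adj`, `significant`.
#' @param edges Edge table with columns `protein1`, `protein2`,
#'   `combined_score` (first three columns used if names differ).
#' @param min_score Confidence cutoff on the table's score scale; `NULL`
#'   picks 400 or 0.4 by the detected scale.
#' @return An object of class `interaction_network`: list with `graph`
#'   (igraph), `nodes` (tibble `gene`, `log2fc`, `p_adj`, `degree`,
#'   `component`), `edges` (tibble), `min_score`, and `n_skipped` (edge
#'   rows mentioning genes outside the significant set).
#' @examples
#' de <- tibble::tibble(gene = c("A", "B", "C"),
#'                      log2fc = c(1, -1, 2), p_adj = c(0.01, 0.02, 0.03),
#'                      significant = TRUE)
#' ed <- tibble::tibble(protein1 = c("A", "B"), protein2 = c("B", "D"),
#'                      combined_score = c(900, 900))
#' build_network(de, ed)$nodes
#' @export
build_network <- function(de, edges, min_score = NULL) {
  genes <- if (inherits(de, "paired_de")) de$genes else as_tibble(de)
  if (!all(c("gene", "significant") %in% names(genes))) {
    abort("`de` must provide columns `gene` and `significant`.")
  }
  if (ncol(edges) < 3) abort("`edges` needs protein1, protein2, combined_score.")
  ed <- as_tibble(edges)
  if (!all(c("protein1", "protein2", "combined_score") %in% names(ed))) {
    names(ed)[1:3] <- c("protein1", "protein2", "combined_score")
  }
  ed <- dplyr::mutate(ed,
                      protein1 = toupper(.data$protein1),
                      protein2 = toupper(.data$protein2))
  scale999 <- max(ed$combined_score, 0) > 1
  if (is.null(min_score)) min_score <- if (scale999) 400 else 0.4

  sig <- dplyr::mutate(genes[genes$significant, , drop = FALSE],
                       gene_uc = toupper(.data$gene))
  keep_sym <- sig$gene_uc
  in_sig <- ed$protein1 %in% keep_sym & ed$protein2 %in% keep_sym
  n_skipped <- sum(!in_sig)
  if (n_skipped > 0) {
    inform(sprintf("Skipped %d edge(s) with endpoints outside the significant gene set.",
                   n_skipped))
  }
  ed <- ed[in_sig & ed$combined_score >= min_score &
             ed$protein1 != ed$protein2, , drop = FALSE]
  if (nrow(ed) > 0) {
    a <- pmin(ed$protein1, ed$protein2)
    b <- pmax(ed$protein1, ed$protein2)
    ed <- dplyr::summarise(
      dplyr::group_by(tibble(protein1 = a, protein2 = b,
                             combined_score = ed$combined_score),
                      .data$protein1, .data$protein2),
      combined_score = max(.data$combined_score), .groups = "drop"
    )
  }

  g <- igraph::graph_from_data_frame(ed[, c("protein1", "protein2")],
                                     directed = FALSE)
  if (nrow(ed) > 0) igraph::E(g)$combined_score <- ed$combined_score
  comp <- igraph::components(g)
  nodes <- tibble(
    gene_uc = igraph::V(g)$name,
    degree = as.integer(igraph::degree(g)),
    component = as.integer(comp$membership)
  )
  nodes <- dplyr::left_join(nodes, sig[, c("gene_uc", "gene", "log2fc", "p_adj")],
                            by = "gene_uc")
  nodes <- dplyr::select(nodes, "gene", "log2fc", "p_adj", "degree", "component")
  nodes <- dplyr::arrange(nodes, dplyr::desc(.data$degree), .data$gene)
  igraph::V(g)$log2fc <- nodes$log2fc[match(igraph::V(g)$name, toupper(nodes$gene))]
  igraph::V(g)$p_adj <- nodes$p_adj[match(igraph::V(g)$name, toupper(nodes$gene))]

  out <- list(graph = g, nodes = nodes,
              edges = ed, min_score = min_score, n_skipped = n_skipped)
  class(out) <- "interaction_network"
  out
}

#' Hub genes of an interaction network
#'
#' Multi-edged nodes are hubs; the conventional criterion here is a degree
#' of at least 10. Hubs are ranked by degree (descending, ties
#' lexicographic) and the top hub is flagged — in 2-week post-surgery
#' cartilage that role falls to fibronectin.
#'
#' @param net An `interaction_network`.
#' @param min_degree Minimum degree for hub status.
#' @return Tibble `gene`, `degree`, `log2fc`, `p_adj`, `is_top`, sorted.
#' @export
find_hubs <- function(net, min_degree = 10) {
  min_degree <- check_count(min_degree, "min_degree")
  hubs <- net$nodes[net$nodes$degree >= min_degree, , drop = FALSE]
  hubs <- dplyr::arrange(hubs, dplyr::desc(.data$degree), .data$gene)
  hubs <- dplyr::select(hubs, "gene", "degree", "log2fc", "p_adj")
  dplyr::mutate(hubs, is_top = dplyr::row_number() == 1L & nrow(hubs) > 0)
}

#' Write a network as GraphML
#'
#' @param net An `interaction_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf(
    "Interaction network: %d nodes, %d edges (min combined score %g), %d component(s)\n",
    nrow(x$nodes), nrow(x$edges), x$min_score,
    length(unique(x$nodes$component))
  ))
  invisible(x)
}

#' @rdname build_network
#' @param x An `interaction_network`.
#' @param ... Unused.
#' @method tidy interaction_network
#' @export
tidy.interaction_network <- function(x, ...) x$nodes

#' @rdname build_network
#' @method glance interaction_network
#' @export
glance.interaction_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_components = length(unique(x$nodes$component)),
    max_degree = if (nrow(x$nodes)) max(x$nodes$degree) else 0L,
    min_score = x$min_score,
    n_skipped_edges = x$n_skipped
  )
}
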