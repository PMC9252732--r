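#' Extract the subgraph of top-ranked genes
#'
#' Selects nodes either as the top `n_nodes` by rank or as all genes with
#' probability at or above `prob_threshold` (the intersection when both are
#' given), capped at 50 nodes, then induces the network edges among them and
#' keeps those with weight at or above `edge_threshold`. This is the data
#' behind the interactive top-gene network view; layout and interaction are
#' left to the viewer.
#'
#' @param table a `prediction_table`.
#' @param network the `gene_network` the predictions were made on.
#' @param n_nodes number of top-ranked genes to keep (values above the 50-node
#'   cap are reduced to 50); must be positive.
#' @param prob_threshold optional probability cutoff for node selection.
#' @param edge_threshold minimum edge weight to retain (default 0 keeps all).
#' @param max_nodes the hard node cap (default 50).
#' @return object of class `subgraph_export`: list with `nodes` (data frame
#'   `entrez`, `symbol`, `probability`, `training_label`, `rank`), `edges`
#'   (data frame `entrez_a`, `entrez_b`, `weight`), and `thresholds`.
#' @export
top_subgraph <- function(table, network, n_nodes = 50, prob_threshold = NULL,
                         edge_threshold = 0, max_nodes = 50) {
  stopifnot(inherits(table, "prediction_table"),
            inherits(network, "gene_network"))
  if (!is.numeric(n_nodes) || n_nodes <= 0)
    stop("n_nodes must be positive", call. = FALSE)
  if (!all(table$entrez %in% network$nodes))
    stop("prediction table and network do not share a gene space",
         call. = FALSE)
  keep <- table$rank <= min(n_nodes, max_nodes)
  if (!is.null(prob_threshold))
    keep <- keep & table$probability >= prob_threshold
  nodes <- table[keep, c("entrez", "symbol", "probability",
                         "training_label", "rank")]
  nodes <- nodes[seq_len(min(nrow(nodes), max_nodes)), , drop = FALSE]
  rownames(nodes) <- NULL
  e <- network$edges
  in_set <- e$from %in% nodes$entrez & e$to %in% nodes$entrez
  edges <- e[in_set & e$weight >= edge_threshold, , drop = FALSE]
  names(edges) <- c("entrez_a", "entrez_b", "weight")
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 thresholds = list(n_nodes = n_nodes,
                                   prob_threshold = prob_threshold,
                                   edge_threshold = edge_threshold,
                                   max_nodes = max_nodes)),
            class = "subgraph_export")
}

#' @export
print.subgraph_export <- function(x, ...) {
  cat(sprintf("subgraph_export: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Write a subgraph export to JSON or GraphML
#'
#' JSON uses a nodes/links layout; GraphML is written through igraph and
#' carries the node attributes (probability, training label, rank) and edge
#' weights.
#'
#' @param subgraph a `subgraph_export`.
#' @param path output path.
#' @param format `"json"` or `"graphml"`.
#' @export
write_subgraph <- function(subgraph, path, format = c("json", "graphml")) {
  stopifnot(inherits(subgraph, "subgraph_export"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(list(nodes = subgraph$nodes,
                              links = subgraph$edges,
                              thresholds = subgraph$thresholds),
                         path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    g <- igraph::graph_from_data_frame(
      subgraph$edges, directed = FALSE,
      vertices = data.frame(name = subgraph$nodes$entrez,
                            symbol = ifelse(is.na(subgraph$nodes$symbol), "",
                                            subgraph$nodes$symbol),
                            probability = subgraph$nodes$probability,
                            training_label = subgraph$nodes$training_label,
                            rank = subgraph$nodes$rank))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
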