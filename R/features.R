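new_feature_matrix <- function(representation, genes, values, params) {
  stopifnot(nrow(values) == length(genes))
  rownames(values) <- genes
  if (any(!is.finite(values))) stop("non-finite feature values", call. = FALSE)
  structure(list(
    representation = representation,
    genes = genes,
    values = values,
    params = params,
    fingerprint = do.call(make_fingerprint,
                          c(list(representation = representation), params))
  ), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix (%s): %d genes x %d features\n",
              x$representation, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Adjacency feature representation
#'
#' Each gene's feature vector is its row of the weighted adjacency matrix:
#' the connections in the original network, used directly as classifier
#' features.
#'
#' @param network a `gene_network`.
#' @return a `feature_matrix` with a square symmetric value matrix
#'   (zero diagonal), rows and columns in canonical node order.
#' @export
adjacency_features <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  A <- adjacency_matrix(network)
  new_feature_matrix("adjacency", network$nodes, A,
                     list(network = network$name,
                          n_nodes = length(network$nodes)))
}

#' Random-walk-with-restart influence features
#'
#' Computes the diffusion kernel `F = a * (I - (1-a) P)^-1`, where `P` is the
#' row-normalized adjacency matrix (`P[i,j] = w_ij / degree(i)`) and `a` the
#' restart probability: `F[i,j]` is the stationary probability that a walker
#' restarting at gene `i` is found at gene `j`, so each row sums to 1 and walk
#' mass never leaves a connected component. The linear system is solved per
#' component.
#'
#' @param network a `gene_network`.
#' @param restart_prob restart probability `a` in (0, 1]; default 0.85.
#' @return a `feature_matrix` with a square row-stochastic value matrix.
#' @export
influence_features <- function(network, restart_prob = 0.85) {
  stopifnot(inherits(network, "gene_network"))
  if (!is.numeric(restart_prob) || length(restart_prob) != 1L ||
      restart_prob <= 0 || restart_prob > 1)
    stop("restart_prob must be in (0, 1]", call. = FALSE)
  A <- adjacency_matrix(network)
  n <- nrow(A)
  P <- A / rowSums(A)
  g <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
  comp <- igraph::components(g)$membership
  F <- matrix(0, n, n, dimnames = dimnames(A))
  for (c in unique(comp)) {
    idx <- which(comp == c)
    F[idx, idx] <- restart_prob *
      solve(diag(length(idx)) - (1 - restart_prob) * P[idx, idx, drop = FALSE],
            diag(length(idx)))
  }
  new_feature_matrix("influence", network$nodes, F,
                     list(network = network$name,
                          n_nodes = n, restart_prob = restart_prob))
}

#' node2vec embedding features
#'
#' Generates second-order biased random walks over the network (return
#' parameter `p`, in-out parameter `q`) and fits gene vectors by skip-gram
#' with negative sampling on the walk corpus. All randomness comes from a
#' private generator, so the same seed and parameters always produce the
#' identical matrix.
#'
#' Defaults follow the conventions of the original embedding algorithm:
#' 128 dimensions, 10 walks of length 80 per node, window 10, `p = q = 1`
#' (unbiased walks), 5 training epochs, 5 negative samples.
#'
#' @param network a `gene_network`.
#' @param dim embedding dimension (>= 2); a warning is issued when the network
#'   has fewer nodes than dimensions.
#' @param walk_length,walks_per_node,window,p,q,epochs,negative,start_lr
#'   embedding hyperparameters; all must be positive.
#' @param seed integer seed for the private random generator.
#' @return a `feature_matrix` with an `n_genes x dim` value matrix.
#' @export
embedding_features <- function(network, dim = 128, walk_length = 80,
                               walks_per_node = 10, window = 10, p = 1, q = 1,
                               epochs = 5, negative = 5, start_lr = 0.025,
                               seed = 1) {
  stopifnot(inherits(network, "gene_network"))
  num <- c(dim = dim, walk_length = walk_length, walks_per_node = walks_per_node,
           window = window, p = p, q = q, epochs = epochs, negative = negative,
           start_lr = start_lr)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("embedding hyperparameters must be positive", call. = FALSE)
  if (dim < 2) stop("dim must be >= 2", call. = FALSE)
  n <- length(network$nodes)
  if (n < dim)
    warning("network has fewer nodes (", n, ") than embedding dimensions (",
            dim, ")")
  walks <- node2vec_walks(network, walk_length = walk_length,
                          walks_per_node = walks_per_node, p = p, q = q,
                          seed = seed)
  emb <- .n2v_embed(walks, n, as.integer(dim), as.integer(window),
                    as.integer(epochs), as.integer(negative), start_lr,
                    as.integer(seed))
  colnames(emb) <- paste0("dim", seq_len(dim))
  new_feature_matrix("embedding", network$nodes, emb,
                     list(network = network$name, n_nodes = n, dim = dim,
                          walk_length = walk_length,
                          walks_per_node = walks_per_node, window = window,
                          p = p, q = q, epochs = epochs, negative = negative,
                          start_lr = start_lr, seed = seed))
}

#' Generate second-order biased random walks
#'
#' Exposed separately from [embedding_features()] so the walk distribution can
#' be inspected: with `p = q = 1` the transition frequencies converge to the
#' row-normalized adjacency matrix.
#'
#' @inheritParams embedding_features
#' @return integer matrix, one walk per row, entries are 1-based indices into
#'   `network$nodes` (NA-padded if a walk hits a dead end).
#' @export
node2vec_walks <- function(network, walk_length = 80, walks_per_node = 10,
                           p = 1, q = 1, seed = 1) {
  stopifnot(inherits(network, "gene_network"))
  idx <- setNames(seq_along(network$nodes) - 1L, network$nodes)
  e <- network$edges
  .n2v_walks(length(network$nodes), as.integer(idx[e$from]),
             as.integer(idx[e$to]), as.numeric(e$weight),
             as.integer(walk_length), as.integer(walks_per_node),
             as.numeric(p), as.numeric(q), as.integer(seed))
}
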