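#' Construct a weighted undirected gene network
#'
#' Canonicalizes an edge table into a `gene_network`: edges are symmetrized
#' (`a-b` and `b-a` are the same edge), duplicate pairs are collapsed keeping
#' the maximum weight, self-loops are dropped (with a message), and nodes are
#' ordered by ascending numeric Entrez ID so that matrix layouts are
#' reproducible across runs. Nodes are defined as edge endpoints, so isolated
#' nodes cannot occur.
#'
#' @param edges data frame with columns `entrez_a`, `entrez_b` and optionally
#'   `weight` (defaults to 1). IDs are coerced to character.
#' @param name network name used in summaries and fingerprints.
#' @return An object of class `gene_network` with elements `name`, `nodes`
#'   (character vector in canonical order), and `edges` (data frame with
#'   columns `from`, `to`, `weight`; `from` precedes `to` in node order).
#' @examples
#' net <- gene_network(data.frame(entrez_a = c("1", "2"),
#'                                entrez_b = c("2", "3"),
#'                                weight = c(0.5, 1)), name = "toy")
#' net$nodes
#' @export
gene_network <- function(edges, name = "network") {
  stopifnot(is.data.frame(edges), all(c("entrez_a", "entrez_b") %in% names(edges)))
  a <- trimws(as.character(edges$entrez_a))
  b <- trimws(as.character(edges$entrez_b))
  w <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else rep(1, length(a))
  if (length(a) == 0L) stop("network has no edges", call. = FALSE)
  if (anyNA(w)) stop("non-numeric edge weight", call. = FALSE)
  if (any(w <= 0)) stop("edge weights must be positive", call. = FALSE)

  loops <- a == b
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped")
    a <- a[!loops]; b <- b[!loops]; w <- w[!loops]
  }
  if (length(a) == 0L) stop("network has no edges after dropping self-loops",
                            call. = FALSE)

  # undirected canonical orientation: smaller numeric Entrez first
  swap <- as.numeric(a) > as.numeric(b)
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b, sep = "\r")
  # duplicate pairs collapse to the maximum weight (order-invariant)
  w <- tapply(w, key, max)
  keys <- names(w)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  a <- vapply(parts, `[[`, character(1), 1L)
  b <- vapply(parts, `[[`, character(1), 2L)
  w <- as.numeric(w)

  nodes <- order_entrez(unique(c(a, b)))
  ord <- order(as.numeric(a), as.numeric(b))
  net <- structure(list(
    name  = name,
    nodes = nodes,
    edges = data.frame(from = a[ord], to = b[ord], weight = w[ord],
                       stringsAsFactors = FALSE)
  ), class = "gene_network")
  net
}

#' Read a gene network from an edge-list TSV
#'
#' Expects at least two columns (`entrez_a`, `entrez_b`) and an optional third
#' weight column (missing weights default to 1). A header row is detected by a
#' non-numeric first field and skipped. The result is canonicalized by
#' [gene_network()], so reading is invariant to row order.
#'
#' @param path path to a tab-separated edge list.
#' @param name network name.
#' @return A `gene_network`.
#' @export
read_edge_list <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("network file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty network file: ", path, call. = FALSE)
  first <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  offset <- 0L
  if (length(first) >= 1L && is.na(suppressWarnings(as.numeric(first[[1L]])))) {
    lines <- lines[-1L]; offset <- 1L            # header row
    if (length(lines) == 0L) stop("empty network file: ", path, call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 2L))
    stop("line ", which(ncol < 2L)[1L] + offset, ": fewer than 2 columns",
         call. = FALSE)
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  w <- ifelse(ncol >= 3L,
              vapply(fields, function(f) if (length(f) >= 3L) f[[3L]] else "1",
                     character(1)),
              "1")
  wn <- suppressWarnings(as.numeric(w))
  if (anyNA(wn))
    stop("line ", which(is.na(wn))[1L] + offset, ": non-numeric weight '",
         w[which(is.na(wn))[1L]], "'", call. = FALSE)
  gene_network(data.frame(entrez_a = a, entrez_b = b, weight = wn,
                          stringsAsFactors = FALSE), name = name)
}

#' Write a gene network to an edge-list TSV
#'
#' Writes the canonical edge table (header `entrez_a`, `entrez_b`, `weight`);
#' `read_edge_list(write_edge_list(net))` reproduces `net` exactly.
#'
#' @param network a `gene_network`.
#' @param path output path.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "gene_network"))
  df <- network$edges
  names(df) <- c("entrez_a", "entrez_b", "weight")
  write_tsv(df, path)
}

#' Weighted node degrees
#'
#' @param network a `gene_network`.
#' @return named numeric vector of weighted degrees (sum of incident edge
#'   weights), in canonical node order; strictly positive for every node.
#' @export
degree_vector <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  d <- setNames(numeric(length(network$nodes)), network$nodes)
  e <- network$edges
  for (side in c("from", "to")) {
    s <- tapply(e$weight, e[[side]], sum)
    d[names(s)] <- d[names(s)] + as.numeric(s)
  }
  d
}

# dense symmetric adjacency in canonical node order (fixture-scale networks)
adjacency_matrix <- function(network) {
  n <- length(network$nodes)
  idx <- setNames(seq_len(n), network$nodes)
  A <- matrix(0, n, n, dimnames = list(network$nodes, network$nodes))
  e <- network$edges
  i <- idx[e$from]; j <- idx[e$to]
  A[cbind(i, j)] <- e$weight
  A[cbind(j, i)] <- e$weight
  A
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network '%s': %d nodes, %d edges\n",
              x$name, length(x$nodes), nrow(x$edges)))
  invisible(x)
}
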