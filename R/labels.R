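#' Construct a gene-set collection
#'
#' @param sets list of gene sets, each a list with `id`, `name`, and `members`
#'   (character vector of Entrez IDs; duplicates are dropped).
#' @param collection_name name of the collection.
#' @return object of class `gene_set_collection`: list with `collection_name`,
#'   `sets`, and `universe` (the exact union of all members).
#' @export
gene_set_collection <- function(sets, collection_name = "collection") {
  stopifnot(is.list(sets), length(sets) > 0L)
  sets <- lapply(sets, function(s) {
    stopifnot(!is.null(s$id), !is.null(s$members))
    members <- unique(as.character(s$members))
    if (length(members) == 0L)
      stop("gene set '", s$id, "' has no members", call. = FALSE)
    list(id = as.character(s$id), name = as.character(s$name %||% s$id),
         members = members)
  })
  ids <- vapply(sets, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate set id: ", ids[duplicated(ids)][1L], call. = FALSE)
  structure(list(
    collection_name = collection_name,
    sets = sets,
    universe = unique(unlist(lapply(sets, `[[`, "members")))
  ), class = "gene_set_collection")
}

#' Read a gene-set collection from a GMT file
#'
#' One set per line: `set_id TAB description TAB member TAB member ...`.
#' Parsed by hand because the collection needs the description field, which
#' available GMT readers discard.
#'
#' @param path path to the GMT file.
#' @param collection_name collection name; defaults to the file name.
#' @return a `gene_set_collection`.
#' @export
read_gmt <- function(path, collection_name = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, ": expected at least 3 tab-separated fields",
           call. = FALSE)
    list(id = f[[1L]], name = f[[2L]], members = f[-(1:2)])
  })
  gene_set_collection(sets, collection_name = collection_name)
}

#' Write a gene-set collection to GMT
#'
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(collection$sets, function(s)
    paste(c(s$id, s$name, s$members), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection '%s': %d sets, universe of %d genes\n",
              x$collection_name, length(x$sets), length(x$universe)))
  invisible(x)
}

#' Select positive training genes
#'
#' The positive examples are exactly the user genes (already in Entrez space)
#' that are present in the chosen network; the rest are dropped with a
#' message.
#'
#' @param user_genes character vector of Entrez IDs.
#' @param network a `gene_network`.
#' @return character vector of positives in canonical node order, with the
#'   dropped genes in attribute `dropped`.
#' @export
select_positives <- function(user_genes, network) {
  stopifnot(inherits(network, "gene_network"))
  genes <- unique(as.character(user_genes))
  pos <- genes[genes %in% network$nodes]
  dropped <- setdiff(genes, pos)
  if (length(dropped))
    message(length(dropped), " input gene(s) not in network '",
            network$name, "' dropped")
  if (length(pos) == 0L)
    stop("no positives in network: none of the input genes are nodes of '",
         network$name, "'", call. = FALSE)
  structure(order_entrez(pos), dropped = dropped)
}

# one-sided (upper-tail) hypergeometric probability of seeing at least
# `overlap` positives in a set of size m drawn from a universe of size N
# containing k positives
hyper_overlap_p <- function(overlap, set_size, universe_size, n_positives) {
  stats::phyper(overlap - 1L, n_positives, universe_size - n_positives,
                set_size, lower.tail = FALSE)
}

#' Partition network genes into positive, negative, and unused labels
#'
#' Candidate negatives are all genes of the collection universe that are in
#' the network and not positives. Any collection set whose overlap with the
#' positive set is significant under a one-sided hypergeometric test
#' (p < `alpha`, unadjusted) has all of its members removed from the
#' candidates — such genes are too related to the positives to serve as
#' negatives and become unused instead. The test universe is the collection
#' universe restricted to network nodes, since labels only ever apply to
#' network genes.
#'
#' @param positives character vector of positive Entrez IDs (from
#'   [select_positives()]); all must be network nodes.
#' @param collection a `gene_set_collection`.
#' @param network a `gene_network`.
#' @param alpha significance level of the overlap test (default 0.05).
#' @return object of class `labeled_sets`: list with disjoint character
#'   vectors `positives`, `negatives`, `unused` that together cover the
#'   network node set, and `excluded_sets` (data frame `set_id`,
#'   `overlap_count`, `p_value` for each removed set).
#' @export
select_negatives <- function(positives, collection, network, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"),
            inherits(network, "gene_network"),
            is.numeric(alpha), alpha > 0, alpha <= 1)
  positives <- unique(as.character(positives))
  if (length(positives) == 0L) stop("positives must be nonempty", call. = FALSE)
  if (!all(positives %in% network$nodes))
    stop("all positives must be network nodes", call. = FALSE)

  universe <- intersect(collection$universe, network$nodes)
  if (length(universe) == 0L)
    stop("collection universe does not intersect the network", call. = FALSE)
  pos_u <- intersect(positives, universe)
  candidates <- setdiff(universe, positives)

  excl_id <- character(0); excl_n <- integer(0); excl_p <- numeric(0)
  removed <- character(0)
  for (s in collection$sets) {
    members <- intersect(s$members, universe)
    if (length(members) == 0L) next
    overlap <- length(intersect(members, pos_u))
    p <- hyper_overlap_p(overlap, length(members), length(universe),
                         length(pos_u))
    if (p < alpha) {
      excl_id <- c(excl_id, s$id)
      excl_n <- c(excl_n, overlap)
      excl_p <- c(excl_p, p)
      removed <- union(removed, members)
    }
  }
  negatives <- setdiff(candidates, removed)
  if (length(negatives) == 0L)
    stop("no negatives remain after overlap exclusion; ",
         "try a different gene-set collection", call. = FALSE)
  unused <- setdiff(network$nodes, c(positives, negatives))
  structure(list(
    positives = order_entrez(positives),
    negatives = order_entrez(negatives),
    unused    = order_entrez(unused),
    excluded_sets = data.frame(set_id = excl_id, overlap_count = excl_n,
                               p_value = excl_p, stringsAsFactors = FALSE)
  ), class = "labeled_sets")
}

#' @export
print.labeled_sets <- function(x, ...) {
  cat(sprintf("labeled_sets: %d positive, %d negative, %d unused (%d set(s) excluded)\n",
              length(x$positives), length(x$negatives), length(x$unused),
              nrow(x$excluded_sets)))
  invisible(x)
}

# P/N/U label per node, in canonical node order
label_vector <- function(labels, network) {
  lab <- setNames(rep("U", length(network$nodes)), network$nodes)
  lab[labels$positives] <- "P"
  lab[labels$negatives] <- "N"
  lab
}
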