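#' Specify a synthetic benchmark scenario
#'
#' Describes a stochastic-block-model (SBM) network with planted functional
#' modules plus a matching gene-set collection and identifier map. The SBM is
#' the natural stand-in for functional modules because dense within-block
#' connectivity is exactly the guilt-by-association signal the classifier
#' exploits. No attempt is made to mimic the degree distribution of any
#' specific real network.
#'
#' @param n_blocks number of blocks (modules).
#' @param block_sizes integer vector of block sizes (recycled to `n_blocks`).
#' @param p_within,p_between within- and between-block edge probabilities;
#'   planted-signal benchmarks require `p_within > p_between`.
#' @param weight_range range of uniform edge weights.
#' @param n_sets number of gene sets in the generated collection (the first
#'   `n_blocks` are block-aligned, the rest are random).
#' @param set_size_range range of set sizes.
#' @param noise fraction of false positives injected into the planted user
#'   set by [planted_recovery_benchmark()].
#' @param seed integer seed recorded in every generated artifact.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_blocks = 2, block_sizes = c(50, 50),
                           p_within = 0.3, p_between = 0.01,
                           weight_range = c(0.5, 1), n_sets = 8,
                           set_size_range = c(10, 30), noise = 0, seed = 1) {
  block_sizes <- rep_len(as.integer(block_sizes), n_blocks)
  stopifnot(n_blocks >= 1, all(block_sizes >= 1),
            p_within >= 0, p_within <= 1, p_between >= 0, p_between <= 1,
            length(weight_range) == 2, weight_range[1] > 0,
            weight_range[2] >= weight_range[1],
            n_sets >= 1, length(set_size_range) == 2,
            noise >= 0, noise <= 1)
  structure(list(n_blocks = n_blocks, block_sizes = block_sizes,
                 p_within = p_within, p_between = p_between,
                 weight_range = weight_range, n_sets = n_sets,
                 set_size_range = set_size_range, noise = noise,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# synthetic Entrez IDs live far above the real range
synthetic_entrez <- function(n) as.character(900000000 + seq_len(n))

#' Generate a synthetic gene network with planted modules
#'
#' Draws an SBM with the spec's block structure, assigns uniform edge weights
#' from `weight_range`, and gives nodes synthetic Entrez IDs (900000001
#' upward). Nodes left isolated by the draw are re-wired with one edge to a
#' random gene of the same block so that every gene appears in the network;
#' a block of size 1 with no possible within-block partner is an error.
#' The block membership of every gene is attached as attribute `blocks`.
#'
#' @param spec a `synthetic_spec`.
#' @return a `gene_network` with attribute `blocks` (named integer vector).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- sum(spec$block_sizes)
  ids <- synthetic_entrez(n)
  block <- rep(seq_len(spec$n_blocks), spec$block_sizes)
  with_seed(spec$seed, {
    pref <- matrix(spec$p_between, spec$n_blocks, spec$n_blocks)
    diag(pref) <- spec$p_within
    g <- igraph::sample_sbm(n, pref.matrix = pref,
                            block.sizes = spec$block_sizes, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    iso <- setdiff(seq_len(n), unique(as.vector(el)))
    for (v in iso) {
      mates <- setdiff(which(block == block[v]), v)
      if (length(mates) == 0L)
        stop("infeasible spec: block of size 1 cannot host a within-block edge",
             call. = FALSE)
      el <- rbind(el, c(v, if (length(mates) == 1L) mates
                           else sample(mates, 1L)))
    }
    w <- runif(nrow(el), spec$weight_range[1], spec$weight_range[2])
    net <- gene_network(data.frame(entrez_a = ids[el[, 1]],
                                   entrez_b = ids[el[, 2]],
                                   weight = w),
                        name = sprintf("sbm_seed%d", spec$seed))
    attr(net, "blocks") <- setNames(block, ids)[net$nodes]
    net
  })
}

#' Generate a synthetic gene-set collection
#'
#' The first `n_sets` slots up to `n_blocks` are block-aligned sets (sampled
#' from within one block, for exercising the overlap-exclusion rule); the
#' remainder are random sets drawn from all genes (clean negative sources).
#'
#' @param network a network from [generate_network()] (block attribute
#'   required for the aligned sets).
#' @param spec the `synthetic_spec` used to generate the network.
#' @return a `gene_set_collection`.
#' @export
generate_collection <- function(network, spec) {
  stopifnot(inherits(network, "gene_network"), inherits(spec, "synthetic_spec"))
  blocks <- attr(network, "blocks")
  if (is.null(blocks)) stop("network lacks block annotations", call. = FALSE)
  with_seed(spec$seed + 1000L, {
    sets <- vector("list", spec$n_sets)
    for (i in seq_len(spec$n_sets)) {
      size <- sample(seq(spec$set_size_range[1], spec$set_size_range[2]), 1L)
      if (i <= spec$n_blocks) {
        pool <- names(blocks)[blocks == i]
        kind <- sprintf("block %d aligned", i)
      } else {
        pool <- network$nodes
        kind <- "random"
      }
      members <- sample(pool, min(size, length(pool)))
      sets[[i]] <- list(id = sprintf("SYN%04d", i),
                        name = sprintf("synthetic set %d (%s)", i, kind),
                        members = members)
    }
    gene_set_collection(sets, collection_name = sprintf("syn_collection_seed%d",
                                                        spec$seed))
  })
}

#' Generate a synthetic identifier map
#'
#' Produces entrez identity rows plus synthetic symbol and Ensembl-style
#' aliases for every network gene, so the full ID-conversion stage can run on
#' synthetic data.
#'
#' @param network a `gene_network`.
#' @return an `id_map`.
#' @export
generate_id_map <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  ids <- network$nodes
  k <- seq_along(ids)
  id_map(data.frame(
    alias = c(ids, sprintf("SYNG%05d", k), sprintf("ENSG9%011d", k)),
    namespace = rep(c("entrez", "symbol", "ensembl_gene"), each = length(ids)),
    entrez = rep(ids, 3L)))
}

#' Write synthetic inputs to disk
#'
#' Emits the three plain-text artifacts every pipeline stage consumes:
#' `network.tsv` (edge list), `collection.gmt`, and `id_map.tsv`.
#'
#' @param spec a `synthetic_spec`.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the generated `network`, `collection`, and
#'   `id_map` objects and their file paths.
#' @export
write_synthetic_data <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- generate_network(spec)
  coll <- generate_collection(net, spec)
  map <- generate_id_map(net)
  paths <- list(network = file.path(dir, "network.tsv"),
                collection = file.path(dir, "collection.gmt"),
                id_map = file.path(dir, "id_map.tsv"))
  write_edge_list(net, paths$network)
  write_gmt(coll, paths$collection)
  write_tsv(as.data.frame(map), paths$id_map)
  jsonlite::write_json(unclass(spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(network = net, collection = coll, id_map = map,
                 paths = paths))
}

#' Planted-module recovery benchmark
#'
#' Operationalizes the claim that the classifier recovers genes functionally
#' similar to the input set: one SBM block is designated the true module, a
#' fraction of its genes is hidden, the model is trained on the remainder,
#' and the positions of the hidden genes among the *novel* (non-positive)
#' predictions are measured. Hidden genes are hidden completely — they are
#' removed from the gene-set collection as well as from the positive set, so
#' they are scored but never enter training; a gene that still served as a
#' labeled negative would not be held out in any meaningful sense. Recovery
#' is measured among the novel genes because that is the pool a user
#' actually inspects: training positives always occupy the top of the full
#' ranking. Under random ranking the expected top-decile recall is 0.10 and
#' the expected mean novel-rank is half the novel count; a working
#' representation must beat both.
#'
#' @param spec a `synthetic_spec`; block 1 is the true module.
#' @param held_out_fraction fraction of module genes hidden from the positive
#'   set (0 yields no held-out genes; recall is then reported as `NA`).
#' @param seeds integer vector of seeds; one network/split per seed.
#' @param representations feature representations to benchmark.
#' @param restart_prob restart probability for the influence representation.
#' @param embedding_dim embedding dimension for the embedding representation.
#' @param alpha overlap-test significance level.
#' @param inverse_reg inverse regularization strength C.
#' @return object of class `recovery_report`: data frame with one row per
#'   (representation, seed) plus per-representation mean rows (`seed = NA`);
#'   columns `representation`, `seed`, `n_held_out`, `n_novel`, `mean_rank`
#'   (mean rank of held-out genes among novel genes), `top_decile_recall`
#'   (fraction of held-out genes ranked in the top tenth of the novel genes).
#' @export
planted_recovery_benchmark <- function(spec = synthetic_spec(),
                                       held_out_fraction = 0.3,
                                       seeds = 1:5,
                                       representations = c("adjacency",
                                                           "influence"),
                                       restart_prob = 0.85,
                                       embedding_dim = 16,
                                       alpha = 0.05, inverse_reg = 1) {
  stopifnot(inherits(spec, "synthetic_spec"),
            held_out_fraction >= 0, held_out_fraction < 1)
  representations <- match.arg(representations,
                               c("adjacency", "influence", "embedding"),
                               several.ok = TRUE)
  rows <- list()
  for (s in seeds) {
    sp <- spec
    sp$seed <- as.integer(s)
    net <- generate_network(sp)
    blocks <- attr(net, "blocks")
    module <- names(blocks)[blocks == 1L]
    n <- length(net$nodes)
    split <- with_seed(sp$seed + 2000L, {
      held <- sample(module, round(held_out_fraction * length(module)))
      visible <- setdiff(module, held)
      if (sp$noise > 0) {
        n_noise <- round(sp$noise * length(visible))
        if (n_noise > 0) {
          outside <- setdiff(net$nodes, module)
          visible <- c(sample(visible, length(visible) - n_noise),
                       sample(outside, n_noise))
        }
      }
      list(held = held, visible = visible)
    })
    coll <- generate_collection(net, sp)
    # hide the held-out genes from the annotation source too: they must be
    # scored but never labeled
    if (length(split$held)) {
      sets <- lapply(coll$sets, function(s) {
        s$members <- setdiff(s$members, split$held)
        s
      })
      sets <- Filter(function(s) length(s$members) > 0L, sets)
      coll <- gene_set_collection(sets, collection_name = coll$collection_name)
    }
    pos <- suppressMessages(select_positives(split$visible, net))
    labels <- select_negatives(pos, coll, net, alpha = alpha)
    for (rep_name in representations) {
      features <- switch(rep_name,
        adjacency = adjacency_features(net),
        influence = influence_features(net, restart_prob = restart_prob),
        embedding = embedding_features(net, dim = embedding_dim, seed = sp$seed))
      model <- train_model(features, labels, inverse_reg = inverse_reg)
      tab <- predict_all(model, features, labels)
      novel <- tab[tab$known_novel == "Novel", ]
      novel_rank <- setNames(seq_len(nrow(novel)), novel$entrez)
      held_rank <- novel_rank[split$held]
      rows[[length(rows) + 1L]] <- data.frame(
        representation = rep_name, seed = s,
        n_held_out = length(split$held), n_novel = nrow(novel),
        mean_rank = if (length(split$held)) mean(held_rank) else NA_real_,
        top_decile_recall = if (length(split$held))
          mean(held_rank <= ceiling(nrow(novel) / 10)) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  means <- do.call(rbind, lapply(split(out, out$representation), function(d)
    data.frame(representation = d$representation[1L], seed = NA_integer_,
               n_held_out = mean(d$n_held_out), n_novel = mean(d$n_novel),
               mean_rank = mean(d$mean_rank),
               top_decile_recall = mean(d$top_decile_recall),
               stringsAsFactors = FALSE)))
  out <- rbind(out, means)
  rownames(out) <- NULL
  structure(out, class = c("recovery_report", "data.frame"),
            n_nodes = sum(spec$block_sizes),
            held_out_fraction = held_out_fraction)
}
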