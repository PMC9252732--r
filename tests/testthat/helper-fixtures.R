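# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# Erdos-Renyi-ish random weighted network over n synthetic Entrez IDs
random_network <- function(n, p = 0.2, seed = 1, name = "fix") {
  ids <- as.character(900000000 + seq_len(n))
  set.seed(seed)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  pairs <- pairs[keep, , drop = FALSE]
  # guarantee no isolated node: chain all nodes
  chain <- cbind(seq_len(n - 1), 2:n)
  pairs <- unique(rbind(pairs, chain))
  gene_network(data.frame(entrez_a = ids[pairs[, 1]],
                          entrez_b = ids[pairs[, 2]],
                          weight = round(runif(nrow(pairs), 0.2, 1), 3)),
               name = name)
}

toy_id_map <- function() {
  id_map(data.frame(
    alias = c("7157", "TP53", "BRCA1", "ENSG00000012048", "AMBIG", "AMBIG2",
              "AMBIG", "AMBIG2", "ENSP00000269305", "900000001", "672"),
    namespace = c("entrez", "symbol", "symbol", "ensembl_gene", "symbol",
                  "symbol", "symbol", "symbol", "ensembl_protein", "entrez",
                  "entrez"),
    entrez = c("7157", "7157", "672", "672", "111", "222", "333", "444",
               "7157", "900000001", "672")))
}

# independent brute-force negative selection used as the oracle in several
# tests: literal re-statement of the rule with no shared code
brute_force_negatives <- function(positives, collection, network, alpha) {
  universe <- intersect(collection$universe, network$nodes)
  pos_u <- intersect(positives, universe)
  candidates <- setdiff(universe, positives)
  excluded <- character(0)
  removed <- character(0)
  for (s in collection$sets) {
    members <- intersect(s$members, universe)
    if (!length(members)) next
    x <- length(intersect(members, pos_u))
    # exact upper-tail hypergeometric by enumeration with choose()
    N <- length(universe); K <- length(pos_u); m <- length(members)
    p <- sum(vapply(x:min(m, K), function(i)
      choose(K, i) * choose(N - K, m - i), numeric(1))) / choose(N, m)
    if (p < alpha) {
      excluded <- c(excluded, s$id)
      removed <- union(removed, members)
    }
  }
  list(negatives = sort(setdiff(candidates, removed)),
       excluded = sort(excluded))
}

# small labeled fixture for classifier tests: two gaussian clouds in 2-D
toy_training_problem <- function() {
  X <- matrix(c(-1.2, -0.8, -1.0, 1.1, 0.9, 1.0,
                -0.5, 0.3, -0.1, 0.4, -0.2, 0.6), ncol = 2)
  colnames(X) <- c("f1", "f2")
  list(X = X, y = c(0, 0, 0, 1, 1, 1))
}

# full netprio-ready synthetic scenario
sbm_scenario <- function(seed = 7, n_pos = 35) {
  spec <- synthetic_spec(seed = seed)
  net <- generate_network(spec)
  coll <- generate_collection(net, spec)
  blocks <- attr(net, "blocks")
  module <- names(blocks)[blocks == 1]
  list(spec = spec, network = net, collection = coll,
       module = module, positives = module[seq_len(n_pos)])
}
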