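test_that("adjacency features equal an independently built dense matrix", {
  net <- gene_network(data.frame(entrez_a = "10", entrez_b = "20",
                                 weight = 0.5))
  fm <- adjacency_features(net)
  expect_equal(unname(fm$values), matrix(c(0, 0.5, 0.5, 0), 2))

  net <- random_network(30, p = 0.2, seed = 9)
  fm <- adjacency_features(net)
  A <- matrix(0, 30, 30, dimnames = list(net$nodes, net$nodes))
  for (k in seq_len(nrow(net$edges))) {
    e <- net$edges[k, ]
    A[e$from, e$to] <- e$weight
    A[e$to, e$from] <- e$weight
  }
  expect_equal(fm$values, A)
  expect_equal(fm$values, t(fm$values))
  expect_true(all(diag(fm$values) == 0))
})

test_that("influence kernel: restart 1 gives identity; 2-node closed form", {
  net <- random_network(10, p = 0.3, seed = 2)
  expect_equal(unname(influence_features(net, 1)$values), diag(10))

  two <- gene_network(data.frame(entrez_a = "1", entrez_b = "2",
                                 weight = 3))
  for (a in c(0.15, 0.5, 0.85)) {
    F <- influence_features(two, a)$values
    # hand-inverted 2x2 system: P = [[0,1],[1,0]],
    # (I - (1-a)P)^-1 = 1/(1-(1-a)^2) * [[1, 1-a], [1-a, 1]]
    expect_equal(unname(F),
                 a / (1 - (1 - a)^2) * matrix(c(1, 1 - a, 1 - a, 1), 2),
                 tolerance = 1e-12)
  }
  expect_error(influence_features(net, 0), "restart_prob")
  expect_error(influence_features(net, 1.2), "restart_prob")
})

test_that("influence kernel matches the truncated power series and is row-stochastic", {
  for (seed in c(1, 2)) {
    net <- random_network(40, p = 0.12, seed = seed)
    a <- 0.85
    F <- influence_features(net, a)$values
    # truncated-series oracle: sum_k a (1-a)^k P^k
    A <- unname(adjacency_features(net)$values)
    P <- A / rowSums(A)
    S <- diag(40) * a
    Pk <- diag(40)
    for (k in 1:200) {
      Pk <- Pk %*% P
      S <- S + a * (1 - a)^k * Pk
    }
    expect_equal(unname(F), S, tolerance = 1e-8)
    expect_equal(unname(rowSums(F)), rep(1, 40), tolerance = 1e-8)
    expect_true(all(F >= 0))
  }
})

test_that("influence diagonal is monotone in the restart probability", {
  net <- random_network(25, p = 0.2, seed = 4)
  alphas <- c(0.1, 0.3, 0.5, 0.7, 0.9, 1)
  diags <- sapply(alphas, function(a)
    diag(influence_features(net, a)$values))
  expect_true(all(diff(t(diags)) >= -1e-12))
})

test_that("adjacency and influence are permutation-equivariant", {
  # relabeling genes permutes rows/columns but leaves values intact
  net <- random_network(15, p = 0.3, seed = 6)
  set.seed(60)
  relabel <- setNames(as.character(800 + sample(15)), net$nodes)
  e <- net$edges
  net2 <- gene_network(data.frame(entrez_a = unname(relabel[e$from]),
                                  entrez_b = unname(relabel[e$to]),
                                  weight = e$weight), name = net$name)
  for (build in list(adjacency_features,
                     function(n) influence_features(n, 0.85))) {
    F1 <- build(net)$values
    F2 <- build(net2)$values
    perm <- match(net2$nodes, unname(relabel[net$nodes]))
    expect_equal(unname(F2), unname(F1[perm, perm]), tolerance = 1e-12)
  }
})

test_that("walk-mass stays within connected components", {
  # two disjoint triangles: kernel is block diagonal, rows still sum to 1
  net <- gene_network(data.frame(
    entrez_a = c("1", "2", "3", "11", "12", "13"),
    entrez_b = c("2", "3", "1", "12", "13", "11"), weight = 1))
  F <- influence_features(net, 0.6)$values
  expect_equal(unname(rowSums(F)), rep(1, 6), tolerance = 1e-12)
  expect_equal(unname(F[1:3, 4:6]), matrix(0, 3, 3))
})

test_that("embeddings are deterministic given seed and parameters", {
  net <- random_network(30, p = 0.2, seed = 3)
  e1 <- embedding_features(net, dim = 8, walk_length = 20,
                           walks_per_node = 4, epochs = 2, seed = 42)
  e2 <- embedding_features(net, dim = 8, walk_length = 20,
                           walks_per_node = 4, epochs = 2, seed = 42)
  expect_identical(e1$values, e2$values)
  e3 <- embedding_features(net, dim = 8, walk_length = 20,
                           walks_per_node = 4, epochs = 2, seed = 43)
  expect_false(identical(e1$values, e3$values))
  expect_error(embedding_features(net, dim = -4), "positive")
  expect_warning(embedding_features(net, dim = 64, walk_length = 5,
                                    walks_per_node = 1, epochs = 1),
                 "fewer nodes")
})

test_that("unbiased walks (p = q = 1) follow the row-normalized adjacency", {
  net <- random_network(10, p = 0.4, seed = 8)
  A <- unname(adjacency_features(net)$values)
  P <- A / rowSums(A)
  walks <- node2vec_walks(net, walk_length = 100, walks_per_node = 100,
                          p = 1, q = 1, seed = 5)
  trans <- matrix(0, 10, 10)
  for (r in seq_len(nrow(walks))) {
    w <- walks[r, !is.na(walks[r, ])]
    for (t in seq_len(length(w) - 1))
      trans[w[t], w[t + 1]] <- trans[w[t], w[t + 1]] + 1
  }
  emp <- trans / rowSums(trans)
  expect_lt(max(abs(emp - P)), 0.02)
})

test_that("embeddings separate planted blocks", {
  # within-block cosine similarity should exceed between-block, every seed
  spec <- synthetic_spec(p_within = 0.3, p_between = 0.01)
  for (s in 1:5) {
    spec$seed <- s
    net <- generate_network(spec)
    blocks <- attr(net, "blocks")
    emb <- embedding_features(net, dim = 16, seed = s)$values
    emb <- emb / sqrt(rowSums(emb^2))
    S <- emb %*% t(emb)
    same <- outer(blocks, blocks, "==")
    diag(S) <- NA
    expect_gt(mean(S[same], na.rm = TRUE), mean(S[!same], na.rm = TRUE))
  }
})
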