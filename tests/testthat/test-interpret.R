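test_that("a corpus entry trained on the user's own genes ranks first with similarity 1", {
  sc <- sbm_scenario()
  fm <- adjacency_features(sc$network)
  fit <- suppressMessages(netprio(sc$positives, sc$network, sc$collection,
                                  features = fm, cv = FALSE))
  # collection containing the user's exact gene set plus distractors
  coll <- gene_set_collection(c(
    list(list(id = "SELF", name = "the user set", members = sc$positives)),
    sc$collection$sets), collection_name = "with_self")
  corpus <- suppressMessages(build_corpus(coll, fm, sc$network,
                                          sc$collection))
  sim <- rank_similar(fit$model, corpus)
  expect_equal(sim$set_id[1], "SELF")
  expect_equal(sim$rank[1], 1L)
  expect_equal(sim$similarity[1], 1, tolerance = 1e-12)
})

test_that("corpus entries equal individually invoked pipeline runs", {
  sc <- sbm_scenario()
  fm <- adjacency_features(sc$network)
  corpus <- suppressMessages(build_corpus(sc$collection, fm, sc$network,
                                          sc$collection, min_positives = 10))
  for (e in corpus$entries) {
    s <- Filter(function(x) x$id == e$set_id, sc$collection$sets)[[1]]
    pos <- suppressMessages(select_positives(s$members, sc$network))
    labels <- select_negatives(pos, sc$collection, sc$network)
    model <- train_model(fm, labels)
    expect_identical(e$model$weights, model$weights)
    expect_identical(e$model$intercept, model$intercept)
  }
})

test_that("sets below the in-network floor are skipped; empty corpus errors", {
  sc <- sbm_scenario()
  fm <- adjacency_features(sc$network)
  tiny <- gene_set_collection(list(
    list(id = "T", name = "tiny", members = sc$network$nodes[1:3])))
  expect_error(suppressMessages(
    build_corpus(tiny, fm, sc$network, sc$collection, min_positives = 10)),
    "empty corpus")
  mixed <- gene_set_collection(list(
    list(id = "T", name = "tiny", members = sc$network$nodes[1:3]),
    list(id = "OK", name = "ok", members = sc$module[1:20])))
  corpus <- suppressMessages(
    build_corpus(mixed, fm, sc$network, sc$collection, min_positives = 10))
  expect_length(corpus$entries, 1L)
  expect_equal(attr(corpus, "skipped"), "T")
})

test_that("similarity is cosine on weights: antipodes, symmetry, scale invariance", {
  w <- c(a = 1, b = -2, c = 0.5)
  mk <- function(weights) structure(
    list(weights = weights, intercept = 9, feature_fingerprint = "fp",
         label_counts = c(n_pos = 1, n_neg = 1), settings = list()),
    class = "trained_model")
  corpus <- structure(list(entries = list(
    list(set_id = "NEG", set_name = "antipode", model = mk(-w)),
    list(set_id = "POS", set_name = "same", model = mk(3 * w))),
    fingerprint = "fp", collection_name = "c"), class = "model_corpus")
  sim <- rank_similar(mk(w), corpus)
  expect_equal(sim$similarity[sim$set_id == "NEG"], -1, tolerance = 1e-12)
  # scale invariance: 3*w has similarity exactly 1; intercept ignored
  expect_equal(sim$similarity[sim$set_id == "POS"], 1, tolerance = 1e-12)
  # symmetry of the measure itself
  cs <- netprio:::cosine_similarity
  expect_equal(cs(w, -2 * w + 1), cs(-2 * w + 1, w), tolerance = 1e-15)
  # fingerprint mismatch refused
  user <- mk(w); user$feature_fingerprint <- "other"
  expect_error(rank_similar(user, corpus), "fingerprint")
})

test_that("similarities match brute-force cosines and ties break by set id", {
  sc <- sbm_scenario()
  fm <- adjacency_features(sc$network)
  fit <- suppressMessages(netprio(sc$positives, sc$network, sc$collection,
                                  features = fm, cv = FALSE))
  corpus <- suppressMessages(build_corpus(sc$collection, fm, sc$network,
                                          sc$collection))
  sim <- rank_similar(fit$model, corpus)
  for (e in corpus$entries) {
    u <- fit$model$weights; v <- e$model$weights
    bf <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))  # dot-product oracle
    expect_equal(sim$similarity[sim$set_id == e$set_id], bf,
                 tolerance = 1e-12)
  }
  expect_equal(sim$rank, seq_len(nrow(sim)))
  expect_false(is.unsorted(-sim$similarity))
})

test_that("saved models reload and interpret identically", {
  sc <- sbm_scenario()
  fm <- adjacency_features(sc$network)
  fit <- suppressMessages(netprio(sc$positives, sc$network, sc$collection,
                                  features = fm, cv = FALSE))
  d <- tempfile()
  save_trained_model(fit$model, d)
  back <- load_trained_model(d)
  expect_equal(back$weights, fit$model$weights)
  expect_equal(back$intercept, fit$model$intercept)
  expect_identical(back$feature_fingerprint, fit$model$feature_fingerprint)
  corpus <- suppressMessages(build_corpus(sc$collection, fm, sc$network,
                                          sc$collection))
  expect_equal(rank_similar(back, corpus)$similarity,
               rank_similar(fit$model, corpus)$similarity, tolerance = 1e-12)
})

test_that("corpora persist to a text directory and reload identically", {
  sc <- sbm_scenario()
  fm <- adjacency_features(sc$network)
  corpus <- suppressMessages(build_corpus(sc$collection, fm, sc$network,
                                          sc$collection))
  d <- tempfile()
  save_corpus(corpus, d)
  expect_true(file.exists(file.path(d, "manifest.json")))
  back <- load_corpus(d)
  expect_equal(back$fingerprint, corpus$fingerprint)
  expect_equal(length(back$entries), length(corpus$entries))
  expect_equal(back$entries[[1]]$model$weights,
               corpus$entries[[1]]$model$weights)
  # a reloaded corpus still interprets a model trained in-session
  fit <- suppressMessages(netprio(sc$positives, sc$network, sc$collection,
                                  features = fm, cv = FALSE))
  expect_s3_class(rank_similar(fit$model, back), "similarity_table")
})
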