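make_features <- function(X, representation = "test") {
  genes <- as.character(seq_len(nrow(X)) * 10)
  rownames(X) <- genes
  structure(list(representation = representation, genes = genes,
                 values = X,
                 params = list(network = "fix", n_nodes = nrow(X)),
                 fingerprint = paste0("fp-", representation, "-", nrow(X))),
            class = "feature_matrix")
}

make_labels <- function(genes, pos, neg) {
  structure(list(positives = pos, negatives = neg,
                 unused = setdiff(genes, c(pos, neg)),
                 excluded_sets = data.frame(set_id = character(0),
                                            overlap_count = integer(0),
                                            p_value = numeric(0))),
            class = "labeled_sets")
}

test_that("training matches a generic convex-optimizer oracle", {
  prob <- toy_training_problem()
  fm <- make_features(prob$X)
  labels <- make_labels(fm$genes, fm$genes[prob$y == 1], fm$genes[prob$y == 0])
  model <- train_model(fm, labels, inverse_reg = 1)

  # oracle: BFGS on the penalized objective, written from the loss definition
  obj <- function(theta, C = 1) {
    w <- theta[1:2]; b <- theta[3]
    z <- (2 * prob$y - 1) * (prob$X %*% w + b)
    0.5 * sum(w^2) + C * sum(log1p(exp(-z)))
  }
  oracle <- optim(c(0, 0, 0), obj, method = "BFGS",
                  control = list(reltol = 1e-15, maxit = 2000))$par
  expect_equal(unname(model$weights), oracle[1:2], tolerance = 1e-4)
  expect_equal(model$intercept, oracle[3], tolerance = 1e-4)
})

test_that("training agrees with glmnet ridge logistic at the equivalent lambda", {
  skip_if_not_installed("glmnet")
  set.seed(77)
  X <- matrix(rnorm(40 * 5), 40, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- rbinom(40, 1, 1 / (1 + exp(-X[, 1] + 0.5 * X[, 2])))
  if (sum(y) < 2 || sum(1 - y) < 2) y[1:2] <- c(0, 1)
  fit <- netprio:::fit_logistic(X, y, inverse_reg = 1)
  g <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                      lambda = 1 / (40 * 1), standardize = FALSE,
                      thresh = 1e-14, maxit = 1e6)
  expect_equal(unname(fit$weights), as.vector(coef(g))[-1], tolerance = 1e-5)
  expect_equal(fit$intercept, as.vector(coef(g))[1], tolerance = 1e-5)
})

test_that("a perfectly separating coordinate gets the dominant positive weight", {
  X <- cbind(sep = c(-1, -1, -1, 1, 1, 1), noise = c(0.1, -0.2, 0, 0.1, -0.1, 0))
  fm <- make_features(X)
  labels <- make_labels(fm$genes, fm$genes[4:6], fm$genes[1:3])
  model <- train_model(fm, labels)
  expect_gt(model$weights["sep"], 0)
  expect_gt(abs(model$weights["sep"]), abs(model$weights["noise"]))
})

test_that("uniformly duplicating training rows barely moves probabilities", {
  # duplication only rescales the loss-to-penalty ratio; at a realistic
  # training size the decision function is nearly unchanged
  set.seed(10)
  n <- 40
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rbinom(n, 1, 1 / (1 + exp(-(1.5 * X[, 1] - X[, 2]))))
  fm <- make_features(X)
  labels <- make_labels(fm$genes, fm$genes[y == 1], fm$genes[y == 0])
  m1 <- train_model(fm, labels)
  fm2 <- make_features(rbind(X, X))
  y2 <- c(y, y)
  labels2 <- make_labels(fm2$genes, fm2$genes[y2 == 1], fm2$genes[y2 == 0])
  m2 <- train_model(fm2, labels2)
  p1 <- 1 / (1 + exp(-(X %*% m1$weights + m1$intercept)))
  p2 <- 1 / (1 + exp(-(X %*% m2$weights + m2$intercept)))
  expect_lt(max(abs(p1 - p2)), 0.05)
})

test_that("degenerate single-class input errors", {
  prob <- toy_training_problem()
  fm <- make_features(prob$X)
  labels <- make_labels(fm$genes, fm$genes, character(0))
  expect_error(train_model(fm, labels), "at least one positive and one negative")
})

test_that("auPRC and auROC match brute-force threshold sweeps", {
  set.seed(123)
  for (rep in 1:3) {
    scores <- round(rnorm(20), 2)  # rounding forces some ties
    y <- rbinom(20, 1, 0.4)
    if (sum(y) == 0 || sum(y) == 20) y[1:2] <- c(0, 1)

    # brute-force sweep over every distinct threshold, from the definitions
    th <- sort(unique(scores), decreasing = TRUE)
    prec <- rec <- numeric(length(th))
    for (i in seq_along(th)) {
      called <- scores >= th[i]
      prec[i] <- sum(y == 1 & called) / sum(called)
      rec[i] <- sum(y == 1 & called) / sum(y == 1)
    }
    ap_bf <- sum(diff(c(0, rec)) * prec)
    expect_equal(auprc(scores, y), ap_bf, tolerance = 1e-12)

    # brute-force pair counting for auROC
    pos <- scores[y == 1]; neg <- scores[y == 0]
    wins <- 0
    for (p in pos) for (q in neg)
      wins <- wins + (p > q) + 0.5 * (p == q)
    expect_equal(auroc(scores, y), wins / (length(pos) * length(neg)),
                 tolerance = 1e-12)
  }
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auprc(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1)
})

test_that("cross-validation is gated at 15 positives and uses 3 folds", {
  set.seed(42)
  X <- matrix(rnorm(80 * 4), 80, 4, dimnames = list(NULL, paste0("f", 1:4)))
  fm <- make_features(X)

  lab14 <- make_labels(fm$genes, fm$genes[1:14], fm$genes[31:80])
  expect_message(cv <- cross_validate(fm, lab14), "skipped")
  expect_null(cv)

  lab15 <- make_labels(fm$genes, fm$genes[1:15], fm$genes[31:80])
  cv <- cross_validate(fm, lab15)
  expect_s3_class(cv, "cv_metrics")
  expect_equal(attr(cv, "n_folds"), 3)
  expect_equal(cv$fold, c("1", "2", "3", "mean"))
  expect_true(all(cv$auPRC >= 0 & cv$auPRC <= 1))
  expect_true(all(cv$auROC >= 0 & cv$auROC <= 1))
  expect_true(all(cv$P_topK >= 0 & cv$P_topK <= 1))
  # same seed, same folds, identical metrics
  expect_identical(as.data.frame(cross_validate(fm, lab15)),
                   as.data.frame(cv))
})

test_that("cross-validation recovers a strongly separable planted module", {
  # small module in a large background keeps the positive prior low enough
  # for the 3x-over-prior bar to be meaningful
  for (s in 1:5) {
    spec <- synthetic_spec(block_sizes = c(20, 80), p_within = 0.5,
                           p_between = 0.01, seed = s)
    net <- generate_network(spec)
    coll <- generate_collection(net, spec)
    module <- names(attr(net, "blocks"))[attr(net, "blocks") == 1]
    pos <- suppressMessages(select_positives(module[1:15], net))
    labels <- select_negatives(pos, coll, net)
    fm <- adjacency_features(net)
    cv <- cross_validate(fm, labels, seed = s)
    prior <- length(intersect(labels$positives, fm$genes)) /
      (length(intersect(labels$positives, fm$genes)) +
         length(intersect(labels$negatives, fm$genes)))
    expect_gt(cv$auPRC[cv$fold == "mean"], 3 * prior)
  }
})

test_that("genome-wide scoring: closed-form probabilities, labels, tie-breaking", {
  X <- matrix(c(2, 1, 0, -1, 1,
                0, 1, 1, 0, 1), ncol = 2,
              dimnames = list(NULL, c("f1", "f2")))
  fm <- make_features(X)
  labels <- make_labels(fm$genes, fm$genes[1], fm$genes[4])
  model <- structure(list(weights = c(f1 = 0.7, f2 = -0.3), intercept = 0.1,
                          feature_fingerprint = fm$fingerprint,
                          label_counts = c(n_pos = 1, n_neg = 1),
                          settings = list()), class = "trained_model")
  tab <- predict_all(model, fm, labels)
  expected <- 1 / (1 + exp(-(X %*% c(0.7, -0.3) + 0.1)))
  expect_equal(sort(tab$probability, decreasing = TRUE),
               sort(as.vector(expected), decreasing = TRUE),
               tolerance = 1e-10)
  # genes 2 and 5 have identical rows -> identical probabilities, Entrez order
  r2 <- tab[tab$entrez == "20", ]; r5 <- tab[tab$entrez == "50", ]
  expect_identical(r2$probability, r5$probability)
  expect_lt(r2$rank, r5$rank)
  # P -> Known, N/U -> Novel
  expect_equal(tab$known_novel[tab$training_label == "P"], "Known")
  expect_true(all(tab$known_novel[tab$training_label != "P"] == "Novel"))
  # rank is a bijection onto 1..n, probabilities strictly inside (0,1)
  expect_setequal(tab$rank, seq_len(nrow(tab)))
  expect_true(all(tab$probability > 0 & tab$probability < 1))
  # fingerprint mismatch is refused
  fm2 <- make_features(X, representation = "other")
  expect_error(predict_all(model, fm2, labels), "fingerprint")
})

test_that("display truncation keeps the exact rank prefix", {
  sc <- sbm_scenario()
  fit <- suppressMessages(netprio(sc$positives, sc$network, sc$collection,
                                  representation = "adjacency"))
  tab <- fit$predictions
  expect_identical(truncate_for_display(tab, 500), tab)  # below the cap
  t30 <- truncate_for_display(tab, 30)
  expect_equal(nrow(t30), 30L)
  expect_identical(as.data.frame(t30), as.data.frame(tab[1:30, ]))

  big <- tab[rep(seq_len(nrow(tab)), 12), ]  # 1200 rows
  big$rank <- seq_len(nrow(big))
  expect_equal(nrow(truncate_for_display(big)), 500L)
})

test_that("prediction tables serialize with the documented column names", {
  sc <- sbm_scenario()
  fit <- suppressMessages(netprio(sc$positives, sc$network, sc$collection,
                                  representation = "adjacency"))
  f <- tempfile(fileext = ".tsv")
  write_predictions(fit$predictions, f)
  header <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_equal(header, c("Entrez", "Symbol", "Name", "Probability",
                         "Training-Label", "Known/Novel", "Rank"))
})
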