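#' Fit a network-based gene classifier
#'
#' The main entry point: given a user gene set (Entrez IDs), a gene network,
#' and a gene-set collection for negative selection, this runs the full
#' supervised pipeline — positive selection, hypergeometric overlap-filtered
#' negative selection, feature construction, l2-regularized logistic
#' regression (inverse regularization C = 1 by default), optional stratified
#' 3-fold cross-validation (run when there are at least 15 positives), and
#' genome-wide scoring of every network gene.
#'
#' @param genes character vector of Entrez IDs (use [convert_ids()] first for
#'   symbols or Ensembl IDs).
#' @param network a `gene_network` (see [read_edge_list()]).
#' @param negative_collection a `gene_set_collection` (see [read_gmt()]) used
#'   to draw negative examples.
#' @param representation feature representation: `"adjacency"` (raw network
#'   connections), `"influence"` (random-walk-with-restart diffusion kernel),
#'   or `"embedding"` (node2vec vectors). Ignored when `features` is given.
#' @param features optional pre-built `feature_matrix` (reuse across fits).
#' @param overlap_alpha significance level of the negative-selection overlap
#'   test (default 0.05).
#' @param inverse_reg inverse regularization strength C (default 1).
#' @param restart_prob restart probability for the influence representation
#'   (default 0.85).
#' @param embedding_dim embedding dimension (default 128).
#' @param embedding_args named list of further [embedding_features()]
#'   arguments.
#' @param annotations optional data frame (`entrez`, `symbol`, `name`) for
#'   the display columns of the prediction table.
#' @param cv run cross-validation when the positive set allows it.
#' @param min_cv_positives minimum positive-set size for CV (default 15).
#' @param seed integer seed for CV fold assignment and the embedding
#'   generator (default 42).
#' @return An object of class `netprio`: a list with components `model`
#'   (a `trained_model`), `labels` (a `labeled_sets`), `cv` (a `cv_metrics`
#'   data frame or `NULL`), `predictions` (the genome-wide
#'   `prediction_table`), `settings`, and `call`. Methods: [print.netprio()],
#'   [summary.netprio()], [coef.netprio()], [predict.netprio()],
#'   [plot.netprio()].
#' @examples
#' spec <- synthetic_spec(seed = 7)
#' net <- generate_network(spec)
#' coll <- generate_collection(net, spec)
#' module <- names(attr(net, "blocks"))[attr(net, "blocks") == 1]
#' fit <- netprio(module[1:30], net, coll, representation = "adjacency")
#' fit
#' head(fit$predictions)
#' @export
netprio <- function(genes, network, negative_collection,
                    representation = c("adjacency", "influence", "embedding"),
                    features = NULL, overlap_alpha = 0.05, inverse_reg = 1,
                    restart_prob = 0.85, embedding_dim = 128,
                    embedding_args = list(), annotations = NULL,
                    cv = TRUE, min_cv_positives = 15, seed = 42) {
  stopifnot(inherits(network, "gene_network"),
            inherits(negative_collection, "gene_set_collection"))
  if (is.null(features)) {
    representation <- match.arg(representation)
    features <- switch(representation,
      adjacency = adjacency_features(network),
      influence = influence_features(network, restart_prob = restart_prob),
      embedding = do.call(embedding_features,
                          c(list(network = network, dim = embedding_dim,
                                 seed = seed), embedding_args)))
  } else {
    stopifnot(inherits(features, "feature_matrix"))
    representation <- features$representation
  }
  positives <- select_positives(genes, network)
  labels <- select_negatives(positives, negative_collection, network,
                             alpha = overlap_alpha)
  model <- train_model(features, labels, inverse_reg = inverse_reg)
  cv_res <- if (isTRUE(cv))
    cross_validate(features, labels, seed = seed,
                   min_positives = min_cv_positives,
                   inverse_reg = inverse_reg)
  predictions <- predict_all(model, features, labels,
                             annotations = annotations)
  structure(list(
    call = match.call(),
    model = model,
    labels = labels,
    cv = cv_res,
    predictions = predictions,
    settings = list(network = network$name,
                    representation = representation,
                    collection = negative_collection$collection_name,
                    overlap_alpha = overlap_alpha,
                    inverse_reg = inverse_reg,
                    seed = seed),
    feature_fingerprint = features$fingerprint
  ), class = "netprio")
}

#' @rdname netprio
#' @param x,object a `netprio` fit.
#' @param ... passed on to methods.
#' @export
print.netprio <- function(x, ...) {
  cat("netprio fit\n")
  cat(sprintf("  network: %s | representation: %s | negatives from: %s\n",
              x$settings$network, x$settings$representation,
              x$settings$collection))
  cat(sprintf("  labels: %d positive, %d negative, %d unused\n",
              length(x$labels$positives), length(x$labels$negatives),
              length(x$labels$unused)))
  if (!is.null(x$cv)) {
    m <- x$cv[x$cv$fold == "mean", ]
    cat(sprintf("  3-fold CV: auPRC %.3f | auROC %.3f | P@topK %.3f\n",
                m$auPRC, m$auROC, m$P_topK))
  } else cat("  cross-validation: not run (fewer than 15 positives)\n")
  cat(sprintf("  top prediction: %s (probability %.3f, %s)\n",
              x$predictions$entrez[1], x$predictions$probability[1],
              x$predictions$known_novel[1]))
  invisible(x)
}

#' Summarize a netprio fit
#'
#' @param object a `netprio` fit.
#' @param n_top number of top predictions to display.
#' @param ... ignored.
#' @export
summary.netprio <- function(object, n_top = 10, ...) {
  structure(list(fit = object, n_top = n_top,
                 top = truncate_for_display(object$predictions, n_top),
                 novel = truncate_for_display(
                   object$predictions[object$predictions$known_novel == "Novel", ],
                   n_top)),
            class = "summary.netprio")
}

#' @export
print.summary.netprio <- function(x, ...) {
  print(x$fit)
  excl <- x$fit$labels$excluded_sets
  if (nrow(excl)) {
    cat(sprintf("\n  %d gene set(s) excluded from negatives (overlap p < %g):\n",
                nrow(excl), x$fit$settings$overlap_alpha))
    print.data.frame(excl, digits = 3, row.names = FALSE)
  }
  cat("\nTop predictions:\n")
  print.data.frame(as.data.frame(x$top), digits = 4, row.names = FALSE)
  cat("\nTop novel candidates:\n")
  print.data.frame(as.data.frame(x$novel), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @rdname netprio
#' @export
coef.netprio <- function(object, ...) {
  c("(Intercept)" = unname(object$model$intercept), object$model$weights)
}

#' Predict association probabilities from a netprio fit
#'
#' With no new features, returns the stored genome-wide prediction table.
#' With a `feature_matrix` (whose fingerprint must match the one the model
#' was trained on), returns scores for its rows.
#'
#' @param object a `netprio` fit.
#' @param features optional `feature_matrix` to score.
#' @param type `"response"` for probabilities, `"link"` for the linear score.
#' @param ... ignored.
#' @export
predict.netprio <- function(object, features = NULL,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(features)) return(object$predictions)
  stopifnot(inherits(features, "feature_matrix"))
  if (!identical(object$feature_fingerprint, features$fingerprint))
    stop("feature fingerprint mismatch", call. = FALSE)
  eta <- drop(features$values %*% object$model$weights) +
    object$model$intercept
  if (type == "link") eta else 1 / (1 + exp(-eta))
}

#' Plot predicted probabilities by training label
#'
#' A quick diagnostic: positives should concentrate near 1, negatives near 0,
#' with the unused genes spread according to how module-like they are.
#'
#' @param x a `netprio` fit.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.netprio <- function(x, ...) {
  p <- x$predictions
  graphics::boxplot(probability ~ factor(training_label, c("P", "N", "U")),
                    data = p, xlab = "training label",
                    ylab = "predicted probability",
                    main = sprintf("%s / %s", x$settings$network,
                                   x$settings$representation), ...)
  invisible(x)
}
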