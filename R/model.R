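# Exact Newton (IRLS) fit of the l2-penalized logistic objective
#   0.5 * ||w||^2 + C * sum_i log(1 + exp(-y_i (w.x_i + b)))
# with the intercept unpenalized; C is the inverse regularization strength.
# The objective is strictly convex in w, so Newton converges to machine
# precision at these feature dimensions.
fit_logistic <- function(X, y, inverse_reg = 1, tol = 1e-6, max_iter = 100L) {
  stopifnot(is.matrix(X), length(y) == nrow(X), all(y %in% c(0, 1)))
  p <- ncol(X)
  Xa <- cbind(X, `(Intercept)` = 1)
  theta <- numeric(p + 1L)
  pen <- c(rep(1, p), 0)
  for (iter in seq_len(max_iter)) {
    eta <- drop(Xa %*% theta)
    mu <- 1 / (1 + exp(-eta))
    grad <- inverse_reg * drop(crossprod(Xa, mu - y)) + pen * theta
    wvar <- pmax(mu * (1 - mu), 1e-12)
    H <- inverse_reg * crossprod(Xa, Xa * wvar) + diag(pen, p + 1L)
    step <- solve(H, grad)
    theta <- theta - step
    if (max(abs(step)) < tol) break
  }
  list(weights = setNames(theta[seq_len(p)],
                          colnames(X) %||% paste0("f", seq_len(p))),
       intercept = unname(theta[p + 1L]), iterations = iter)
}

#' Train the gene classifier
#'
#' Fits an l2-regularized logistic regression on the network feature rows of
#' the positive and negative genes (unused genes are excluded from the fit).
#' The regularization follows the inverse convention: the objective is
#' `0.5 ||w||^2 + C * logistic loss` with `C = inverse_reg`, default 1.
#'
#' @param features a `feature_matrix`.
#' @param labels a `labeled_sets`.
#' @param inverse_reg inverse regularization strength C (default 1).
#' @return object of class `trained_model`: list with `weights`, `intercept`,
#'   `feature_fingerprint`, `label_counts`, `settings`.
#' @export
train_model <- function(features, labels, inverse_reg = 1) {
  stopifnot(inherits(features, "feature_matrix"),
            inherits(labels, "labeled_sets"))
  pos <- intersect(labels$positives, features$genes)
  neg <- intersect(labels$negatives, features$genes)
  if (length(pos) < 1L || length(neg) < 1L)
    stop("training requires at least one positive and one negative gene",
         call. = FALSE)
  X <- features$values[c(pos, neg), , drop = FALSE]
  y <- c(rep(1, length(pos)), rep(0, length(neg)))
  fit <- fit_logistic(X, y, inverse_reg = inverse_reg)
  structure(list(
    weights = fit$weights,
    intercept = fit$intercept,
    feature_fingerprint = features$fingerprint,
    label_counts = c(n_pos = length(pos), n_neg = length(neg)),
    settings = list(representation = features$representation,
                    network = features$params$network,
                    inverse_reg = inverse_reg)
  ), class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("trained_model (%s on '%s'): %d features, %d pos / %d neg\n",
              x$settings$representation, x$settings$network,
              length(x$weights), x$label_counts["n_pos"],
              x$label_counts["n_neg"]))
  invisible(x)
}

#' Save a trained model as plain text
#'
#' Writes `model_weights.tsv` and `model_meta.json` into `dir` so a finished
#' run can be interpreted against a corpus later.
#'
#' @param model a `trained_model`.
#' @param dir output directory (created if needed).
#' @export
save_trained_model <- function(model, dir) {
  stopifnot(inherits(model, "trained_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(data.frame(feature = names(model$weights),
                       weight = unname(model$weights)),
            file.path(dir, "model_weights.tsv"))
  jsonlite::write_json(list(intercept = model$intercept,
                            feature_fingerprint = model$feature_fingerprint,
                            label_counts = as.list(model$label_counts),
                            settings = model$settings),
                       file.path(dir, "model_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a trained model saved by [save_trained_model()]
#'
#' @param dir directory holding `model_weights.tsv` and `model_meta.json`.
#' @return a `trained_model`.
#' @export
load_trained_model <- function(dir) {
  tab <- utils::read.table(file.path(dir, "model_weights.tsv"), header = TRUE,
                           sep = "\t", colClasses = c("character", "numeric"))
  meta <- jsonlite::read_json(file.path(dir, "model_meta.json"),
                              simplifyVector = FALSE)
  structure(list(weights = setNames(tab$weight, tab$feature),
                 intercept = meta$intercept,
                 feature_fingerprint = meta$feature_fingerprint,
                 label_counts = unlist(meta$label_counts),
                 settings = meta$settings), class = "trained_model")
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: scores are swept from high to low and the
#' area is accumulated as `sum over thresholds of (delta recall) * precision`,
#' with tied scores treated as a single threshold.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (1 = positive).
#' @return auPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels)
  if (n_pos == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- which(!duplicated(s, fromLast = TRUE))  # end of each tie group
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic (ties count 1/2).
#'
#' @inheritParams auprc
#' @return auROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels); n_neg <- sum(1 - labels)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision among the top-K scored items
#'
#' Ties at the K-th score are resolved by the stable ordering of
#' `order(scores, decreasing = TRUE)`.
#'
#' @inheritParams auprc
#' @param k number of top items (defaults to the number of positives).
#' @return P@topK in \[0, 1\].
#' @export
precision_at_k <- function(scores, labels, k = sum(labels)) {
  stopifnot(length(scores) == length(labels), k >= 1)
  top <- order(scores, decreasing = TRUE)[seq_len(min(k, length(scores)))]
  mean(labels[top])
}

#' Cross-validate the classifier
#'
#' Internal model evaluation, performed only when the positive set has at
#' least `min_positives` genes (default 15): positives and negatives are each
#' shuffled with the given seed and split into `n_folds` stratified folds
#' (default 3); per fold a model is trained on the remainder exactly as
#' [train_model()] does and auPRC, auROC and P@topK (K = positives in the
#' held-out fold) are computed on the held-out genes.
#'
#' @param features a `feature_matrix`.
#' @param labels a `labeled_sets`.
#' @param seed integer seed for the fold assignment (default 42).
#' @param n_folds number of folds (default 3).
#' @param min_positives minimum positive-set size to run CV (default 15).
#' @param inverse_reg inverse regularization strength C.
#' @return object of class `cv_metrics` (data frame with one row per fold and
#'   a `mean` row; columns `fold`, `auPRC`, `auROC`, `P_topK`), or `NULL`
#'   when the positive set is too small (absence is a valid result).
#' @export
cross_validate <- function(features, labels, seed = 42, n_folds = 3,
                           min_positives = 15, inverse_reg = 1) {
  stopifnot(inherits(features, "feature_matrix"),
            inherits(labels, "labeled_sets"))
  pos <- intersect(labels$positives, features$genes)
  neg <- intersect(labels$negatives, features$genes)
  if (length(pos) < min_positives) {
    message("cross-validation skipped: ", length(pos), " positives < ",
            min_positives)
    return(NULL)
  }
  fold_of <- function(ids) with_seed(seed, {
    f <- rep_len(seq_len(n_folds), length(ids))
    setNames(f, sample(ids))
  })
  pf <- fold_of(pos); nf <- fold_of(neg)
  rows <- lapply(seq_len(n_folds), function(f) {
    test_pos <- names(pf)[pf == f]; test_neg <- names(nf)[nf == f]
    train_pos <- setdiff(pos, test_pos); train_neg <- setdiff(neg, test_neg)
    X <- features$values[c(train_pos, train_neg), , drop = FALSE]
    y <- c(rep(1, length(train_pos)), rep(0, length(train_neg)))
    fit <- fit_logistic(X, y, inverse_reg = inverse_reg)
    Xt <- features$values[c(test_pos, test_neg), , drop = FALSE]
    scores <- drop(Xt %*% fit$weights) + fit$intercept
    yt <- c(rep(1, length(test_pos)), rep(0, length(test_neg)))
    data.frame(fold = as.character(f),
               auPRC = auprc(scores, yt),
               auROC = auroc(scores, yt),
               P_topK = precision_at_k(scores, yt, k = length(test_pos)))
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(fold = "mean", auPRC = mean(out$auPRC),
                               auROC = mean(out$auROC),
                               P_topK = mean(out$P_topK)))
  structure(out, class = c("cv_metrics", "data.frame"),
            n_folds = n_folds, seed = seed)
}

#' Score every network gene with a trained model
#'
#' Applies the logistic model to all genes — positives, negatives, and
#' unused alike — producing the genome-wide prediction table. Rows are sorted
#' by predicted probability descending; ties are broken by ascending numeric
#' Entrez so the ranking is deterministic. Positive training genes are
#' labelled `Known`; negative and unused genes are `Novel` candidates.
#'
#' @param model a `trained_model`.
#' @param features the `feature_matrix` the model was trained on (the
#'   fingerprints must match; scoring against a different representation is
#'   refused).
#' @param labels a `labeled_sets`.
#' @param annotations optional data frame with columns `entrez`, `symbol`,
#'   `name` used to fill the display columns.
#' @return data frame of class `prediction_table` with columns `entrez`,
#'   `symbol`, `name`, `probability`, `training_label` (P/N/U),
#'   `known_novel`, `rank`.
#' @export
predict_all <- function(model, features, labels, annotations = NULL) {
  stopifnot(inherits(model, "trained_model"),
            inherits(features, "feature_matrix"),
            inherits(labels, "labeled_sets"))
  if (!identical(model$feature_fingerprint, features$fingerprint))
    stop("feature fingerprint mismatch: model was trained on a different ",
         "feature matrix", call. = FALSE)
  eta <- drop(features$values %*% model$weights) + model$intercept
  prob <- 1 / (1 + exp(-eta))
  lab <- label_vector(labels, list(nodes = features$genes))
  df <- data.frame(entrez = features$genes,
                   symbol = NA_character_, name = NA_character_,
                   probability = prob,
                   training_label = unname(lab[features$genes]),
                   stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    m <- match(df$entrez, as.character(annotations$entrez))
    if ("symbol" %in% names(annotations))
      df$symbol <- as.character(annotations$symbol)[m]
    if ("name" %in% names(annotations))
      df$name <- as.character(annotations$name)[m]
  }
  df$known_novel <- ifelse(df$training_label == "P", "Known", "Novel")
  ord <- order(-df$probability, as.numeric(df$entrez))
  df <- df[ord, c("entrez", "symbol", "name", "probability",
                  "training_label", "known_novel")]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  structure(df, class = c("prediction_table", "data.frame"))
}

#' Truncate a ranked table for display
#'
#' Display tables keep only the top entries (default 500) so they stay fast
#' to load; the full table remains available separately.
#'
#' @param table a `prediction_table` or `similarity_table` (any ranked data
#'   frame).
#' @param limit maximum number of rows (default 500).
#' @return the first `min(limit, nrow)` rows, classes preserved.
#' @export
truncate_for_display <- function(table, limit = 500) {
  stopifnot(is.data.frame(table), limit >= 1)
  table[seq_len(min(limit, nrow(table))), , drop = FALSE]
}

#' @export
print.prediction_table <- function(x, n = 10, ...) {
  cat(sprintf("prediction_table: %d genes (%d Known, %d Novel)\n",
              nrow(x), sum(x$known_novel == "Known"),
              sum(x$known_novel == "Novel")))
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4)
  if (nrow(x) > n) cat("... ", nrow(x) - n, " more rows\n", sep = "")
  invisible(x)
}

#' Write a prediction table to TSV or JSON
#'
#' Column headers are `Entrez`, `Symbol`, `Name`, `Probability`,
#' `Training-Label`, `Known/Novel`, `Rank`.
#'
#' @param table a `prediction_table`.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_predictions <- function(table, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  out <- as.data.frame(table)
  names(out) <- c("Entrez", "Symbol", "Name", "Probability", "Training-Label",
                  "Known/Novel", "Rank")
  if (format == "tsv") write_tsv(out, path)
  else jsonlite::write_json(out, path, digits = NA)
  invisible(path)
}
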