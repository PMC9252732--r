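#' Build a corpus of pre-trained models from a gene-set collection
#'
#' Trains one classifier per gene set, through exactly the same pipeline a
#' user set goes through ([select_positives()] -> [select_negatives()] ->
#' [train_model()]) with the same network, feature matrix, and negative
#' collection. Sets with fewer than `min_positives` in-network genes are
#' skipped (too few examples to learn from) and recorded in the `skipped`
#' attribute.
#'
#' @param collection `gene_set_collection` providing the sets to pre-train on.
#' @param features `feature_matrix` shared by all corpus entries.
#' @param network the `gene_network` the features were built from.
#' @param negative_collection `gene_set_collection` used for negative
#'   selection (usually the same collection).
#' @param alpha significance level of the overlap exclusion test.
#' @param min_positives minimum in-network positives to train an entry
#'   (default 10).
#' @param inverse_reg inverse regularization strength C.
#' @return object of class `model_corpus`: list with `entries` (each
#'   `set_id`, `set_name`, `model`) and `fingerprint` shared by all entries.
#' @export
build_corpus <- function(collection, features, network, negative_collection,
                         alpha = 0.05, min_positives = 10, inverse_reg = 1) {
  stopifnot(inherits(collection, "gene_set_collection"),
            inherits(features, "feature_matrix"),
            inherits(network, "gene_network"),
            inherits(negative_collection, "gene_set_collection"))
  skipped <- character(0)
  entries <- list()
  for (s in collection$sets) {
    in_net <- intersect(s$members, network$nodes)
    if (length(in_net) < min_positives) {
      skipped <- c(skipped, s$id)
      next
    }
    pos <- suppressMessages(select_positives(in_net, network))
    labels <- select_negatives(pos, negative_collection, network, alpha = alpha)
    model <- train_model(features, labels, inverse_reg = inverse_reg)
    entries[[length(entries) + 1L]] <-
      list(set_id = s$id, set_name = s$name, model = model)
  }
  if (length(skipped))
    message(length(skipped), " set(s) below the ", min_positives,
            "-gene floor skipped")
  if (length(entries) == 0L)
    stop("empty corpus: no set has enough in-network genes", call. = FALSE)
  structure(list(entries = entries,
                 fingerprint = features$fingerprint,
                 collection_name = collection$collection_name),
            class = "model_corpus", skipped = skipped)
}

#' @export
print.model_corpus <- function(x, ...) {
  cat(sprintf("model_corpus '%s': %d pre-trained models\n",
              x$collection_name, length(x$entries)))
  invisible(x)
}

cosine_similarity <- function(a, b) {
  sum(a * b) / sqrt(sum(a * a) * sum(b * b))
}

#' Rank pre-trained models by similarity to a user model
#'
#' Interpretation by model comparison: instead of enriching the gene list,
#' the user's trained classifier is compared to every corpus entry by the
#' cosine of their weight vectors (intercepts excluded). A pre-trained model
#' is similar when it exploits the same patterns of network connectivity,
#' even if its gene set barely overlaps the user's.
#'
#' @param user_model a `trained_model`.
#' @param corpus a `model_corpus` built with the same network, representation,
#'   and negative collection (fingerprints must match).
#' @return data frame of class `similarity_table` with columns `set_id`,
#'   `set_name`, `similarity` in \[-1, 1\], `rank` (ties broken by `set_id`
#'   lexicographically).
#' @export
rank_similar <- function(user_model, corpus) {
  stopifnot(inherits(user_model, "trained_model"),
            inherits(corpus, "model_corpus"))
  if (!identical(user_model$feature_fingerprint, corpus$fingerprint))
    stop("feature fingerprint mismatch: corpus was built on a different ",
         "feature matrix", call. = FALSE)
  sim <- vapply(corpus$entries, function(e)
    cosine_similarity(user_model$weights, e$model$weights), numeric(1))
  df <- data.frame(
    set_id = vapply(corpus$entries, `[[`, character(1), "set_id"),
    set_name = vapply(corpus$entries, `[[`, character(1), "set_name"),
    similarity = sim, stringsAsFactors = FALSE)
  df <- df[order(-df$similarity, df$set_id), ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  structure(df, class = c("similarity_table", "data.frame"))
}

#' Write a similarity table to TSV or JSON
#'
#' Column headers are `ID`, `Name`, `Similarity`, `Rank`.
#'
#' @param table a `similarity_table`.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_similarity <- function(table, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  out <- as.data.frame(table)
  names(out) <- c("ID", "Name", "Similarity", "Rank")
  if (format == "tsv") write_tsv(out, path)
  else jsonlite::write_json(out, path, digits = NA)
  invisible(path)
}

#' Save a model corpus to a directory
#'
#' Writes a `manifest.json` plus one per-set TSV of weights, all plain text,
#' so a corpus can be built once and reused across runs.
#'
#' @param corpus a `model_corpus`.
#' @param dir output directory (created if needed).
#' @export
save_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "model_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    collection_name = corpus$collection_name,
    fingerprint = corpus$fingerprint,
    entries = lapply(seq_along(corpus$entries), function(i) {
      e <- corpus$entries[[i]]
      list(set_id = e$set_id, set_name = e$set_name,
           file = sprintf("entry_%04d.tsv", i),
           intercept = e$model$intercept,
           label_counts = as.list(e$model$label_counts),
           settings = e$model$settings)
    }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(corpus$entries)) {
    w <- corpus$entries[[i]]$model$weights
    write_tsv(data.frame(feature = names(w), weight = unname(w)),
              file.path(dir, sprintf("entry_%04d.tsv", i)))
  }
  invisible(dir)
}

#' Load a model corpus saved by [save_corpus()]
#'
#' @param dir directory containing `manifest.json` and the weight files.
#' @return a `model_corpus`.
#' @export
load_corpus <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  entries <- lapply(manifest$entries, function(e) {
    tab <- utils::read.table(file.path(dir, e$file), header = TRUE,
                             sep = "\t", colClasses = c("character", "numeric"))
    model <- structure(list(
      weights = setNames(tab$weight, tab$feature),
      intercept = e$intercept,
      feature_fingerprint = manifest$fingerprint,
      label_counts = unlist(e$label_counts),
      settings = e$settings), class = "trained_model")
    list(set_id = e$set_id, set_name = e$set_name, model = model)
  })
  structure(list(entries = entries, fingerprint = manifest$fingerprint,
                 collection_name = manifest$collection_name),
            class = "model_corpus")
}
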