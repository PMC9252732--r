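#' Create a reproducible job configuration
#'
#' Bundles every parameter of a pipeline run into one object that serializes
#' to YAML and fully reproduces the run. A job name is generated as 8 random
#' alphanumeric characters, optionally prefixed with a memorable user string.
#'
#' @param genes_file path to the input gene list (newline- or
#'   comma-separated).
#' @param network_file path to the edge-list TSV.
#' @param collection_file path to the GMT collection used for negative
#'   selection.
#' @param id_map_file optional path to the 3-column ID-mapping TSV; when
#'   absent the gene list must already contain Entrez IDs.
#' @param network_name network display name (defaults to the file name).
#' @param representation feature representation.
#' @param overlap_alpha,inverse_reg,restart_prob,embedding_dim model
#'   parameters, as in [netprio()].
#' @param corpus_dir optional directory of a saved model corpus (see
#'   [save_corpus()]) for the interpretation stage.
#' @param n_subgraph_nodes,edge_threshold,prob_threshold subgraph-export
#'   parameters, as in [top_subgraph()].
#' @param display_limit row cap of the truncated display tables (default
#'   500).
#' @param seed integer seed used for CV folds and the embedding generator.
#' @param jobname_prefix optional prefix for the generated job name.
#' @param out_dir results directory (defaults to the job name under the
#'   current directory).
#' @return object of class `job_config`.
#' @export
job_config <- function(genes_file, network_file, collection_file,
                       id_map_file = NULL, network_name = NULL,
                       representation = c("adjacency", "influence",
                                          "embedding"),
                       overlap_alpha = 0.05, inverse_reg = 1,
                       restart_prob = 0.85, embedding_dim = 128,
                       corpus_dir = NULL, n_subgraph_nodes = 50,
                       edge_threshold = 0, prob_threshold = NULL,
                       display_limit = 500, seed = 42,
                       jobname_prefix = "", out_dir = NULL) {
  representation <- match.arg(representation)
  pool <- c(LETTERS, letters, 0:9)
  jobname <- paste0(jobname_prefix,
                    paste(sample(pool, 8, replace = TRUE), collapse = ""))
  if (!grepl("^[A-Za-z0-9_-]*[A-Za-z0-9]{8}$", jobname))
    stop("jobname_prefix may only contain letters, digits, '_' and '-'",
         call. = FALSE)
  cfg <- list(jobname = jobname, genes_file = genes_file,
              network_file = network_file, collection_file = collection_file,
              id_map_file = id_map_file,
              network_name = network_name %||%
                sub("\\.[^.]*$", "", basename(network_file)),
              representation = representation, overlap_alpha = overlap_alpha,
              inverse_reg = inverse_reg, restart_prob = restart_prob,
              embedding_dim = embedding_dim, corpus_dir = corpus_dir,
              n_subgraph_nodes = n_subgraph_nodes,
              edge_threshold = edge_threshold,
              prob_threshold = prob_threshold,
              display_limit = display_limit, seed = as.integer(seed),
              out_dir = out_dir %||% jobname)
  structure(cfg, class = "job_config")
}

#' Read a job configuration from YAML
#'
#' @param path YAML file written by [write_job_config()] (or by hand).
#' @return a `job_config`.
#' @export
read_job_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "job_config")
}

#' Write a job configuration to YAML
#'
#' @param config a `job_config`.
#' @param path output path.
#' @export
write_job_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full pipeline from a job configuration
#'
#' Executes every stage — ID conversion (when an ID map is supplied), network
#' loading and overlap summary, feature construction, label selection, model
#' training with optional cross-validation, genome-wide prediction,
#' interpretation against a saved corpus (when supplied), and subgraph
#' export — writing all results plus the resolved configuration and a run log
#' into the output directory, and bundling everything into one compressed
#' archive (`results.tar.gz`). Any stage failure is reported with the stage
#' name and a remediation hint.
#'
#' @param config a `job_config`.
#' @return invisibly, a list with the fitted `netprio` object, the
#'   `similarity_table` (or `NULL`), the `subgraph_export`, the output
#'   directory, and the archive path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "job_config"))
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
    log_lines <<- c(log_lines, line)
  }
  collect <- function(expr) withCallingHandlers(expr, message = function(m) {
    log_lines <<- c(log_lines, sub("\n$", "", conditionMessage(m)))
    invokeRestart("muffleMessage")
  })
  for (f in c("genes_file", "network_file", "collection_file")) {
    if (!file.exists(config[[f]] %||% ""))
      stop_stage("input", paste0(f, " not found: ", config[[f]]),
                 hint = "check the paths in the job configuration")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  note("job ", config$jobname, " started (seed ", config$seed, ")")

  # --- input: gene list and optional ID conversion -------------------------
  raw_ids <- read_gene_list(config$genes_file)
  annotations <- NULL
  if (!is.null(config$id_map_file)) {
    map <- read_id_map(config$id_map_file)
    conv <- collect(convert_ids(raw_ids, map))
    note(sprintf("id conversion: %d mapped, %d unmapped, %d ambiguous",
                 nrow(conv$mapped), length(conv$unmapped),
                 nrow(conv$ambiguous)))
    write_tsv(conv$mapped, file.path(config$out_dir, "conversion_mapped.tsv"))
    jsonlite::write_json(list(unmapped = conv$unmapped,
                              ambiguous = conv$ambiguous),
                         file.path(config$out_dir, "conversion_issues.json"),
                         digits = NA)
    entrez <- conv$mapped$entrez
    sym <- map[map$namespace == "symbol", ]
    annotations <- data.frame(entrez = sym$entrez, symbol = sym$alias,
                              name = NA_character_)
  } else {
    entrez <- trimws(raw_ids)
    if (!all(is_entrez(entrez)))
      stop_stage("input", "gene list contains non-Entrez ids",
                 hint = "supply id_map_file to convert symbols/Ensembl ids")
  }
  if (length(entrez) == 0L)
    stop_stage("input", "no genes supplied after conversion",
               hint = "check the identifier namespace of your gene list")

  # --- network -------------------------------------------------------------
  network <- tryCatch(read_edge_list(config$network_file,
                                     name = config$network_name),
                      error = function(e) stop_stage("network",
                                                     conditionMessage(e)))
  overlap <- summarize_overlap(entrez, network)
  write_overlap_summary(overlap, file.path(config$out_dir,
                                           "overlap_summary.tsv"))
  note(sprintf("network '%s': %d nodes, %d edges; %d/%d input genes present",
               network$name, length(network$nodes), nrow(network$edges),
               overlap$n_in_network[1], overlap$n_input_mapped[1]))

  # --- model ---------------------------------------------------------------
  collection <- tryCatch(read_gmt(config$collection_file),
                         error = function(e) stop_stage("labels",
                                                        conditionMessage(e)))
  fit <- tryCatch(collect(netprio(
    entrez, network, collection,
    representation = config$representation,
    overlap_alpha = config$overlap_alpha,
    inverse_reg = config$inverse_reg,
    restart_prob = config$restart_prob,
    embedding_dim = config$embedding_dim,
    annotations = annotations,
    seed = config$seed)),
    error = function(e) stop_stage("model", conditionMessage(e),
                                   hint = "try another network, collection, or representation"))
  labels_df <- data.frame(entrez = c(fit$labels$positives,
                                     fit$labels$negatives,
                                     fit$labels$unused),
                          training_label = c(
                            rep("P", length(fit$labels$positives)),
                            rep("N", length(fit$labels$negatives)),
                            rep("U", length(fit$labels$unused))))
  write_tsv(labels_df, file.path(config$out_dir, "labeled_sets.tsv"))
  if (nrow(fit$labels$excluded_sets))
    write_tsv(fit$labels$excluded_sets,
              file.path(config$out_dir, "excluded_sets.tsv"))
  if (!is.null(fit$cv))
    jsonlite::write_json(list(n_folds = attr(fit$cv, "n_folds"),
                              seed = attr(fit$cv, "seed"),
                              metrics = as.data.frame(fit$cv)),
                         file.path(config$out_dir, "cv_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  save_trained_model(fit$model, config$out_dir)
  write_predictions(fit$predictions,
                    file.path(config$out_dir, "predictions_full.tsv"))
  write_predictions(truncate_for_display(fit$predictions,
                                         config$display_limit),
                    file.path(config$out_dir, "predictions_top.tsv"))
  note(sprintf("model trained: %d positives, %d negatives; %d genes scored",
               length(fit$labels$positives), length(fit$labels$negatives),
               nrow(fit$predictions)))

  # --- interpretation ------------------------------------------------------
  similarity <- NULL
  if (!is.null(config$corpus_dir)) {
    corpus <- tryCatch(load_corpus(config$corpus_dir),
                       error = function(e) stop_stage("interpret",
                                                      conditionMessage(e)))
    similarity <- tryCatch(rank_similar(fit$model, corpus),
                           error = function(e) stop_stage("interpret",
                                                          conditionMessage(e),
                                                          hint = "corpus must share network/representation/collection settings"))
    write_similarity(similarity,
                     file.path(config$out_dir, "similarity_full.tsv"))
    write_similarity(truncate_for_display(similarity, config$display_limit),
                     file.path(config$out_dir, "similarity_top.tsv"))
    note(sprintf("interpretation: %d corpus models ranked",
                 nrow(similarity)))
  }

  # --- subgraph ------------------------------------------------------------
  subgraph <- top_subgraph(fit$predictions, network,
                           n_nodes = config$n_subgraph_nodes,
                           prob_threshold = config$prob_threshold,
                           edge_threshold = config$edge_threshold)
  write_subgraph(subgraph, file.path(config$out_dir, "subgraph.json"),
                 format = "json")
  write_subgraph(subgraph, file.path(config$out_dir, "subgraph.graphml"),
                 format = "graphml")
  note(sprintf("subgraph: %d nodes, %d edges exported",
               nrow(subgraph$nodes), nrow(subgraph$edges)))

  # --- metadata + archive --------------------------------------------------
  write_job_config(config, file.path(config$out_dir, "config.yaml"))
  note("job ", config$jobname, " finished")
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  archive <- file.path(config$out_dir, "results.tar.gz")
  old <- setwd(config$out_dir)
  on.exit(setwd(old))
  utils::tar("results.tar.gz",
             files = setdiff(list.files("."), "results.tar.gz"),
             compression = "gzip", tar = "internal")
  setwd(old)
  on.exit()
  invisible(list(fit = fit, similarity = similarity, subgraph = subgraph,
                 out_dir = config$out_dir, archive = archive))
}
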