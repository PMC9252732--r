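ID_NAMESPACES <- c("symbol", "ensembl_gene", "ensembl_protein",
                   "ensembl_transcript", "entrez")

#' Read an identifier-mapping table
#'
#' The table drives all identifier conversion; no live queries are made.
#' Format: 3-column TSV with header, columns `alias`, `namespace`, `entrez`.
#' `namespace` is one of `symbol`, `ensembl_gene`, `ensembl_protein`,
#' `ensembl_transcript`, `entrez`. An alias may map to several Entrez IDs
#' (ambiguity is representable and reported by [convert_ids()]).
#'
#' @param path path to the TSV.
#' @return data frame of class `id_map` with columns `alias`, `namespace`,
#'   `entrez`.
#' @export
read_id_map <- function(path) {
  if (!file.exists(path)) stop("id map file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("id map is empty: ", path, call. = FALSE)
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad))
    stop("id map line ", bad[1L] + 1L, ": expected 3 tab-separated columns",
         call. = FALSE)
  df <- data.frame(
    alias     = trimws(vapply(fields, `[[`, character(1), 1L)),
    namespace = trimws(vapply(fields, `[[`, character(1), 2L)),
    entrez    = trimws(vapply(fields, `[[`, character(1), 3L)),
    stringsAsFactors = FALSE
  )
  id_map(df)
}

#' Construct an identifier-mapping table from a data frame
#'
#' @param df data frame with columns `alias`, `namespace`, `entrez`.
#' @return validated `id_map`.
#' @export
id_map <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("alias", "namespace", "entrez") %in% names(df)))
  df <- df[, c("alias", "namespace", "entrez")]
  df[] <- lapply(df, as.character)
  bad_ns <- !df$namespace %in% ID_NAMESPACES
  if (any(bad_ns))
    stop("unknown namespace '", df$namespace[bad_ns][1L], "' in id map",
         call. = FALSE)
  if (!all(is_entrez(df$entrez)))
    stop("id map entrez values must be digit strings", call. = FALSE)
  if (anyDuplicated(df[c("alias", "namespace", "entrez")]))
    df <- unique(df)
  structure(df, class = c("id_map", "data.frame"))
}

#' Read a plain-text gene list
#'
#' Accepts newline- or comma-separated identifiers; whitespace is stripped and
#' empty tokens dropped.
#'
#' @param path path to the file.
#' @return character vector of raw identifiers, in file order.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  ids <- trimws(unlist(strsplit(raw, "[,\n]")))
  ids[nzchar(ids)]
}

#' Convert heterogeneous gene identifiers to Entrez space
#'
#' Inputs may mix Entrez IDs, gene symbols, and Ensembl gene / protein /
#' transcript IDs. Matching is table-driven: case-insensitive for symbols
#' (common user-file variation), case-sensitive for everything else.
#' Duplicate inputs are collapsed to their first occurrence. Each distinct
#' cleaned input lands in exactly one bucket:
#' * `mapped` — exactly one candidate Entrez ID (and that ID not already
#'   claimed by an earlier input; later aliases of an already-mapped gene are
#'   reported in the `collapsed` attribute so no Entrez appears twice),
#' * `ambiguous` — more than one candidate Entrez ID; reported, never guessed,
#' * `unmapped` — no match in the table.
#'
#' @param raw_ids character vector of identifiers (whitespace tolerated).
#' @param table an `id_map`.
#' @return object of class `conversion_result`: list with `mapped` (data frame
#'   `input_alias`, `entrez`), `unmapped` (character), `ambiguous` (data frame
#'   `input_alias`, `candidates` comma-joined), plus attributes
#'   `n_duplicates` (identical inputs collapsed) and `collapsed` (aliases
#'   whose Entrez was already mapped by an earlier alias).
#' @examples
#' tab <- id_map(data.frame(alias = c("7157", "TP53"),
#'                          namespace = c("entrez", "symbol"),
#'                          entrez = c("7157", "7157")))
#' convert_ids(c("TP53", "7157"), tab)
#' @export
convert_ids <- function(raw_ids, table) {
  stopifnot(inherits(table, "id_map"))
  ids <- trimws(as.character(raw_ids))
  ids <- ids[nzchar(ids)]
  if (length(ids) == 0L) stop("no genes supplied", call. = FALSE)
  n_dup <- sum(duplicated(ids))
  if (n_dup > 0L) message(n_dup, " duplicate input id(s) collapsed")
  ids <- ids[!duplicated(ids)]

  sym <- table$namespace == "symbol"
  sym_key <- tolower(table$alias[sym])
  sym_val <- table$entrez[sym]
  other_key <- table$alias[!sym]
  other_val <- table$entrez[!sym]

  mapped_alias <- character(0); mapped_entrez <- character(0)
  unmapped <- character(0)
  amb_alias <- character(0); amb_cand <- character(0)
  collapsed <- character(0)
  seen <- character(0)

  for (id in ids) {
    cand <- unique(c(other_val[other_key == id],
                     sym_val[sym_key == tolower(id)]))
    if (length(cand) == 0L) {
      unmapped <- c(unmapped, id)
    } else if (length(cand) > 1L) {
      amb_alias <- c(amb_alias, id)
      amb_cand <- c(amb_cand, paste(order_entrez(cand), collapse = ","))
    } else if (cand %in% seen) {
      collapsed <- c(collapsed, id)
    } else {
      mapped_alias <- c(mapped_alias, id)
      mapped_entrez <- c(mapped_entrez, cand)
      seen <- c(seen, cand)
    }
  }
  structure(list(
    mapped    = data.frame(input_alias = mapped_alias, entrez = mapped_entrez,
                           stringsAsFactors = FALSE),
    unmapped  = unmapped,
    ambiguous = data.frame(input_alias = amb_alias, candidates = amb_cand,
                           stringsAsFactors = FALSE)
  ), class = "conversion_result", n_duplicates = n_dup, collapsed = collapsed)
}

#' @export
print.conversion_result <- function(x, ...) {
  cat(sprintf("id conversion: %d mapped, %d unmapped, %d ambiguous\n",
              nrow(x$mapped), length(x$unmapped), nrow(x$ambiguous)))
  invisible(x)
}

#' Summarize overlap of a gene set with one or more networks
#'
#' For each network, counts how many of the supplied Entrez IDs are present
#' among its nodes — the validation summary a user consults before choosing a
#' network.
#'
#' @param entrez_ids character vector of Entrez IDs (typically
#'   `conversion_result$mapped$entrez`).
#' @param networks a `gene_network` or list of them.
#' @return data frame of class `overlap_summary` with columns `network_name`,
#'   `n_input_mapped`, `n_in_network`, `fraction_in_network`.
#' @export
summarize_overlap <- function(entrez_ids, networks) {
  if (inherits(networks, "gene_network")) networks <- list(networks)
  stopifnot(length(networks) > 0L,
            all(vapply(networks, inherits, logical(1), "gene_network")))
  ids <- unique(as.character(entrez_ids))
  n <- length(ids)
  rows <- lapply(networks, function(net) {
    k <- length(intersect(ids, net$nodes))
    data.frame(network_name = net$name, n_input_mapped = n, n_in_network = k,
               fraction_in_network = if (n == 0L) 0 else k / n,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("overlap_summary", "data.frame"))
}

#' Write an overlap summary to TSV or JSON
#'
#' @param summary an `overlap_summary`.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_overlap_summary <- function(summary, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") write_tsv(as.data.frame(summary), path)
  else jsonlite::write_json(as.data.frame(summary), path, digits = NA)
  invisible(path)
}
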