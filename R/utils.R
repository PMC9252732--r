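`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
is_entrez <- function(x) grepl("^[0-9]+$", x)

# canonical node order: ascending numeric Entrez
order_entrez <- function(x) x[order(as.numeric(x))]

# one canonical string per parameter set; embedded in every feature matrix and
# trained model so cross-representation scoring can be refused
make_fingerprint <- function(...) {
  params <- list(...)
  stopifnot(!is.null(names(params)), all(nzchar(names(params))))
  params <- params[order(names(params))]
  paste(vapply(names(params), function(k) {
    v <- params[[k]]
    paste0(k, "=", paste(format(v, digits = 15, scientific = FALSE,
                                trim = TRUE), collapse = ","))
  }, character(1)), collapse = "|")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

stop_stage <- function(stage, msg, hint = NULL, call. = FALSE) {
  full <- sprintf("[%s] %s", stage, msg)
  if (!is.null(hint)) full <- paste0(full, "\n  hint: ", hint)
  stop(full, call. = call.)
}

# run code with a private RNG stream, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
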