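# serialization: payoff tables and chains as TSV (matrix with headers) and
# JSON (full object incl. strategies, game and terms)

#' Write and read payoff tables
#'
#' `write_payoff_table()` serialises a [payoff_table()] either as TSV (the
#' matrix with strategy names as row and column headers) or as JSON
#' carrying the ordered strategy list with traits, the nested payoff
#' array, and the game and commitment terms. `read_payoff_table()` reads
#' either format back; a TSV file only stores the matrix, so strategy
#' traits are restored from the sharing catalog when the names match and
#' left `NA` otherwise.
#'
#' @param x A `payoff_table`.
#' @param path Output/input file path.
#' @param format `"tsv"` or `"json"`; inferred from the file extension
#'   when omitted.
#'
#' @return `write_payoff_table()` returns `path` invisibly;
#'   `read_payoff_table()` returns a `payoff_table`.
#' @export
write_payoff_table <- function(x, path, format = NULL) {
  stopifnot(inherits(x, "payoff_table"))
  format <- format %||% tools_ext(path)
  if (format == "tsv") {
    utils::write.table(x$payoff, path, sep = "\t", quote = FALSE,
                       col.names = NA)
  } else if (format == "json") {
    obj <- list(strategies = x$strategies, payoff = unname(x$payoff),
                game = unclass(x$game), terms = unclass(x$terms))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unknown format '", format, "'", call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_payoff_table
#' @export
read_payoff_table <- function(path, format = NULL) {
  format <- format %||% tools_ext(path)
  if (format == "tsv") {
    M <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                     row.names = 1, check.names = FALSE))
    catalog <- strategy_catalog("sharing")
    idx <- match(rownames(M), catalog$name)
    strategies <- tibble::tibble(
      name = rownames(M),
      proposes = catalog$proposes[idx],
      accepts_full = catalog$accepts_full[idx],
      accepts_shared = catalog$accepts_shared[idx],
      committed = catalog$committed[idx],
      uncommitted = catalog$uncommitted[idx]
    )
    structure(list(strategies = strategies, payoff = M,
                   game = NULL, terms = NULL), class = "payoff_table")
  } else if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    M <- as.matrix(obj$payoff)
    dimnames(M) <- list(obj$strategies$name, obj$strategies$name)
    structure(
      list(strategies = tibble::as_tibble(obj$strategies), payoff = M,
           game = do.call(game_matrix,
                          c(obj$game, list(check_pd = FALSE))),
           terms = do.call(commitment_terms, obj$terms)),
      class = "payoff_table")
  } else {
    stop("unknown format '", format, "'", call. = FALSE)
  }
}

#' Write a small-mutation chain
#'
#' JSON output carries the ordered strategies, the transition matrix, the
#' stationary distribution and the population parameters; TSV output holds
#' the stationary distribution as a two-column table.
#'
#' @param x A `small_mutation_chain`.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`; inferred from the extension when
#'   omitted.
#' @return `path`, invisibly.
#' @export
write_chain <- function(x, path, format = NULL) {
  stopifnot(inherits(x, "small_mutation_chain"))
  format <- format %||% tools_ext(path)
  if (format == "tsv") {
    utils::write.table(tidy(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "json") {
    obj <- list(strategies = x$strategies, M = unname(x$M),
                stationary = unname(x$stationary), N = x$N, beta = x$beta)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unknown format '", format, "'", call. = FALSE)
  }
  invisible(path)
}

tools_ext <- function(path) {
  ext <- tolower(sub(".*\\.", "", basename(path)))
  if (ext %in% c("tsv", "txt")) "tsv" else ext
}

`%||%` <- function(a, b) if (is.null(a)) b else a
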