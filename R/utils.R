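#' @keywords internal
"_PACKAGE"

# Separators used everywhere text is tokenized: whitespace, comma, hyphen,
# slash, parentheses, and remaining punctuation.  Case is folded so that
# matching and frequency counting are case-insensitive.
.token_split_re <- "[^[:alnum:]*]+"

#' Tokenize free text
#'
#' Lower-cases and splits text into alphanumeric tokens.  Hyphens, slashes,
#' commas, parentheses and all other punctuation act as separators, so an
#' alias such as `"A-2"` becomes the token sequence `c("a", "2")`.  Embedded
#' `*` characters are preserved so wildcard query terms survive tokenization.
#'
#' @param text character vector.
#' @return a list (one element per input string) of character token vectors.
#' @export
tokenize <- function(text) {
  text[is.na(text)] <- ""
  toks <- strsplit(tolower(text), .token_split_re)
  lapply(toks, function(x) x[nzchar(x)])
}

# Deterministic substream seed derived from a master seed and a stream name.
# Each simulated table draws from its own substream so that adding one table
# never perturbs another.  Kept below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- 0
  for (cp in utf8ToInt(name)) h <- (h * 131 + cp) %% 2147483629
  as.integer((as.numeric(seed) %% 2147483629 * 7919 + h) %% 2147483629 + 1)
}

# Evaluate `expr` under a named RNG substream, restoring the caller's RNG
# state afterwards.
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}

#' Read / write tab-separated tables
#'
#' Thin wrappers around [utils::read.delim()] / [utils::write.table()] with
#' the conventions used by every table in this package: a header row, no
#' quoting, no row names, and `"."` never treated as missing.  Output is
#' byte-stable for a given data frame, which the simulator's determinism
#' contract relies on.
#'
#' @param x data frame to write.
#' @param path file path.
#' @return `read_tsv_table()` returns a data frame; `write_tsv_table()`
#'   returns `path` invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# Collapse / expand pipe-separated list columns (gene_info dialect: "-" for
# an empty synonym list).
collapse_pipes <- function(x) {
  vapply(x, function(v) if (length(v) == 0L) "-" else paste(v, collapse = "|"),
         character(1))
}

split_pipes <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || s == "-" || !nzchar(s)) character(0)
    else strsplit(s, "|", fixed = TRUE)[[1]]
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
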