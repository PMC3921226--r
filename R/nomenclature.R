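#' Read a gene_info-dialect nomenclature table
#'
#' Expects TSV columns `gene_id`, `symbol`, `synonyms` (pipe-separated, `-`
#' when empty), `full_name`, and optionally `species`.
#'
#' @param path file path.
#' @return data frame with a `synonyms` pipe-separated column.
#' @export
read_gene_info <- function(path) {
  df <- read_tsv_table(path)
  need <- c("gene_id", "symbol", "synonyms", "full_name")
  if (!all(need %in% names(df)))
    stop("gene_info table must have columns: ", paste(need, collapse = ", "))
  for (col in need) df[[col]] <- as.character(df[[col]])
  df
}

# All searchable names for one gene record: symbol plus synonyms.
gene_aliases <- function(record) {
  unique(c(record$symbol, split_pipes(record$synonyms)[[1]]))
}

#' Flag ambiguous gene names
#'
#' Classifies every alias (official symbol and synonyms) of every gene into
#' one of four categories, checked in order of precedence with first match
#' winning:
#' \describe{
#'   \item{english_word}{case-insensitive match against a common English
#'     word list (e.g. "CALM");}
#'   \item{acronym_multisense}{used with more than one sense according to an
#'     acronym-sense table (e.g. "NSE", which is both neuron-specific
#'     enolase and "normal squamous epithelia");}
#'   \item{short}{too short for unambiguous retrieval -- at most
#'     `short_cutoff` characters after stripping hyphens (e.g. "sp", "F3",
#'     "A-2");}
#'   \item{none}{everything else.}
#' }
#'
#' A known multi-sense acronym outranks the length rule so that short
#' acronyms keep their informative category; plain short strings absent
#' from the sense table still fall through to `short`.
#'
#' @param records gene nomenclature data frame (see [read_gene_info()]).
#' @param english_words character vector of lower-case English words.
#' @param acronym_senses data frame with columns `alias` and `n_senses`
#'   (number of distinct senses observed for the alias); may be `NULL`.
#' @param short_cutoff maximum length counted as "short" (default 3).
#' @return data frame with one row per (gene, alias): `gene_id`, `alias`,
#'   `category`.
#' @export
flag_ambiguous_names <- function(records, english_words,
                                 acronym_senses = NULL, short_cutoff = 3) {
  english_words <- unique(tolower(english_words))
  sense_count <- integer(0)
  if (!is.null(acronym_senses) && nrow(acronym_senses)) {
    sense_count <- acronym_senses$n_senses
    names(sense_count) <- tolower(acronym_senses$alias)
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    aliases <- gene_aliases(records[i, ])
    aliases <- aliases[!is.na(aliases) & nzchar(aliases)]
    if (!length(aliases)) return(NULL)
    cat_of <- vapply(aliases, function(a) {
      la <- tolower(a)
      if (la %in% english_words) return("english_word")
      ns <- sense_count[la]
      if (!is.na(ns) && ns > 1) return("acronym_multisense")
      if (nchar(gsub("-", "", a, fixed = TRUE)) <= short_cutoff)
        return("short")
      "none"
    }, character(1))
    data.frame(gene_id = records$gene_id[i], alias = aliases,
               category = unname(cat_of), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Derive one informative keyword per gene
#'
#' Splits compound full gene/protein names into constituent words, removes
#' generic stopwords ("protein", "factor", "family", "binding", ...) and
#' words that occur more than `max_global_frequency` times across the whole
#' collection, then picks the lowest-frequency surviving constituent (ties
#' broken by longest word, then lexicographically).  The keyword is what an
#' ambiguous alias is conjoined with in literature queries (e.g. "enolase"
#' for ENO2/NSE).
#'
#' @param records gene nomenclature data frame; the `full_name` field may
#'   hold several pipe-separated name variants (mouse/human/rat).
#' @param stopwords character vector of uninformative words.
#' @param max_global_frequency occurrence count above which a word is
#'   considered uninformative (default 20, strict).
#' @param ambiguity optional output of [flag_ambiguous_names()]; when
#'   supplied, a candidate keyword equal to one of the gene's own ambiguous
#'   aliases is skipped (it could not disambiguate anything).
#' @return data frame `gene_id`, `keyword` (`NA` when no constituent
#'   survives), `keyword_frequency`.
#' @export
informative_keywords <- function(records, stopwords = default_stopwords(),
                                 max_global_frequency = 20,
                                 ambiguity = NULL) {
  stopwords <- unique(tolower(stopwords))
  name_tokens <- lapply(split_pipes(records$full_name), function(v)
    unique(unlist(tokenize(paste(v, collapse = " ")))))
  freq <- table(unlist(name_tokens))
  ambig_by_gene <- list()
  if (!is.null(ambiguity)) {
    amb <- ambiguity[ambiguity$category != "none", , drop = FALSE]
    ambig_by_gene <- split(tolower(amb$alias), amb$gene_id)
  }
  pick <- function(toks, banned) {
    toks <- setdiff(toks, stopwords)
    toks <- toks[!grepl("^[0-9]+$", toks)]
    toks <- toks[freq[toks] <= max_global_frequency]
    toks <- setdiff(toks, banned)
    if (!length(toks)) return(c(NA_character_, NA_character_))
    f <- as.integer(freq[toks])
    ord <- order(f, -nchar(toks), toks)
    c(toks[ord[1]], f[ord[1]])
  }
  sel <- vapply(seq_along(name_tokens), function(i)
    pick(name_tokens[[i]],
         ambig_by_gene[[records$gene_id[i]]] %||% character(0)),
    character(2))
  n_null <- sum(is.na(sel[1, ]))
  if (n_null) message(n_null, " gene(s) have no informative keyword")
  data.frame(gene_id = records$gene_id, keyword = sel[1, ],
             keyword_frequency = as.integer(sel[2, ]),
             stringsAsFactors = FALSE)
}

#' Bundled word lists
#'
#' `default_stopwords()` returns the generic, uninformative name
#' constituents excluded from keyword selection; `default_english_words()`
#' returns the bundled common-English word list used by the ambiguity
#' detector and the simulator; `default_generic_domain_terms()` returns the
#' generic neuroscience terms always appended to the extracted
#' domain-keyword list (trailing `*` marks prefix wildcards).
#'
#' @return character vector.
#' @export
default_stopwords <- function() {
  readLines(system.file("extdata", "stopwords.txt", package = "ignoromics"))
}

#' @rdname default_stopwords
#' @export
default_english_words <- function() {
  readLines(system.file("extdata", "english_words.txt",
                        package = "ignoromics"))
}

#' @rdname default_stopwords
#' @export
default_generic_domain_terms <- function() {
  readLines(system.file("extdata", "generic_neuro_terms.txt",
                        package = "ignoromics"))
}
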