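#' Read / write article records as a MEDLINE-like flat file
#'
#' Articles are exchanged as keyed flat records separated by blank lines:
#' `PMID-` (id), `DP  -` (year), `JC  -` (journal class), `SP  -` (species,
#' repeated), `MH  -` (MeSH term, repeated), `TI  -` (title), `AB  -`
#' (abstract).  In memory, articles are a data frame with columns
#' `article_id`, `year`, `journal_class`, `species` (pipe-separated),
#' `mesh` (pipe-separated), `title`, `abstract`.
#'
#' @param articles article data frame.
#' @param path file path.
#' @return `read_medline()` returns the article data frame.
#' @export
write_medline <- function(articles, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(articles))) {
    a <- articles[i, ]
    lines <- c(paste0("PMID- ", a$article_id),
               paste0("DP  - ", a$year),
               paste0("JC  - ", a$journal_class),
               paste0("SP  - ", split_pipes(a$species)[[1]]),
               paste0("MH  - ", split_pipes(a$mesh)[[1]]),
               paste0("TI  - ", a$title),
               paste0("AB  - ", a$abstract),
               "")
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_medline
#' @export
read_medline <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  rec_start <- grepl("^PMID- ", lines)
  idx <- cumsum(rec_start)
  keep <- idx > 0 & nzchar(lines)
  recs <- split(lines[keep], idx[keep])
  field <- function(rec, tag) sub(paste0("^", tag, "- *"), "",
                                  rec[startsWith(rec, paste0(tag, "-"))])
  rows <- lapply(recs, function(rec) {
    data.frame(article_id = field(rec, "PMID"),
               year = as.integer(field(rec, "DP  ")),
               journal_class = field(rec, "JC  "),
               species = collapse_pipes(list(field(rec, "SP  "))),
               mesh = collapse_pipes(list(field(rec, "MH  "))),
               title = field(rec, "TI  "),
               abstract = field(rec, "AB  "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract domain-specific keywords from MeSH-tagged corpora
#'
#' Selects MeSH terms whose document frequency strictly exceeds
#' `min_domain_freq` in the domain corpus and is strictly below
#' `max_other_freq` in the contrast corpus, and appends the supplied generic
#' term list.  Document frequency is the fraction of articles carrying the
#' term at least once.
#'
#' @param domain_corpus,other_corpus article data frames (see
#'   [read_medline()]); both must be non-empty and MeSH-tagged.
#' @param min_domain_freq minimum domain document frequency (default 0.20).
#' @param max_other_freq maximum contrast document frequency (default 0.01).
#' @param generic_terms terms always included (may carry trailing `*`
#'   wildcards).
#' @return character vector of domain keywords, lower-cased, extracted
#'   terms first (by decreasing domain frequency) then generic terms.
#' @export
extract_domain_keywords <- function(domain_corpus, other_corpus,
                                    min_domain_freq = 0.20,
                                    max_other_freq = 0.01,
                                    generic_terms = character(0)) {
  if (!nrow(domain_corpus) || !nrow(other_corpus))
    stop("both corpora must be non-empty")
  doc_freq <- function(articles) {
    per_doc <- lapply(split_pipes(articles$mesh), function(m)
      unique(tolower(m)))
    tab <- table(unlist(per_doc))
    tab / nrow(articles)
  }
  fd <- doc_freq(domain_corpus)
  fo <- doc_freq(other_corpus)
  terms <- names(fd)[fd > min_domain_freq]
  other <- as.numeric(fo[terms])
  other[is.na(other)] <- 0
  terms <- terms[other < max_other_freq]
  terms <- terms[order(-as.numeric(fd[terms]), terms)]
  unique(c(terms, tolower(generic_terms)))
}

#' Flag noisy articles
#'
#' An article is noisy when it links to strictly more than `max_genes`
#' distinct genes (typical of genome-wide surveys that name hundreds of
#' genes with only cursory annotation); noisy articles are excluded from
#' literature counts.
#'
#' @param links data frame with columns `gene_id`, `article_id` (a
#'   gene2pubmed-like table; a `tax_id` column is ignored if present).
#' @param max_genes strict threshold (default 50).
#' @return character vector of noisy article ids.
#' @export
flag_noisy_articles <- function(links, max_genes = 50) {
  if (!nrow(links)) return(character(0))
  n_genes <- tapply(links$gene_id, links$article_id,
                    function(g) length(unique(g)))
  names(n_genes)[n_genes > max_genes]
}

#' Build a disambiguation-aware literature query
#'
#' Assembles the concatenated query used to count one gene's
#' domain-restricted literature.  The query is the conjunction of three
#' clauses: (1) the disjunction of the gene's searchable names, each
#' restricted to title/abstract (`[TIAB]`), with every ambiguous alias
#' conjoined with the gene's informative keyword (e.g.
#' `(NSE[TIAB] AND enolase[TIAB])`); (2) the disjunction of the domain
#' keywords; (3) the disjunction of the species names.  Ambiguous aliases
#' of a gene without a keyword are dropped (with a message); a gene left
#' with no usable name is an error.
#'
#' @param gene a list or one-row data frame with elements `gene_id`,
#'   `aliases` (character vector, or pipe-separated string), optional
#'   `ambiguous` (subset of aliases, or pipe-separated) and `keyword`.
#' @param domain_keywords character vector (trailing `*` = prefix
#'   wildcard).
#' @param species species clause (default mouse, human, rat).
#' @return an object of class `lit_query`; serialize with
#'   [format()][format.lit_query].
#' @export
build_query <- function(gene, domain_keywords,
                        species = c("Mus musculus", "Homo sapiens",
                                    "Rattus norvegicus")) {
  as_chr <- function(x) {
    if (is.null(x) || all(is.na(x))) return(character(0))
    if (length(x) == 1L && grepl("|", x, fixed = TRUE))
      x <- split_pipes(x)[[1]]
    x[!is.na(x) & nzchar(x)]
  }
  aliases <- unique(as_chr(gene$aliases))
  ambiguous <- intersect(unique(as_chr(gene$ambiguous)), aliases)
  keyword <- as_chr(gene$keyword)
  keyword <- if (length(keyword)) keyword[1] else NULL
  if (!length(aliases)) stop("gene has no usable names")
  if (length(ambiguous) && is.null(keyword)) {
    message("dropping ", length(ambiguous),
            " ambiguous alias(es) with no keyword for gene ",
            gene$gene_id %||% "?")
    aliases <- setdiff(aliases, ambiguous)
    ambiguous <- character(0)
    if (!length(aliases)) stop("gene has no usable names")
  }
  structure(list(gene_id = gene$gene_id %||% NA_character_,
                 plain_aliases = setdiff(aliases, ambiguous),
                 ambiguous_aliases = ambiguous,
                 keyword = keyword,
                 domain_keywords = unique(domain_keywords),
                 species = species),
            class = "lit_query")
}

quote_term <- function(x) {
  ifelse(grepl("[[:space:]]", x), paste0("\"", x, "\""), x)
}

#' Serialize a literature query to the PubMed dialect
#'
#' @param x a `lit_query`.
#' @param ... unused.
#' @return a single query string, byte-stable for a given query.
#' @export
format.lit_query <- function(x, ...) {
  alias_terms <- c(
    paste0(quote_term(x$plain_aliases), "[TIAB]"),
    if (length(x$ambiguous_aliases))
      paste0("(", quote_term(x$ambiguous_aliases), "[TIAB] AND ",
             quote_term(x$keyword), "[TIAB])"))
  paste0("(", paste(alias_terms, collapse = " OR "), ")",
         " AND (", paste(quote_term(x$domain_keywords), collapse = " OR "),
         ")",
         " AND (", paste(x$species, collapse = " OR "), ")")
}

#' @export
print.lit_query <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# --- local query evaluator -------------------------------------------------

# Match a term (token sequence; trailing '*' on the final token = prefix)
# anywhere in a token vector.
match_term_tokens <- function(term_tokens, tokens) {
  k <- length(term_tokens)
  if (k == 0L || length(tokens) < k) return(FALSE)
  last <- term_tokens[k]
  wild <- endsWith(last, "*")
  if (wild) last <- substr(last, 1L, nchar(last) - 1L)
  for (start in seq_len(length(tokens) - k + 1L)) {
    seg <- tokens[start:(start + k - 1L)]
    head_ok <- k == 1L || all(seg[-k] == term_tokens[-k])
    tail_ok <- if (wild) startsWith(seg[k], last) else seg[k] == last
    if (head_ok && tail_ok) return(TRUE)
  }
  FALSE
}

#' Count a gene's domain-restricted literature against a local corpus
#'
#' Evaluates a [build_query()] query against a local article corpus with
#' the following semantics: alias terms match case-insensitive whole tokens
#' (multiword aliases as consecutive token phrases) in title+abstract;
#' ambiguous aliases count only when the keyword also matches; domain
#' keywords match title+abstract tokens or MeSH entries, with trailing `*`
#' doing prefix matching; the species clause matches article species
#' metadata; noisy articles are removed when `exclude_noisy` is set.
#'
#' @param query a `lit_query`.
#' @param corpus article data frame (see [read_medline()]).
#' @param noisy character vector of noisy article ids (see
#'   [flag_noisy_articles()]).
#' @param exclude_noisy drop noisy articles (default `TRUE`).
#' @return list with `count` and `article_ids` of matching articles.
#' @export
count_literature <- function(query, corpus, noisy = character(0),
                             exclude_noisy = TRUE) {
  stopifnot(inherits(query, "lit_query"))
  if (!nrow(corpus)) return(list(count = 0L, article_ids = character(0)))
  idx <- index_corpus(corpus)
  hits <- eval_query_indexed(query, idx)
  ids <- corpus$article_id[hits]
  if (exclude_noisy) ids <- setdiff(ids, noisy)
  list(count = length(ids), article_ids = ids)
}

# Pre-tokenize a corpus once so many queries can be evaluated against it.
index_corpus <- function(corpus) {
  list(article_id = corpus$article_id,
       text_tokens = tokenize(paste(corpus$title, corpus$abstract)),
       mesh_tokens = lapply(split_pipes(corpus$mesh), function(m)
         unlist(tokenize(paste(m, collapse = " ")))),
       species = split_pipes(corpus$species))
}

eval_query_indexed <- function(query, idx) {
  n <- length(idx$article_id)
  term_tok <- function(t) tokenize(t)[[1]]
  plain <- lapply(query$plain_aliases, term_tok)
  ambig <- lapply(query$ambiguous_aliases, term_tok)
  kw <- if (is.null(query$keyword)) NULL else term_tok(query$keyword)
  dom <- lapply(query$domain_keywords, term_tok)
  sp <- tolower(query$species)
  vapply(seq_len(n), function(i) {
    tt <- idx$text_tokens[[i]]
    alias_ok <- any(vapply(plain, match_term_tokens, logical(1),
                           tokens = tt)) ||
      (length(ambig) > 0L && !is.null(kw) &&
         match_term_tokens(kw, tt) &&
         any(vapply(ambig, match_term_tokens, logical(1), tokens = tt)))
    if (!alias_ok) return(FALSE)
    mt <- idx$mesh_tokens[[i]]
    dom_ok <- any(vapply(dom, function(d)
      match_term_tokens(d, tt) || match_term_tokens(d, mt), logical(1)))
    if (!dom_ok) return(FALSE)
    any(tolower(idx$species[[i]]) %in% sp)
  }, logical(1))
}

#' Count literature for many genes at once
#'
#' Convenience wrapper that builds one query per gene record and evaluates
#' all of them against a shared corpus index.
#'
#' @param records gene nomenclature data frame (see [read_gene_info()]).
#' @param ambiguity output of [flag_ambiguous_names()].
#' @param keywords output of [informative_keywords()].
#' @param corpus article data frame.
#' @param domain_keywords character vector of domain keywords.
#' @inheritParams count_literature
#' @param species species clause.
#' @return data frame `gene_id`, `literature_count`, plus a list column
#'   `article_ids`.
#' @export
count_literature_all <- function(records, ambiguity, keywords, corpus,
                                 domain_keywords, noisy = character(0),
                                 exclude_noisy = TRUE,
                                 species = c("Mus musculus", "Homo sapiens",
                                             "Rattus norvegicus")) {
  idx <- index_corpus(corpus)
  amb <- ambiguity[ambiguity$category != "none", , drop = FALSE]
  amb_by_gene <- split(amb$alias, amb$gene_id)
  kw <- keywords$keyword
  names(kw) <- keywords$gene_id
  out <- lapply(seq_len(nrow(records)), function(i) {
    gid <- records$gene_id[i]
    q <- build_query(list(gene_id = gid,
                          aliases = gene_aliases(records[i, ]),
                          ambiguous = amb_by_gene[[gid]] %||% character(0),
                          keyword = kw[[gid]] %||% NA_character_),
                     domain_keywords, species)
    ids <- idx$article_id[eval_query_indexed(q, idx)]
    if (exclude_noisy) ids <- setdiff(ids, noisy)
    ids
  })
  data.frame(gene_id = records$gene_id,
             literature_count = lengths(out),
             article_ids = I(out),
             stringsAsFactors = FALSE)
}
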