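# Small in-code fixtures shared across test files.

# A hand-built panel: one target tissue, `n_other` identical non-target
# tissues, explicit linear values per probe.
toy_panel <- function(target_values, other_values, n_other = 10,
                      platform_id = "p1") {
  stopifnot(length(target_values) == nrow(as.matrix(other_values)) ||
              length(other_values) == length(target_values))
  if (is.vector(other_values))
    other_values <- matrix(rep(other_values, n_other),
                           ncol = n_other)
  m <- cbind(target = target_values, other_values)
  colnames(m) <- c("brain", paste0("tissue", seq_len(ncol(other_values))))
  rownames(m) <- sprintf("pr%02d", seq_len(nrow(m)))
  expression_panel(m, colnames(m), "brain", platform_id, scale = "linear")
}

# Minimal article data frame builder.
toy_articles <- function(title, abstract = "", year = 2000,
                         journal_class = "domain",
                         species = "Mus musculus",
                         mesh = "brain") {
  n <- max(length(title), length(abstract))
  data.frame(article_id = sprintf("A%03d", seq_len(n)),
             year = rep_len(year, n),
             journal_class = rep_len(journal_class, n),
             species = rep_len(species, n),
             mesh = rep_len(mesh, n),
             title = rep_len(title, n),
             abstract = rep_len(abstract, n),
             stringsAsFactors = FALSE)
}

# Independent naive query oracle: per-article regex scan, written without
# reusing the package's tokenizer or index.  Terms are matched as whole
# words (case-insensitive), multiword terms as literal phrases, trailing
# '*' as a word prefix.
naive_match_term <- function(term, text) {
  term <- tolower(term)
  text <- tolower(gsub("[^[:alnum:]]+", " ", text))
  wild <- grepl("\\*$", term)
  term <- trimws(gsub("[^[:alnum:]]+", " ", sub("\\*$", "", term)))
  pat <- if (wild) paste0("\\b", term, "[[:alnum:]]*\\b")
         else paste0("\\b", term, "\\b")
  grepl(pat, text)
}

naive_count <- function(aliases, ambiguous, keyword, domain_terms, species,
                        corpus, noisy = character(0),
                        exclude_noisy = TRUE) {
  hits <- vapply(seq_len(nrow(corpus)), function(i) {
    a <- corpus[i, ]
    text <- paste(a$title, a$abstract)
    plain <- setdiff(aliases, ambiguous)
    alias_ok <- any(vapply(plain, naive_match_term, logical(1),
                           text = text))
    if (!alias_ok && length(ambiguous) && !is.null(keyword))
      alias_ok <- naive_match_term(keyword, text) &&
        any(vapply(ambiguous, naive_match_term, logical(1), text = text))
    mesh_text <- gsub("|", " ", a$mesh, fixed = TRUE)
    dom_ok <- any(vapply(domain_terms, function(d)
      naive_match_term(d, text) || naive_match_term(d, mesh_text),
      logical(1)))
    sp_ok <- any(tolower(strsplit(a$species, "|", fixed = TRUE)[[1]]) %in%
                   tolower(species))
    alias_ok && dom_ok && sp_ok
  }, logical(1))
  ids <- corpus$article_id[hits]
  if (exclude_noisy) ids <- setdiff(ids, noisy)
  ids
}
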