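test_that("domain keyword extraction applies strict frequency bounds", {
  # constructed corpora with exact document frequencies
  mk <- function(n, term, n_with) {
    mesh <- c(rep(paste0(term, "|filler"), n_with),
              rep("filler", n - n_with))
    toy_articles(title = rep("t", n), mesh = mesh)
  }
  dom <- mk(100, "synapse", 30)          # 30% in domain
  oth <- mk(200, "synapse", 1)           # 0.5% elsewhere
  expect_true("synapse" %in% extract_domain_keywords(dom, oth))
  # 40% domain but 30% elsewhere fails the <1% bound
  oth2 <- mk(200, "synapse", 60)
  dom2 <- mk(100, "synapse", 40)
  expect_false("synapse" %in% extract_domain_keywords(dom2, oth2))
  # exactly at the 20% bound is excluded (strict)
  dom3 <- mk(100, "synapse", 20)
  expect_false("synapse" %in% extract_domain_keywords(dom3, oth))
  # generic terms are always appended
  expect_true("neuron" %in%
                extract_domain_keywords(dom2, oth2,
                                        generic_terms = "neuron"))
  expect_error(extract_domain_keywords(dom[0, ], oth), "non-empty")
})

test_that("noisy-article flagging uses a strict >50 genes rule", {
  links <- rbind(
    data.frame(gene_id = sprintf("g%03d", 1:60), article_id = "A1"),
    data.frame(gene_id = sprintf("g%03d", 1:50), article_id = "A2"),
    data.frame(gene_id = c("g001", "g001", "g002"), article_id = "A3"))
  expect_equal(flag_noisy_articles(links), "A1")
  expect_setequal(flag_noisy_articles(links, max_genes = 2),
                  c("A1", "A2"))
  # duplicated link rows do not inflate the distinct-gene count
  expect_setequal(flag_noisy_articles(links, max_genes = 1),
                  c("A1", "A2", "A3"))
})

test_that("query construction nests alias, domain and species clauses", {
  q <- build_query(list(gene_id = "syn1",
                        aliases = c("Syn1", "synapsin I")),
                   domain_keywords = c("synap*", "brain"))
  s <- format(q)
  expect_equal(s, paste0(
    '(Syn1[TIAB] OR "synapsin I"[TIAB])',
    ' AND (synap* OR brain)',
    ' AND (Mus musculus OR Homo sapiens OR Rattus norvegicus)'))
  # ambiguous alias is conjoined with the keyword
  q2 <- build_query(list(gene_id = "eno2", aliases = c("Eno2", "NSE"),
                         ambiguous = "NSE", keyword = "enolase"),
                    domain_keywords = "brain")
  expect_match(format(q2), "(NSE[TIAB] AND enolase[TIAB])", fixed = TRUE)
  expect_match(format(q2), "Eno2[TIAB]", fixed = TRUE)
  # serialization is byte-stable
  expect_identical(format(q2), format(q2))
  # a gene whose only alias is ambiguous and keyword-less errors
  expect_error(
    suppressMessages(build_query(list(gene_id = "x", aliases = "NSE",
                                      ambiguous = "NSE"),
                                 domain_keywords = "brain")),
    "no usable names")
})

test_that("local evaluator matches its documented semantics", {
  corpus <- toy_articles(
    title = c("Syn1 regulates synaptic vesicles",
              "A study of hippocampus development",
              "SYN1 mutations in epilepsy",
              "Unrelated cardiac work"),
    abstract = c("Vesicle pools in the hippocampus.",
                 "No gene is mentioned here.",
                 "We profile Syn1 in human cortex tissue.",
                 "The heart beats."),
    journal_class = "domain",
    species = c("Mus musculus", "Mus musculus", "Homo sapiens", "Mus musculus"),
    mesh = c("neurons", "brain", "neurons", "heart"))
  q <- build_query(list(gene_id = "syn1", aliases = "Syn1"),
                   domain_keywords = c("hippocamp*", "cortex"))
  res <- count_literature(q, corpus)
  # article 1: alias + hippocampus (abstract); article 3: alias + cortex
  expect_setequal(res$article_ids, c("A001", "A003"))
  expect_equal(res$count, 2)
  # noisy exclusion is monotone
  res2 <- count_literature(q, corpus, noisy = "A003")
  expect_equal(res2$count, 1)
  res3 <- count_literature(q, corpus, noisy = "A003",
                           exclude_noisy = FALSE)
  expect_equal(res3$count, 2)
  # empty corpus
  expect_equal(count_literature(q, corpus[0, ])$count, 0)
  # species clause filters on metadata
  q_mouse <- build_query(list(gene_id = "syn1", aliases = "Syn1"),
                         domain_keywords = c("hippocamp*", "cortex"),
                         species = "Homo sapiens")
  expect_equal(count_literature(q_mouse, corpus)$article_ids, "A003")
})

test_that("wildcards match prefixes but never shorter stems", {
  corpus <- toy_articles(
    title = c("hippocampal slices", "the hippocampus in vivo",
              "a hippo at the zoo"),
    mesh = "neurons")
  q <- build_query(list(gene_id = "g", aliases = c("hippocampal",
                                                   "hippocampus", "hippo")),
                   domain_keywords = "hippocamp*")
  idx <- ignoromics:::index_corpus(corpus)
  hits <- vapply(seq_len(3), function(i)
    ignoromics:::match_term_tokens(c("hippocamp*"),
                                   idx$text_tokens[[i]]), logical(1))
  expect_equal(hits, c(TRUE, TRUE, FALSE))
})

test_that("indexed evaluator equals a naive per-article scan", {
  nm <- simulate_nomenclature(sprintf("g%03d", 1:40),
                              ambiguous_fraction = 0.3, seed = 23)
  amb <- flag_ambiguous_names(nm$records, default_english_words(),
                              nm$acronym_senses)
  kw <- informative_keywords(nm$records, ambiguity = amb)
  co <- simulate_literature_corpus(
    nm$records$gene_id, 150, seed = 23, gene_records = nm$records,
    ambiguous_aliases = names(nm$truth$ambiguous_alias_map),
    offtarget_alias_rate = 0.2)
  dom <- default_generic_domain_terms()
  noisy <- flag_noisy_articles(co$links)
  res <- count_literature_all(nm$records, amb, kw, co$articles, dom, noisy)
  amb_by_gene <- split(amb$alias[amb$category != "none"],
                       amb$gene_id[amb$category != "none"])
  for (i in seq_len(nrow(nm$records))) {
    gid <- nm$records$gene_id[i]
    aliases <- c(nm$records$symbol[i],
                 ignoromics:::split_pipes(nm$records$synonyms[i])[[1]])
    keyword <- kw$keyword[kw$gene_id == gid]
    ambig <- intersect(amb_by_gene[[gid]], aliases)
    if (length(ambig) && is.na(keyword)) {
      aliases <- setdiff(aliases, ambig); ambig <- character(0)
    }
    oracle_ids <- naive_count(aliases, ambig,
                              if (is.na(keyword)) NULL else keyword,
                              dom,
                              c("Mus musculus", "Homo sapiens",
                                "Rattus norvegicus"),
                              co$articles, noisy)
    expect_setequal(res$article_ids[[i]], oracle_ids)
  }
})

test_that("adding an article never decreases a count", {
  corpus <- toy_articles(
    title = c("Abcd1 in brain", "Abcd1 in cortex circuits"),
    mesh = "neurons")
  q <- build_query(list(gene_id = "a", aliases = "Abcd1"),
                   domain_keywords = c("brain", "cortex"))
  c1 <- count_literature(q, corpus[1, , drop = FALSE])$count
  c2 <- count_literature(q, corpus)$count
  expect_gte(c2, c1)
})

test_that("keyword conjunction removes planted off-target matches", {
  nm <- simulate_nomenclature(sprintf("g%03d", 1:60),
                              ambiguous_fraction = 0.3, seed = 31)
  truth <- nm$truth$ambiguous_alias_map
  english_alias <- names(truth)[truth == "english_word"][1]
  gid <- nm$truth$ambiguous_gene_ids[match(english_alias, names(truth))]
  rec <- nm$records[nm$records$gene_id == gid, ]
  co <- simulate_literature_corpus(
    nm$records$gene_id, 400, seed = 31, gene_records = nm$records,
    ambiguous_aliases = english_alias, offtarget_alias_rate = 0.3)
  dom <- default_generic_domain_terms()
  kw <- informative_keywords(nm$records)
  keyword <- kw$keyword[kw$gene_id == gid]
  aliases <- c(rec$symbol, english_alias)
  q_bare <- build_query(list(gene_id = gid, aliases = aliases),
                        domain_keywords = dom)
  q_dis <- build_query(list(gene_id = gid, aliases = aliases,
                            ambiguous = english_alias, keyword = keyword),
                       domain_keywords = dom)
  true_ids <- co$links$article_id[co$links$gene_id == gid]
  fp <- function(q) {
    got <- count_literature(q, co$articles)$article_ids
    length(setdiff(got, true_ids))
  }
  expect_gt(fp(q_bare), 0)
  expect_lt(fp(q_dis), fp(q_bare))
  expect_equal(fp(q_dis), 0)
})

test_that("MEDLINE flat file round-trips", {
  co <- simulate_literature_corpus(sprintf("g%02d", 1:20), 30, seed = 2)
  f <- withr::local_tempfile(fileext = ".txt")
  write_medline(co$articles, f)
  back <- read_medline(f)
  expect_equal(back, co$articles)
})
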