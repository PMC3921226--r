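#' Simulate a multi-tissue expression panel with planted selective genes
#'
#' Emulates a multi-organ expression atlas: every gene gets a baseline log2
#' abundance shared across tissues, `n_selective` genes are planted with a
#' `fold`-times elevated target-tissue signal, Gaussian noise is added on
#' the log2 scale, and intensities are returned on the linear scale, one
#' panel per platform (platforms differ only in noise realization and probe
#' ids).  Each platform also gets a probe annotation table (one probe per
#' gene, all quality flags clear) and a shared gene position map.
#'
#' @param n_genes number of genes.
#' @param tissue_labels distinct tissue names (>= 3).
#' @param target_tissue the tissue selective genes are planted in.
#' @param n_selective number of planted selective genes.
#' @param fold planted linear fold change (> 1 plants signal; 1 plants
#'   none).
#' @param noise_sd per-cell noise sd in log2 units.
#' @param platforms number of platforms to emit.
#' @param seed integer RNG seed; all randomness flows from it via named
#'   substreams.
#' @return list with `panels` (list of [expression_panel()], linear scale),
#'   `annotations` (list of probe annotation data frames),
#'   `gene_positions` (`gene_id`, `chr`, `mb`), and `truth` (list with
#'   `selective_gene_ids`, `planted_fold`, `seed`).
#' @export
simulate_expression_panel <- function(n_genes, tissue_labels,
                                      target_tissue = tissue_labels[1],
                                      n_selective, fold = 16,
                                      noise_sd = 0.25, platforms = 2,
                                      seed = 1) {
  if (n_genes <= 0 || platforms <= 0) stop("non-positive dimensions")
  if (n_selective > n_genes) stop("n_selective exceeds n_genes")
  if (anyDuplicated(tissue_labels)) stop("duplicate tissue labels")
  if (!target_tissue %in% tissue_labels) stop("target tissue absent")
  if (length(tissue_labels) < 3L) stop("need >= 3 tissues")
  if (fold < 1) stop("fold must be >= 1")
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  selective <- gene_ids[seq_len(n_selective)]
  base_mu <- with_substream(seed, "expression/baseline",
                            stats::runif(n_genes, 6, 11))
  gene_positions <- with_substream(seed, "expression/positions", {
    data.frame(gene_id = gene_ids,
               chr = sample(as.character(1:19), n_genes, replace = TRUE),
               mb = round(stats::runif(n_genes, 3, 150), 3),
               stringsAsFactors = FALSE)
  })
  panels <- vector("list", platforms)
  annotations <- vector("list", platforms)
  for (p in seq_len(platforms)) {
    pid <- sprintf("platform%d", p)
    m <- matrix(base_mu, n_genes, length(tissue_labels))
    colnames(m) <- tissue_labels
    m[gene_ids %in% selective, target_tissue] <-
      m[gene_ids %in% selective, target_tissue] + log2(fold)
    if (noise_sd > 0)
      m <- m + with_substream(seed, paste0("expression/noise/", pid),
                              matrix(stats::rnorm(length(m), 0, noise_sd),
                                     nrow(m)))
    probe_ids <- sprintf("%s_probe%05d", pid, seq_len(n_genes))
    rownames(m) <- probe_ids
    panels[[p]] <- expression_panel(2^m, tissue_labels, target_tissue,
                                    pid, scale = "linear")
    annotations[[p]] <- data.frame(
      probe_id = probe_ids, gene_id = gene_ids,
      chr = gene_positions$chr, start = gene_positions$mb,
      end = gene_positions$mb + 0.05,
      multi_mapping = FALSE, non_coding = FALSE, snp_overlap = FALSE,
      annotation_override = NA_character_, stringsAsFactors = FALSE)
  }
  list(panels = panels, annotations = annotations,
       gene_positions = gene_positions,
       truth = list(selective_gene_ids = selective, planted_fold = fold,
                    seed = seed))
}

# Small MeSH-like vocabularies for the two journal classes.
.domain_mesh <- c("neurons", "brain", "synaptic transmission", "hippocampus",
                  "axons", "dendrites", "neuroglia", "cerebral cortex",
                  "neurotransmitter agents", "action potentials",
                  "cerebellum", "memory", "seizures", "myelin sheath")
.other_mesh <- c("liver", "kidney", "metabolism", "cell division",
                 "immunity", "inflammation", "neoplasms", "apoptosis",
                 "signal transduction", "lung", "heart", "muscle",
                 "bone development", "wound healing")
.shared_mesh <- c("mice", "gene expression", "mutation", "phenotype",
                  "protein binding")

#' Simulate a power-law literature corpus
#'
#' Emulates a gene2pubmed-like link table plus article metadata.  Genes are
#' assigned Zipf weights over their rank in `gene_ids` (weight of rank r is
#' `r^-zipf_exponent`, truncated at `length(gene_ids)`) and each ordinary
#' article is linked to one gene drawn from those weights, so per-gene
#' article counts follow the rank power law.  Articles carry a uniform
#' year, a journal class (`domain` with probability
#' `neuro_journal_fraction`), class-specific MeSH terms, species metadata,
#' and template title/abstract text embedding the linked gene's alias.  A
#' `noisy_article_rate` share of articles are genome-wide-survey-like and
#' link to more than 50 genes.  Optionally, an `offtarget_alias_rate` share
#' of non-domain articles mention a planted ambiguous alias as plain text
#' without linking the gene, providing ground truth for disambiguation
#' tests.
#'
#' @param gene_ids gene ids, ordered by literature rank (first = most
#'   published).
#' @param n_articles number of articles (>= 1).
#' @param zipf_exponent power-law exponent (> 0, default 1).
#' @param neuro_journal_fraction probability an article is domain-class.
#' @param year_range integer `c(first, last)` publication years.
#' @param noisy_article_rate share of articles linking to > 50 genes.
#' @param seed integer RNG seed.
#' @param gene_records optional nomenclature table (see
#'   [simulate_nomenclature()]); when given, article text embeds sampled
#'   aliases instead of raw gene ids.
#' @param ambiguous_aliases optional character vector of ambiguous aliases
#'   used for planted off-target mentions.
#' @param offtarget_alias_rate share of articles with a planted off-target
#'   ambiguous-alias mention (default 0).
#' @return list with `articles` (data frame; see [read_medline()]),
#'   `links` (`gene_id`, `article_id`), and `truth` (`zipf_exponent`,
#'   `noisy_article_ids`, `offtarget_article_ids`, `seed`).
#' @export
simulate_literature_corpus <- function(gene_ids, n_articles,
                                       zipf_exponent = 1,
                                       neuro_journal_fraction = 0.5,
                                       year_range = c(1991, 2012),
                                       noisy_article_rate = 0.02,
                                       seed = 1, gene_records = NULL,
                                       ambiguous_aliases = NULL,
                                       offtarget_alias_rate = 0) {
  if (!length(gene_ids)) stop("empty gene list")
  if (n_articles < 1) stop("need at least one article")
  if (year_range[1] > year_range[2]) stop("invalid year range")
  stopifnot(zipf_exponent > 0, noisy_article_rate >= 0,
            noisy_article_rate <= 1)
  n_genes <- length(gene_ids)
  w <- seq_len(n_genes)^(-zipf_exponent)
  alias_of <- function(gid) {
    if (is.null(gene_records)) return(gid)
    rec <- gene_records[gene_records$gene_id == gid, ]
    if (!nrow(rec)) return(gid)
    al <- gene_aliases(rec[1, ])
    al[1]
  }
  species_pool <- c("Mus musculus", "Homo sapiens", "Rattus norvegicus")
  with_substream(seed, "literature/corpus", {
    n_noisy <- round(noisy_article_rate * n_articles)
    is_noisy <- rep(FALSE, n_articles)
    if (n_noisy > 0) is_noisy[sample.int(n_articles, n_noisy)] <- TRUE
    primary <- sample(gene_ids, n_articles, replace = TRUE, prob = w)
    years <- sample(seq(year_range[1], year_range[2]), n_articles,
                    replace = TRUE)
    is_domain <- stats::runif(n_articles) < neuro_journal_fraction
    species <- sample(species_pool, n_articles, replace = TRUE)
    ids <- sprintf("PM%07d", seq_len(n_articles))
    n_offtarget <- round(offtarget_alias_rate * n_articles)
    offtarget_idx <- if (n_offtarget > 0 && length(ambiguous_aliases))
      sample.int(n_articles, n_offtarget) else integer(0)

    mesh <- character(n_articles)
    title <- character(n_articles)
    abstract <- character(n_articles)
    link_rows <- vector("list", n_articles)
    for (i in seq_len(n_articles)) {
      g <- primary[i]
      al <- alias_of(g)
      if (is_domain[i]) {
        mh <- c(sample(.domain_mesh, 3), sample(.shared_mesh, 1))
        title[i] <- paste0("Expression of ", al,
                           " in the developing brain")
        abstract[i] <- paste0("We characterize ", al,
                              " in neurons of the hippocampus and ",
                              "cerebral cortex.")
      } else {
        mh <- c(sample(.other_mesh, 3), sample(.shared_mesh, 1))
        title[i] <- paste0("A role for ", al, " in tissue homeostasis")
        abstract[i] <- paste0("The gene ", al,
                              " modulates metabolism and cell division ",
                              "in peripheral organs.")
      }
      linked <- g
      if (is_noisy[i]) {
        k <- min(n_genes, sample(51:80, 1))
        extra <- sample(setdiff(gene_ids, g), k - 1L)
        linked <- c(g, extra)
        title[i] <- "A genome-wide survey of transcript abundance"
        abstract[i] <- paste0("Large-scale profiling including ", al,
                              " and many other loci.")
      }
      if (i %in% offtarget_idx) {
        amb <- sample(ambiguous_aliases, 1)
        abstract[i] <- paste0(abstract[i], " The sample remained ", amb,
                              " throughout the procedure.")
      }
      mesh[i] <- paste(unique(mh), collapse = "|")
      link_rows[[i]] <- data.frame(gene_id = linked, article_id = ids[i],
                                   stringsAsFactors = FALSE)
    }
    articles <- data.frame(article_id = ids, year = years,
                           journal_class = ifelse(is_domain, "domain",
                                                  "non_domain"),
                           species = species, mesh = mesh, title = title,
                           abstract = abstract, stringsAsFactors = FALSE)
    links <- do.call(rbind, link_rows)
    list(articles = articles, links = links,
         truth = list(zipf_exponent = zipf_exponent,
                      noisy_article_ids = ids[is_noisy],
                      offtarget_article_ids = ids[offtarget_idx],
                      seed = seed))
  })
}

#' Simulate a gene nomenclature table with planted ambiguous aliases
#'
#' Every gene receives a synthetic official symbol, a compound full name
#' built from word-list constituents plus one rare informative word, and
#' 0-3 harmless aliases.  An `ambiguous_fraction` share of genes
#' additionally receive one planted ambiguous alias whose category cycles
#' through `english_word` (an upper-cased common word, e.g. "CALM"),
#' `short` (<= 3 characters), and `acronym_multisense` (listed with > 1
#' sense in the emitted acronym table).
#'
#' @param gene_ids gene ids.
#' @param english_words common-English word list (default: bundled list).
#' @param ambiguous_fraction share of genes with a planted ambiguous alias.
#' @param seed integer RNG seed.
#' @return list with `records` (gene_info-dialect data frame: `gene_id`,
#'   `symbol`, `synonyms`, `full_name`, `species`), `acronym_senses`
#'   (`alias`, `n_senses`), and `truth` (`ambiguous_alias_map`: alias ->
#'   category, `seed`).
#' @export
simulate_nomenclature <- function(gene_ids,
                                  english_words = default_english_words(),
                                  ambiguous_fraction = 0.2, seed = 1) {
  if (!length(english_words)) stop("word list must be non-empty")
  if (ambiguous_fraction < 0 || ambiguous_fraction > 1)
    stop("ambiguous_fraction outside [0, 1]")
  english_words <- tolower(english_words)
  n <- length(gene_ids)
  with_substream(seed, "nomenclature", {
    long_words <- english_words[nchar(english_words) >= 4]
    symbols <- sprintf("Zq%04d%s", seq_len(n),
                       sample(letters, n, replace = TRUE))
    # informative constituents: decorated words absent from the corpus of
    # common words, each reused rarely
    rare_pool <- paste0(sample(long_words, min(3L * n, length(long_words)),
                               replace = 3L * n > length(long_words)),
                        "in")
    common_pool <- sample(long_words, 12)
    full_names <- vapply(seq_len(n), function(i)
      paste(sample(rare_pool, 1), sample(common_pool, 1),
            "protein", sample(1:9, 1)), character(1))
    n_amb <- round(ambiguous_fraction * n)
    amb_idx <- if (n_amb > 0) sample.int(n, n_amb) else integer(0)
    categories <- rep(c("english_word", "short", "acronym_multisense"),
                      length.out = n_amb)
    amb_alias <- character(n_amb)
    used <- character(0)
    consonants <- setdiff(LETTERS, c("A", "E", "I", "O", "U"))
    for (j in seq_len(n_amb)) {
      repeat {
        a <- switch(categories[j],
          english_word = toupper(sample(long_words, 1)),
          short = paste0(sample(LETTERS, 1), sample(0:9, 1)),
          acronym_multisense = paste0(
            paste(sample(consonants, 3, replace = TRUE), collapse = ""),
            sample(0:9, 1), sample(consonants, 1)))
        if (!a %in% used) break
      }
      used <- c(used, a)
      amb_alias[j] <- a
    }
    synonyms <- vector("list", n)
    for (i in seq_len(n)) {
      n_extra <- sample(0:3, 1)
      extras <- if (n_extra > 0)
        paste0(toupper(substr(symbols[i], 3, 6)),
               sample(consonants, n_extra), seq_len(n_extra)) else character(0)
      synonyms[[i]] <- extras
    }
    for (j in seq_along(amb_idx))
      synonyms[[amb_idx[j]]] <- c(synonyms[[amb_idx[j]]], amb_alias[j])
    records <- data.frame(gene_id = gene_ids, symbol = symbols,
                          synonyms = collapse_pipes(synonyms),
                          full_name = full_names,
                          species = "Mus musculus",
                          stringsAsFactors = FALSE)
    acr <- amb_alias[categories == "acronym_multisense"]
    decoys <- paste0(replicate(5, paste(sample(consonants, 4), collapse = "")),
                     "X")
    acronym_senses <- data.frame(
      alias = c(acr, decoys),
      n_senses = c(sample(2:4, length(acr), replace = TRUE),
                   rep(1L, length(decoys))),
      stringsAsFactors = FALSE)
    amb_map <- categories
    names(amb_map) <- amb_alias
    list(records = records, acronym_senses = acronym_senses,
         truth = list(ambiguous_alias_map = amb_map,
                      ambiguous_gene_ids = gene_ids[amb_idx], seed = seed))
  })
}

#' Simulate a recombinant-inbred-like strain panel
#'
#' Generates biallelic genotypes (`B`/`D`) with recombination-block
#' structure (a per-chromosome Markov chain with a fixed switch probability
#' between adjacent markers), expression traits with additive allele
#' effects at planted cis markers, and phenotypes with planted QTL effects.
#' An effect is the additive allele effect `a`: trait values are
#' `baseline + a * code + N(0, noise_sd)` with codes B = -1 and D = +1, so
#' with the default `noise_sd = 1` effects are in within-strain SD units
#' and the planted B-vs-D line difference is `2a`.
#'
#' @param n_strains number of strains (>= 10).
#' @param n_markers number of markers (default map: chromosomes of 20
#'   markers spaced 1 Mb apart, starting at 3 Mb).
#' @param chromosome_map optional data frame `marker`, `chr`, `mb` (sorted
#'   within chromosome).
#' @param planted_eqtl data frame `gene_id`, `marker`, `effect` (may be
#'   empty).
#' @param planted_pheno_qtl data frame `trait`, `marker`, `effect` (may be
#'   empty).
#' @param n_null_genes extra expression traits with no planted effect.
#' @param n_null_phenotypes extra phenotypes with no planted effect.
#' @param noise_sd residual sd of traits (default 1).
#' @param switch_prob recombination probability between adjacent markers
#'   (default 0.3).
#' @param expr_baseline mean expression of simulated traits (default 9
#'   standardized units, comfortably above the cis-filter floor).
#' @param seed integer RNG seed.
#' @return list with `panel` (a [strain_panel()]) and `truth`
#'   (`planted_eqtl`, `planted_pheno_qtl`, `seed`).  Planted-eQTL genes are
#'   positioned at their marker and annotated with high-impact variants;
#'   null genes at random markers with impact `none`.
#' @export
simulate_strain_panel <- function(n_strains = 30, n_markers = 60,
                                  chromosome_map = NULL,
                                  planted_eqtl = NULL,
                                  planted_pheno_qtl = NULL,
                                  n_null_genes = 0, n_null_phenotypes = 0,
                                  noise_sd = 1, switch_prob = 0.3,
                                  expr_baseline = 9, seed = 1) {
  if (n_strains < 10) stop("need at least 10 strains")
  if (is.null(chromosome_map)) {
    per_chr <- 20L
    n_chr <- ceiling(n_markers / per_chr)
    chr <- rep(seq_len(n_chr), each = per_chr)[seq_len(n_markers)]
    within <- stats::ave(seq_len(n_markers), chr, FUN = seq_along)
    chromosome_map <- data.frame(
      marker = sprintf("m%03d", seq_len(n_markers)),
      chr = as.character(chr), mb = 3 + (within - 1) * 1,
      stringsAsFactors = FALSE)
  }
  for (ch in unique(chromosome_map$chr))
    if (is.unsorted(chromosome_map$mb[chromosome_map$chr == ch]))
      stop("marker positions unsorted on chr ", ch)
  planted_eqtl <- planted_eqtl %||%
    data.frame(gene_id = character(0), marker = character(0),
               effect = numeric(0))
  planted_pheno_qtl <- planted_pheno_qtl %||%
    data.frame(trait = character(0), marker = character(0),
               effect = numeric(0))
  bad <- setdiff(c(planted_eqtl$marker, planted_pheno_qtl$marker),
                 chromosome_map$marker)
  if (length(bad)) stop("effect on nonexistent marker: ",
                        paste(bad, collapse = ", "))
  n_markers <- nrow(chromosome_map)
  strains <- sprintf("BXD%02d", seq_len(n_strains))

  geno_code <- with_substream(seed, "strains/genotypes", {
    g <- matrix(NA_real_, n_markers, n_strains)
    for (s in seq_len(n_strains)) {
      for (ch in unique(chromosome_map$chr)) {
        idx <- which(chromosome_map$chr == ch)
        g[idx[1], s] <- sample(c(-1, 1), 1)
        for (k in idx[-1])
          g[k, s] <- if (stats::runif(1) < switch_prob) -g[k - 1, s]
                     else g[k - 1, s]
      }
    }
    g
  })
  geno <- matrix(ifelse(geno_code > 0, "D", "B"), n_markers, n_strains,
                 dimnames = list(chromosome_map$marker, strains))

  make_traits <- function(spec, id_col, stream, n_null, null_prefix) {
    ids <- c(spec[[id_col]],
             if (n_null > 0) sprintf("%s%03d", null_prefix, seq_len(n_null)))
    vals <- with_substream(seed, stream, {
      m <- matrix(stats::rnorm(length(ids) * n_strains, 0, noise_sd),
                  length(ids), n_strains)
      for (j in seq_len(nrow(spec))) {
        code <- geno_code[match(spec$marker[j], chromosome_map$marker), ]
        m[j, ] <- m[j, ] + spec$effect[j] * code
      }
      m + expr_baseline
    })
    rownames(vals) <- ids
    colnames(vals) <- strains
    vals
  }
  expr <- make_traits(planted_eqtl, "gene_id", "strains/expression",
                      n_null_genes, "nullgene")
  pheno <- make_traits(planted_pheno_qtl, "trait", "strains/phenotypes",
                       n_null_phenotypes, "nulltrait")

  pos_of_marker <- function(m)
    chromosome_map[match(m, chromosome_map$marker), c("chr", "mb")]
  gene_ids <- rownames(expr)
  null_marker_idx <- with_substream(seed, "strains/gene_positions",
    sample.int(n_markers, max(0L, length(gene_ids) - nrow(planted_eqtl)),
               replace = TRUE))
  gene_marker <- c(planted_eqtl$marker,
                   chromosome_map$marker[null_marker_idx])
  gp <- pos_of_marker(gene_marker)
  gene_positions <- data.frame(gene_id = gene_ids, chr = gp$chr, mb = gp$mb,
                               stringsAsFactors = FALSE)
  variant_annotations <- data.frame(
    gene_id = gene_ids,
    impact = c(rep("high", nrow(planted_eqtl)),
               rep("none", length(gene_ids) - nrow(planted_eqtl))),
    stringsAsFactors = FALSE)
  panel <- strain_panel(chromosome_map, geno, expr, pheno, gene_positions,
                        variant_annotations)
  list(panel = panel,
       truth = list(planted_eqtl = planted_eqtl,
                    planted_pheno_qtl = planted_pheno_qtl, seed = seed))
}

#' Simulate homolog / paralog / domain / discovery-year tables
#'
#' Emulates the per-gene comparative annotation tables: ortholog counts
#' bounded by the 21 species available in HomoloGene-like resources,
#' paralog and protein-domain counts, and a discovery year.  When a
#' literature-count vector and a nonzero `correlation` are supplied, counts
#' are drawn from a Gaussian copula with the stated correlation against
#' `log10(L + 1)` (discovery year gets the opposite sign: more literature,
#' earlier discovery).
#'
#' @param gene_ids gene ids (non-empty).
#' @param seed integer RNG seed.
#' @param lit_counts optional named literature-count vector.
#' @param correlation latent correlation in [-1, 1] between counts and
#'   log-literature (default 0).
#' @return data frame `gene_id`, `ortholog_count` (0-21), `paralog_count`,
#'   `domain_count`, `discovery_year`.
#' @export
simulate_annotation_tables <- function(gene_ids, seed = 1,
                                       lit_counts = NULL, correlation = 0) {
  if (!length(gene_ids)) stop("empty gene list")
  stopifnot(abs(correlation) <= 1)
  n <- length(gene_ids)
  zl <- if (is.null(lit_counts)) rep(0, n) else {
    l <- log10(lit_counts[gene_ids] + 1)
    as.numeric(scale(l))
  }
  zl[!is.finite(zl)] <- 0
  with_substream(seed, "annotation_tables", {
    latent <- function(rho) rho * zl + sqrt(1 - rho^2) * stats::rnorm(n)
    clampround <- function(x, lo, hi) pmin(hi, pmax(lo, round(x)))
    data.frame(
      gene_id = gene_ids,
      ortholog_count = clampround(9 + 4 * latent(correlation), 0, 21),
      paralog_count = clampround(2.5 + 2 * latent(correlation), 0, 40),
      domain_count = clampround(3 + 2 * latent(correlation), 0, 30),
      discovery_year = clampround(1995 + 7 * latent(-correlation),
                                  1980, 2012),
      stringsAsFactors = FALSE)
  })
}
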