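#' Pipeline configuration
#'
#' Bundles every tunable threshold of the ignorome pipeline with its
#' default, plus the simulation sizes used when the pipeline generates its
#' own inputs.  Round-trips losslessly through YAML/JSON (see
#' [write_config()] / [read_config()]).
#'
#' @param seed master RNG seed.
#' @param fold_threshold ISE linear fold threshold (default 8).
#' @param max_exempt tissues exempt from the per-tissue fold rule
#'   (default 5).
#' @param floor background clamp in standardized units (default 6).
#' @param short_cutoff maximum "short alias" length (default 3).
#' @param keyword_max_frequency keyword global-frequency cutoff
#'   (default 20).
#' @param mesh_min_domain_freq,mesh_max_other_freq MeSH document-frequency
#'   bounds (defaults 0.20 / 0.01).
#' @param noisy_max_genes noisy-article gene threshold (default 50).
#' @param core_max_articles core-ignorome literature cutoff (default 1).
#' @param r_thresholds connectivity |r| thresholds.
#' @param expr_floor_correlation expression floor for coexpression
#'   (default 8).
#' @param expr_floor_cis expression floor for cis-eQTL calls (default 7).
#' @param lrs_min_cis,lrs_min_phenome LRS thresholds (defaults 12 / 10).
#' @param window_mb cis / phenome / neighbour window in Mb (default 5).
#' @param fdr enrichment FDR level (default 0.05).
#' @param top_n covariates per enrichment sample (default 100).
#' @param timeseries_window trailing window in years (default 5).
#' @param sim simulation sizes: a list with `n_genes`, `n_selective`,
#'   `fold`, `noise_sd`, `platforms`, `tissues`, `n_articles`,
#'   `zipf_exponent`, `neuro_journal_fraction`, `year_range`,
#'   `noisy_article_rate`, `ambiguous_fraction`, `n_strains`, `n_markers`,
#'   `eqtl_effect`, `pheno_effect`.
#' @return a `pipeline_config` list.
#' @export
ignorome_config <- function(seed = 1,
                            fold_threshold = 8, max_exempt = 5, floor = 6,
                            short_cutoff = 3, keyword_max_frequency = 20,
                            mesh_min_domain_freq = 0.20,
                            mesh_max_other_freq = 0.01,
                            noisy_max_genes = 50, core_max_articles = 1,
                            r_thresholds = c(0.75, 0.80, 0.85, 0.90, 0.95),
                            expr_floor_correlation = 8, expr_floor_cis = 7,
                            lrs_min_cis = 12, lrs_min_phenome = 10,
                            window_mb = 5, fdr = 0.05, top_n = 100,
                            timeseries_window = 5,
                            sim = list()) {
  sim_defaults <- list(n_genes = 200, n_selective = 12, fold = 16,
                       noise_sd = 0.25, platforms = 2,
                       tissues = c("brain", "liver", "kidney", "heart",
                                   "lung", "muscle", "spleen", "testis",
                                   "retina", "thymus", "skin", "bone"),
                       n_articles = 3000, zipf_exponent = 1,
                       neuro_journal_fraction = 0.5,
                       year_range = c(1991, 2012),
                       noisy_article_rate = 0.02,
                       ambiguous_fraction = 0.2,
                       n_strains = 30, n_markers = 60,
                       eqtl_effect = 1.5, pheno_effect = 1.5)
  sim <- utils::modifyList(sim_defaults, sim)
  structure(list(seed = seed, fold_threshold = fold_threshold,
                 max_exempt = max_exempt, floor = floor,
                 short_cutoff = short_cutoff,
                 keyword_max_frequency = keyword_max_frequency,
                 mesh_min_domain_freq = mesh_min_domain_freq,
                 mesh_max_other_freq = mesh_max_other_freq,
                 noisy_max_genes = noisy_max_genes,
                 core_max_articles = core_max_articles,
                 r_thresholds = r_thresholds,
                 expr_floor_correlation = expr_floor_correlation,
                 expr_floor_cis = expr_floor_cis,
                 lrs_min_cis = lrs_min_cis,
                 lrs_min_phenome = lrs_min_phenome,
                 window_mb = window_mb, fdr = fdr, top_n = top_n,
                 timeseries_window = timeseries_window, sim = sim),
            class = "pipeline_config")
}

#' Serialize / deserialize a pipeline configuration
#'
#' @param config a [ignorome_config()] object.
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return `read_config()` returns a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                        simplifyVector = TRUE)
       else yaml::read_yaml(path)
  sim <- x$sim
  if (!is.null(sim$year_range)) sim$year_range <- as.numeric(sim$year_range)
  x$sim <- NULL
  x$r_thresholds <- as.numeric(x$r_thresholds)
  do.call(ignorome_config, c(x, list(sim = sim)))
}

#' Run the full ignorome pipeline on simulated inputs
#'
#' Executes every stage end to end: simulate inputs, standardize and screen
#' expression (ISE), flag ambiguous names and derive keywords, count
#' domain-restricted literature with disambiguation-aware queries, compute
#' ignorome scores and the core ignorome, build the shrinkage time series,
#' run the comparative analyses (literature-vs-structure correlations, GO
#' enrichment of top covariates of the top core gene), and perform reverse
#' complex trait analysis on a simulated strain panel.
#'
#' @param config a [ignorome_config()].
#' @param output_dir optional directory; when given, every stage output is
#'   written as TSV (plus the config and manifest as YAML/JSON).
#' @return invisibly, a list with per-stage outputs and a `manifest`
#'   recording row counts in/out per stage and all effective parameters.
#' @export
run_ignorome_pipeline <- function(config = ignorome_config(),
                                  output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sm <- config$sim
  manifest <- list(seed = config$seed,
                   parameters = unclass(config),
                   counts = list())
  note <- function(stage, ...) {
    manifest$counts[[stage]] <<- list(...)
    manifest
  }

  # --- simulate ------------------------------------------------------------
  ex <- simulate_expression_panel(sm$n_genes, sm$tissues,
                                  target_tissue = sm$tissues[1],
                                  n_selective = sm$n_selective,
                                  fold = sm$fold, noise_sd = sm$noise_sd,
                                  platforms = sm$platforms,
                                  seed = config$seed)
  nom <- simulate_nomenclature(sprintf("gene%05d", seq_len(sm$n_genes)),
                               ambiguous_fraction = sm$ambiguous_fraction,
                               seed = config$seed)
  # literature rank is independent of expression selectivity: permute the
  # gene order before assigning Zipf ranks
  rank_order <- with_substream(config$seed, "pipeline/lit_ranks",
                               sample(nom$records$gene_id))
  corpus <- simulate_literature_corpus(
    rank_order, sm$n_articles, sm$zipf_exponent,
    sm$neuro_journal_fraction, sm$year_range, sm$noisy_article_rate,
    seed = config$seed, gene_records = nom$records)
  note("simulate", genes = sm$n_genes, articles = nrow(corpus$articles),
       link_rows = nrow(corpus$links))

  # --- ise -----------------------------------------------------------------
  per_platform <- lapply(seq_along(ex$panels), function(p) {
    std <- standardize_panel(ex$panels[[p]])
    scr <- selectivity_screen(std, config$fold_threshold,
                              config$max_exempt, config$floor)
    gl <- filter_and_deduplicate(scr, ex$annotations[[p]])
    gl[gl$passed, , drop = FALSE]
  })
  ise <- merge_platforms(per_platform)
  note("ise", probes = nrow(ex$panels[[1]]$values) * length(ex$panels),
       ise_genes = nrow(ise))

  # --- names ---------------------------------------------------------------
  ambiguity <- flag_ambiguous_names(nom$records, default_english_words(),
                                    nom$acronym_senses,
                                    config$short_cutoff)
  keywords <- informative_keywords(nom$records,
                                   max_global_frequency =
                                     config$keyword_max_frequency,
                                   ambiguity = ambiguity)
  note("names", aliases = nrow(ambiguity),
       ambiguous = sum(ambiguity$category != "none"),
       keywords = sum(!is.na(keywords$keyword)))

  # --- litcount ------------------------------------------------------------
  domain_kw <- extract_domain_keywords(
    corpus$articles[corpus$articles$journal_class == "domain", ],
    corpus$articles[corpus$articles$journal_class == "non_domain", ],
    config$mesh_min_domain_freq, config$mesh_max_other_freq,
    default_generic_domain_terms())
  noisy <- flag_noisy_articles(corpus$links, config$noisy_max_genes)
  ise_records <- nom$records[nom$records$gene_id %in% ise$gene_id, ]
  lit <- count_literature_all(ise_records, ambiguity, keywords,
                              corpus$articles, domain_kw, noisy)
  note("litcount", domain_keywords = length(domain_kw),
       noisy_articles = length(noisy))

  # --- score ---------------------------------------------------------------
  scored_in <- merge(ise[, c("gene_id", "relative_selectivity")],
                     lit[, c("gene_id", "literature_count")],
                     by = "gene_id")
  scores <- ignorome_scores(scored_in)
  core <- call_core(scores, config$core_max_articles)
  note("score", scored = nrow(scores), core = nrow(core),
       absolute = sum(core$absolute))

  # --- timeseries ----------------------------------------------------------
  gene_articles <- lit$article_ids
  names(gene_articles) <- lit$gene_id
  ts <- shrinkage_timeseries(gene_articles, corpus$articles,
                             years = seq(sm$year_range[1],
                                         sm$year_range[2]),
                             window = config$timeseries_window)
  note("timeseries", years = nrow(ts),
       final_ignorome = utils::tail(ts$ignorome_size, 1))

  # --- compare -------------------------------------------------------------
  lit_vec <- scores$literature_count
  names(lit_vec) <- scores$gene_id
  ann_tab <- simulate_annotation_tables(scores$gene_id,
                                        seed = config$seed,
                                        lit_counts = lit_vec,
                                        correlation = 0)
  feat <- function(col) { v <- ann_tab[[col]]; names(v) <- ann_tab$gene_id; v }
  correlations <- list(
    orthologs = literature_structure_correlation(lit_vec,
                                                 feat("ortholog_count")),
    paralogs = literature_structure_correlation(lit_vec,
                                                feat("paralog_count")),
    domains = literature_structure_correlation(lit_vec,
                                               feat("domain_count")))
  core_sorted <- core[order(-core$score, core$gene_id), ]
  well <- scores[order(scores$literature_count, decreasing = TRUE), ]
  n_half <- max(2L, min(50L, floor(nrow(scores) / 4)))
  years_of <- feat("discovery_year")
  discovery <- if (nrow(core_sorted) >= 2L)
    discovery_year_comparison(
      years_of[well$gene_id[seq_len(n_half)]],
      years_of[core_sorted$gene_id[seq_len(min(n_half,
                                               nrow(core_sorted)))]])
    else NULL
  note("compare", correlations = length(correlations))

  # --- revcta --------------------------------------------------------------
  core_genes <- utils::head(core_sorted$gene_id, 5)
  if (!length(core_genes)) core_genes <- utils::head(scores$gene_id, 5)
  marker_idx <- round(seq(3, sm$n_markers - 2,
                          length.out = length(core_genes)))
  eqtl_spec <- data.frame(gene_id = core_genes,
                          marker = sprintf("m%03d", marker_idx),
                          effect = sm$eqtl_effect,
                          stringsAsFactors = FALSE)
  pheno_spec <- data.frame(trait = paste0("trait_", core_genes[1]),
                           marker = eqtl_spec$marker[1],
                           effect = sm$pheno_effect,
                           stringsAsFactors = FALSE)
  sp <- simulate_strain_panel(sm$n_strains, sm$n_markers,
                              planted_eqtl = eqtl_spec,
                              planted_pheno_qtl = pheno_spec,
                              n_null_genes = 5, n_null_phenotypes = 5,
                              seed = config$seed)
  cis <- cis_eqtl_filter(sp$panel, lrs_min = config$lrs_min_cis,
                         expr_min = config$expr_floor_cis,
                         window = config$window_mb)
  scans <- lapply(cis$gene_id[cis$qualifies], function(g)
    phenome_scan(sp$panel, g, config$lrs_min_phenome, config$window_mb))
  names(scans) <- cis$gene_id[cis$qualifies]
  note("revcta", tested = nrow(cis), cis_qualifying = sum(cis$qualifies),
       phenome_hits = sum(vapply(scans, nrow, numeric(1))))

  out <- list(ise = ise, ambiguity = ambiguity, keywords = keywords,
              domain_keywords = domain_kw, noisy_articles = noisy,
              literature = lit[, c("gene_id", "literature_count")],
              scores = scores, core = core, timeseries = ts,
              correlations = correlations, discovery = discovery,
              annotation_tables = ann_tab, cis_eqtl = cis,
              phenome_scans = scans, manifest = manifest,
              truth = list(expression = ex$truth, nomenclature = nom$truth,
                           corpus = corpus$truth, strains = sp$truth))

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) write_tsv_table(x, file.path(output_dir, f))
    w(ise, "ise_genes.tsv")
    w(ambiguity, "ambiguous_names.tsv")
    w(keywords, "keywords.tsv")
    w(out$literature, "literature_counts.tsv")
    w(scores, "ignorome_scores.tsv")
    w(core, "core_ignorome.tsv")
    w(ts, "shrinkage_timeseries.tsv")
    w(ann_tab, "annotation_tables.tsv")
    w(cis, "cis_eqtl.tsv")
    write_medline(corpus$articles, file.path(output_dir, "articles.medline"))
    write_config(config, file.path(output_dir, "config.yaml"))
    yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))
  }
  invisible(out)
}
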