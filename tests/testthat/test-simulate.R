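tissues12 <- c("brain", "liver", "kidney", "heart", "lung", "muscle",
               "spleen", "testis", "retina", "thymus", "skin", "bone")

test_that("zero-noise panels plant exact fold changes and nothing else", {
  sim <- simulate_expression_panel(100, tissues12, n_selective = 10,
                                   fold = 16, noise_sd = 0, platforms = 1,
                                   seed = 3)
  v <- sim$panels[[1]]$values
  ratio <- v[, "brain"] / rowMeans(v[, -1])
  planted <- sim$annotations[[1]]$gene_id %in% sim$truth$selective_gene_ids
  expect_equal(unname(ratio[planted]), rep(16, 10))
  expect_equal(unname(ratio[!planted]), rep(1, 90))
  # fold = 1 plants no signal: nothing passes an 8-fold screen
  sim1 <- simulate_expression_panel(100, tissues12, n_selective = 10,
                                    fold = 1, noise_sd = 0, platforms = 1,
                                    seed = 3)
  scr <- selectivity_screen(standardize_panel(sim1$panels[[1]]))
  expect_false(any(scr$passed))
})

test_that("zero-noise ISE screen recovers exactly the planted truth", {
  sim <- simulate_expression_panel(200, tissues12, n_selective = 10,
                                   fold = 16, noise_sd = 0, platforms = 2,
                                   seed = 9)
  per <- lapply(seq_along(sim$panels), function(p) {
    scr <- selectivity_screen(standardize_panel(sim$panels[[p]]))
    g <- filter_and_deduplicate(scr, sim$annotations[[p]])
    g[g$passed, ]
  })
  ise <- merge_platforms(per)
  expect_setequal(ise$gene_id, sim$truth$selective_gene_ids)
  expect_true(all(ise$relative_selectivity > 0 &
                    ise$relative_selectivity <= 1))
})

test_that("simulators are deterministic and validate their inputs", {
  a <- simulate_expression_panel(50, tissues12, n_selective = 5, seed = 4)
  b <- simulate_expression_panel(50, tissues12, n_selective = 5, seed = 4)
  expect_identical(a, b)
  expect_error(simulate_expression_panel(10, tissues12, n_selective = 11,
                                         seed = 1), "n_selective")
  expect_error(simulate_expression_panel(10, c("brain", "brain", "x"),
                                         n_selective = 1, seed = 1),
               "duplicate")
  expect_error(simulate_expression_panel(10, tissues12,
                                         target_tissue = "toe",
                                         n_selective = 1, seed = 1),
               "absent")
  g <- sprintf("g%03d", 1:30)
  c1 <- simulate_literature_corpus(g, 200, seed = 8)
  c2 <- simulate_literature_corpus(g, 200, seed = 8)
  expect_identical(c1, c2)
  expect_error(simulate_literature_corpus(character(0), 10), "empty")
  expect_error(simulate_literature_corpus(g, 10,
                                          year_range = c(2010, 2000)),
               "year range")
  t1 <- simulate_annotation_tables(g, seed = 2)
  expect_identical(t1, simulate_annotation_tables(g, seed = 2))
})

test_that("corpus counts follow the rank power law and conserve links", {
  g <- sprintf("g%04d", 1:500)
  co <- simulate_literature_corpus(g, 10000, zipf_exponent = 1.1, seed = 3,
                                   noisy_article_rate = 0)
  cnt <- table(factor(co$links$gene_id, levels = g))
  # conservation: per-gene counts sum to the number of link rows
  expect_equal(sum(cnt), nrow(co$links))
  # log-log slope of rank vs count near the requested exponent
  srt <- sort(as.numeric(cnt), decreasing = TRUE)
  keep <- srt > 0
  fit <- lm(log(srt[keep]) ~ log(seq_along(srt)[keep]))
  expect_lt(abs(unname(coef(fit)[2]) + 1.1), 0.2)
  # top-5% of genes hold a strictly larger share than the bottom 50%
  expect_gt(sum(srt[1:25]), sum(tail(srt, 250)))
})

test_that("noisy-article planting respects the >50 gene definition", {
  g <- sprintf("g%04d", 1:200)
  co0 <- simulate_literature_corpus(g, 300, noisy_article_rate = 0,
                                    seed = 5)
  per_art <- table(co0$links$article_id)
  expect_true(all(per_art <= 50))
  co <- simulate_literature_corpus(g, 400, noisy_article_rate = 0.1,
                                   seed = 5)
  noisy <- flag_noisy_articles(co$links)
  expect_setequal(noisy, co$truth$noisy_article_ids)
  expect_equal(length(noisy), 40)
})

test_that("nomenclature simulator plants detectable ambiguous aliases", {
  g <- sprintf("g%04d", 1:500)
  nm <- simulate_nomenclature(g, ambiguous_fraction = 0.2, seed = 11)
  flags <- flag_ambiguous_names(nm$records, default_english_words(),
                                nm$acronym_senses)
  truth <- nm$truth$ambiguous_alias_map
  found <- flags$category[match(names(truth), flags$alias)]
  # detector recall of planted categories is exactly 1
  expect_equal(unname(found), unname(truth))
  expect_equal(length(truth), 100)
  # fraction 0 plants nothing the detector flags
  nm0 <- simulate_nomenclature(g[1:50], ambiguous_fraction = 0, seed = 2)
  f0 <- flag_ambiguous_names(nm0$records, default_english_words(),
                             nm0$acronym_senses)
  expect_true(all(f0$category == "none"))
})

test_that("strain panel plants recoverable eQTL under zero noise", {
  eq <- data.frame(gene_id = "gX", marker = "m010", effect = 2)
  sp <- simulate_strain_panel(30, 40, planted_eqtl = eq, noise_sd = 0,
                              seed = 6)
  scan <- lrs_scan(sp$panel, sp$panel$expression["gX", ])
  expect_equal(scan$marker[scan$peak], "m010")
  expect_true(scan$perfect_fit[scan$peak])
  expect_error(
    simulate_strain_panel(30, 20,
                          planted_eqtl = data.frame(gene_id = "g",
                                                    marker = "m999",
                                                    effect = 1)),
    "nonexistent marker")
  expect_error(simulate_strain_panel(5, 20), "at least 10")
})

test_that("null strain panels have small LRS peaks", {
  meds <- vapply(1:40, function(s) {
    sp <- simulate_strain_panel(30, 20, n_null_genes = 1, seed = s)
    max(lrs_scan(sp$panel, sp$panel$expression[1, ])$lrs)
  }, numeric(1))
  # max over 20 markers of a null trait: median across seeds stays modest
  expect_lt(median(meds), 12)
  one <- vapply(1:40, function(s) {
    sp <- simulate_strain_panel(30, 20, n_null_genes = 1, seed = s + 100)
    lrs_scan(sp$panel, sp$panel$expression[1, ])$lrs[7]
  }, numeric(1))
  expect_lt(median(one), 4)
})

test_that("annotation tables respect bounds and the correlation control", {
  g <- sprintf("g%05d", 1:1000)
  set.seed(21)
  lit <- rpois(1000, exp(rnorm(1000, 1, 1)))
  names(lit) <- g
  tab0 <- simulate_annotation_tables(g, seed = 13, lit_counts = lit,
                                     correlation = 0)
  expect_true(all(tab0$ortholog_count >= 0 & tab0$ortholog_count <= 21))
  r0 <- cor(log10(lit + 1), tab0$ortholog_count)
  expect_lt(abs(r0), 0.1)
  tab5 <- simulate_annotation_tables(g, seed = 13, lit_counts = lit,
                                     correlation = 0.5)
  r5 <- cor(log10(lit + 1), tab5$ortholog_count)
  expect_gt(r5, 0.3)
})
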