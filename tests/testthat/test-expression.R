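test_that("2z+8 transform yields mean 8, sd 2 and known hand values", {
  set.seed(11)
  x <- rlnorm(1000, 8, 1.5)
  z <- standardize_2z8(x)
  expect_equal(mean(z), 8, tolerance = 1e-12)
  expect_equal(sd(z), 2, tolerance = 1e-12)
  # hand computation: sample sd of (1,2,3) is 1, so z = (x-2)/1
  expect_equal(standardize_2z8(c(1, 2, 3)), c(6, 8, 10))
  expect_equal(standardize_2z8(c(1, 2, 3))[2], 8)
  # population convention keeps the contract under its own sd definition
  zp <- standardize_2z8(x, sd_type = "population")
  expect_equal(mean(zp), 8, tolerance = 1e-12)
  expect_equal(sqrt(mean((zp - mean(zp))^2)), 2, tolerance = 1e-12)
})

test_that("2z+8 transform is idempotent and rejects degenerate input", {
  set.seed(2)
  x <- rnorm(50)
  z <- standardize_2z8(x)
  expect_equal(standardize_2z8(z), z)
  expect_error(standardize_2z8(rep(3, 10)), "variance")
  expect_error(standardize_2z8(5), "at least 2")
})

test_that("selectivity score matches direct arithmetic and strict threshold", {
  # target 512 against ten tissues at 32: S = 16 regardless of trimming
  p <- toy_panel(512, 32, n_other = 10)
  r <- selectivity_screen(p)
  expect_equal(r$selectivity, 16)
  expect_true(r$passed)
  # brute-force check of the trimmed mean definition on unequal tissues
  oth <- c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100)
  p2 <- toy_panel(400, matrix(oth, 1))
  r2 <- selectivity_screen(p2, max_exempt = 5)
  expect_equal(r2$selectivity, 400 / mean(sort(oth)[1:5]))
  # S exactly 8 is not selective (strict inequality)
  p3 <- toy_panel(8 * 32, 32, n_other = 10)
  expect_false(selectivity_screen(p3, fold_threshold = 8 * 32 / 32)$passed)
  expect_equal(selectivity_screen(p3)$selectivity, 8)
  expect_false(selectivity_screen(p3)$passed)
})

test_that("per-tissue exemption cap follows the 5-of-22 rule", {
  # 22 non-target tissues; `k` of them above target/8 violate the rule
  mk <- function(k) {
    oth <- c(rep(100, k), rep(10, 22 - k))
    toy_panel(400, matrix(oth, 1))
  }
  r6 <- selectivity_screen(mk(6))
  expect_equal(r6$n_exempt_tissues, 6)
  expect_false(r6$passed)
  r5 <- selectivity_screen(mk(5))
  expect_equal(r5$n_exempt_tissues, 5)
  expect_true(r5$passed)
  expect_error(selectivity_screen(toy_panel(10, 5, n_other = 4)),
               "non-target")
})

test_that("selectivity is invariant to rescaling linear intensities", {
  set.seed(31)
  m <- matrix(rlnorm(60, 5, 1), 5)
  p1 <- toy_panel(rlnorm(5, 8, 1), m)
  p2 <- expression_panel(p1$values * 37.5, p1$tissue_labels, "brain",
                         scale = "linear")
  r1 <- selectivity_screen(p1)
  r2 <- selectivity_screen(p2)
  expect_equal(r1$selectivity, r2$selectivity)
  expect_equal(r1$passed, r2$passed)
})

test_that("raising max_exempt never shrinks the passed set", {
  set.seed(5)
  sim <- simulate_expression_panel(80, c("brain", paste0("t", 1:11)),
                                   n_selective = 10, fold = 10,
                                   noise_sd = 0.6, platforms = 1, seed = 5)
  std <- standardize_panel(sim$panels[[1]])
  prev <- character(0)
  for (k in 1:5) {
    cur <- selectivity_screen(std, max_exempt = k)
    cur <- cur$probe_id[cur$passed]
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("probe filters and per-gene deduplication follow the rules", {
  res <- data.frame(
    probe_id = sprintf("pr%02d", 1:6),
    selectivity = c(12, 20, 100, 50, 9, 30),
    n_exempt_tissues = 0L, passed = TRUE, platform_id = "p1",
    stringsAsFactors = FALSE)
  ann <- data.frame(
    probe_id = res$probe_id,
    gene_id = c("gA", "gA", "gB", "gC", "gD", NA),
    multi_mapping = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    non_coding = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    snp_overlap = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    annotation_override = NA_character_,
    stringsAsFactors = FALSE)
  out <- filter_and_deduplicate(res, ann)
  # gA deduplicated to S = 20; gB (snp), gC (multi), gD (non-coding),
  # unassigned probe all dropped
  expect_equal(out$gene_id, "gA")
  expect_equal(out$selectivity, 20)
  log <- attr(out, "filter_log")
  expect_equal(unname(log[c("multi_mapping", "non_coding", "snp_overlap",
                            "unassigned", "duplicate_probe")]),
               c(1, 1, 1, 1, 1))
  # annotation override reassigns before filtering
  ann2 <- ann
  ann2$annotation_override[6] <- "gE"
  out2 <- filter_and_deduplicate(res, ann2)
  expect_setequal(out2$gene_id, c("gA", "gE"))
  # equal-S tie keeps the lexicographically smallest probe id
  res3 <- res[1:2, ]; res3$selectivity <- c(20, 20)
  out3 <- filter_and_deduplicate(res3, ann[1:2, ])
  expect_equal(out3$probe_id, "pr01")
})

test_that("platform merge keeps the maximum relative selectivity", {
  d1 <- data.frame(gene_id = c("g1", "g2", "g3"),
                   selectivity = c(4, 8, 16), platform_id = "p1")
  m1 <- merge_platforms(d1)
  expect_equal(m1$relative_selectivity[match(c("g1", "g2", "g3"),
                                             m1$gene_id)],
               c(0.25, 0.5, 1))
  expect_equal(sum(m1$relative_selectivity == 1), 1)
  # shared gene keeps the larger R
  d2 <- data.frame(gene_id = c("g3", "g4"), selectivity = c(6, 20),
                   platform_id = "p2")
  m <- merge_platforms(list(d1, d2))
  expect_setequal(m$gene_id, c("g1", "g2", "g3", "g4"))
  expect_equal(m$relative_selectivity[m$gene_id == "g3"], 1)  # 1 > 0.3
  # disjoint platforms union
  d3 <- data.frame(gene_id = c("h1", "h2", "h3"),
                   selectivity = c(1, 2, 3), platform_id = "p3")
  expect_equal(nrow(merge_platforms(list(d1, d3))), 6)
  expect_error(merge_platforms(list(d1[0, ])), "empty platform")
})

test_that("panel TSV round-trips", {
  p <- toy_panel(c(100, 50), matrix(rlnorm(20, 3, 1), 2))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression_panel(p, f)
  q <- read_expression_panel(f, "brain")
  expect_equal(q$values, p$values)
  expect_equal(q$tissue_labels, p$tissue_labels)
})
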