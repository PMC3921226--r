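#' Recombinant-inbred-like strain panel
#'
#' Container bundling a biallelic marker map and genotypes with expression
#' traits, phenotypes, gene positions, and variant-impact annotations for a
#' family of inbred strains (a BXD-like panel: alleles `B` and `D`,
#' missing = `U`).
#'
#' @param markers data frame `marker`, `chr`, `mb`, sorted by (chr, mb).
#' @param genotypes character matrix markers x strains with entries in
#'   `c("B", "D", "U")`; row names = marker ids.
#' @param expression numeric matrix genes x strains (standardized units).
#' @param phenotypes numeric matrix traits x strains (may have 0 rows).
#' @param gene_positions data frame `gene_id`, `chr`, `mb`.
#' @param variant_annotations data frame `gene_id`, `impact` in
#'   `c("none", "moderate", "high")`.
#' @return an object of class `strain_panel`.
#' @export
strain_panel <- function(markers, genotypes, expression,
                         phenotypes = NULL, gene_positions = NULL,
                         variant_annotations = NULL) {
  stopifnot(all(c("marker", "chr", "mb") %in% names(markers)))
  for (ch in unique(markers$chr)) {
    mb <- markers$mb[markers$chr == ch]
    if (is.unsorted(mb)) stop("marker positions unsorted on chr ", ch)
  }
  if (!all(genotypes %in% c("B", "D", "U")))
    stop("genotype codes must be B, D, or U")
  if (nrow(genotypes) != nrow(markers))
    stop("genotype rows must match markers")
  rownames(genotypes) <- markers$marker
  structure(list(markers = markers, genotypes = genotypes,
                 expression = expression,
                 phenotypes = phenotypes,
                 gene_positions = gene_positions,
                 variant_annotations = variant_annotations,
                 strains = colnames(genotypes)),
            class = "strain_panel")
}

#' @export
print.strain_panel <- function(x, ...) {
  cat("strain_panel:", length(x$strains), "strains,",
      nrow(x$markers), "markers,",
      if (is.null(x$expression)) 0 else nrow(x$expression),
      "expression traits,",
      if (is.null(x$phenotypes)) 0 else nrow(x$phenotypes),
      "phenotypes\n")
  invisible(x)
}

# Numeric allele coding: B = -1, D = +1, U = NA.
code_alleles <- function(g) {
  out <- rep(NA_real_, length(g))
  out[g == "B"] <- -1
  out[g == "D"] <- 1
  out
}

# Cap applied when a marker fits a trait perfectly (RSS1 at machine floor
# would make the likelihood ratio unbounded); ~ LOD 10.
LRS_PERFECT_CAP <- 46.05

#' Likelihood ratio statistic for one marker-trait association
#'
#' Single-marker regression LRS: `n * ln(RSS0 / RSS1)` with `RSS0` from the
#' mean-only model and `RSS1` from ordinary least squares of the trait on
#' allele codes (B = -1, D = +1).  Strains with missing trait or genotype
#' are dropped pairwise.  A monomorphic marker yields LRS 0 with a warning;
#' a perfect fit is capped at `46.05` (~ LOD 10) and flagged via the
#' `perfect_fit` attribute.  `LRS = 4.61 * LOD`.
#'
#' @param trait numeric per-strain trait values.
#' @param genotypes per-strain codes (`"B"`/`"D"`/`"U"` or numeric -1/+1).
#' @return LRS (scalar) with attributes `direction` (`"B"` or `"D"`: allele
#'   associated with higher trait values) and `perfect_fit` (logical).
#' @export
marker_lrs <- function(trait, genotypes) {
  x <- if (is.numeric(genotypes)) genotypes else code_alleles(genotypes)
  ok <- !is.na(trait) & !is.na(x)
  y <- trait[ok]; x <- x[ok]
  n <- length(y)
  if (n < 8L) stop("need >= 8 strains with trait and genotype")
  if (length(unique(x)) < 2L) {
    warning("monomorphic marker: LRS set to 0")
    return(structure(0, direction = NA_character_, perfect_fit = FALSE))
  }
  rss0 <- sum((y - mean(y))^2)
  beta <- stats::cov(x, y) / stats::var(x)
  alpha <- mean(y) - beta * mean(x)
  rss1 <- sum((y - alpha - beta * x)^2)
  direction <- if (beta >= 0) "D" else "B"
  if (rss0 == 0)
    return(structure(0, direction = direction, perfect_fit = FALSE))
  if (rss1 <= rss0 * 1e-12)
    return(structure(LRS_PERFECT_CAP, direction = direction,
                     perfect_fit = TRUE))
  lrs <- n * log(rss0 / rss1)
  structure(min(lrs, LRS_PERFECT_CAP), direction = direction,
            perfect_fit = lrs >= LRS_PERFECT_CAP)
}

#' Genome scan of a trait over all panel markers
#'
#' @param panel a [strain_panel()].
#' @param trait per-strain numeric vector aligned with `panel$strains`.
#' @param markers optional subset of marker ids to scan.
#' @return data frame `marker`, `chr`, `mb`, `lrs`, `direction`,
#'   `perfect_fit`, with the peak row marked in the `peak` column.
#' @export
lrs_scan <- function(panel, trait, markers = NULL) {
  mk <- panel$markers
  if (!is.null(markers)) mk <- mk[mk$marker %in% markers, , drop = FALSE]
  if (!nrow(mk)) {
    warning("no markers to scan")
    return(data.frame(marker = character(0), chr = character(0),
                      mb = numeric(0), lrs = numeric(0),
                      direction = character(0), perfect_fit = logical(0),
                      peak = logical(0)))
  }
  res <- lapply(mk$marker, function(m) {
    l <- suppressWarnings(marker_lrs(trait, panel$genotypes[m, ]))
    data.frame(marker = m, lrs = as.numeric(l),
               direction = attr(l, "direction") %||% NA_character_,
               perfect_fit = attr(l, "perfect_fit"),
               stringsAsFactors = FALSE)
  })
  out <- cbind(mk[, c("marker", "chr", "mb")],
               do.call(rbind, res)[, c("lrs", "direction", "perfect_fit")])
  out$peak <- seq_len(nrow(out)) == which.max(out$lrs)
  rownames(out) <- NULL
  out
}

#' cis-eQTL filter
#'
#' A gene qualifies as cis-modulated when (1) its expression trait's peak
#' LRS strictly exceeds `lrs_min` with the peak marker within `window` Mb
#' of the gene's position on the same chromosome, (2) its mean expression
#' strictly exceeds `expr_min` units, and (3) it carries a moderate- or
#' high-impact coding variant.
#'
#' @param panel a [strain_panel()] with expression, gene positions and
#'   variant annotations.
#' @param genes gene ids to test (default: all expression traits).
#' @param lrs_min LRS threshold (default 12, strict).
#' @param expr_min expression floor in standardized units (default 7,
#'   strict).
#' @param window cis window in Mb (default 5).
#' @return data frame with one row per tested gene: `gene_id`, `peak_marker`,
#'   `peak_chr`, `peak_mb`, `peak_lrs`, `direction`, `mean_expression`,
#'   `impact`, `cis` (peak within window), `qualifies`.
#' @export
cis_eqtl_filter <- function(panel, genes = NULL, lrs_min = 12,
                            expr_min = 7, window = 5) {
  genes <- genes %||% rownames(panel$expression)
  imp <- panel$variant_annotations$impact
  names(imp) <- panel$variant_annotations$gene_id
  rows <- lapply(genes, function(g) {
    gp <- panel$gene_positions[panel$gene_positions$gene_id == g, ]
    if (!nrow(gp)) {
      warning("gene ", g, " has no position; skipped")
      return(NULL)
    }
    scan <- lrs_scan(panel, panel$expression[g, ])
    pk <- scan[scan$peak, ][1, ]
    me <- mean(panel$expression[g, ], na.rm = TRUE)
    impact <- imp[g]
    if (is.na(impact)) impact <- "none"
    cis <- pk$chr == gp$chr && abs(pk$mb - gp$mb) <= window
    data.frame(gene_id = g, peak_marker = pk$marker, peak_chr = pk$chr,
               peak_mb = pk$mb, peak_lrs = pk$lrs, direction = pk$direction,
               mean_expression = me, impact = unname(impact), cis = cis,
               qualifies = pk$lrs > lrs_min && cis && me > expr_min &&
                 impact %in% c("moderate", "high"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Windowed phenome scan around a gene
#'
#' Scans every phenotype in the panel against the markers lying within
#' `window` Mb of a gene's position on its chromosome (the search the
#' paper-style `LRS = (10 999 ChrZ XX YY)` filter expresses), returning
#' phenotypes whose in-window peak LRS strictly exceeds `lrs_min`, together
#' with the Pearson correlation between the phenotype and the gene's
#' expression.
#'
#' @param panel a [strain_panel()] with phenotypes.
#' @param gene gene id (must have a position; its expression trait is used
#'   for the correlation when available).
#' @param lrs_min LRS threshold (default 10, strict).
#' @param window window half-width in Mb (default 5).
#' @return data frame `trait`, `peak_marker`, `peak_mb`, `peak_lrs`,
#'   `direction`, `r_expression`; empty (with a warning) when no markers
#'   fall in the window.
#' @export
phenome_scan <- function(panel, gene, lrs_min = 10, window = 5) {
  gp <- panel$gene_positions[panel$gene_positions$gene_id == gene, ]
  if (!nrow(gp)) stop("unknown gene position: ", gene)
  mk <- panel$markers
  in_win <- mk$chr == gp$chr & abs(mk$mb - gp$mb) <= window
  empty <- data.frame(trait = character(0), peak_marker = character(0),
                      peak_mb = numeric(0), peak_lrs = numeric(0),
                      direction = character(0), r_expression = numeric(0))
  if (!any(in_win)) {
    warning("no markers within ", window, " Mb of ", gene)
    return(empty)
  }
  win_markers <- mk$marker[in_win]
  expr <- if (!is.null(panel$expression) &&
              gene %in% rownames(panel$expression))
    panel$expression[gene, ] else NULL
  rows <- lapply(rownames(panel$phenotypes), function(tr) {
    scan <- lrs_scan(panel, panel$phenotypes[tr, ], markers = win_markers)
    pk <- scan[which.max(scan$lrs), ][1, ]
    if (pk$lrs <= lrs_min) return(NULL)
    r <- if (is.null(expr)) NA_real_ else
      suppressWarnings(stats::cor(panel$phenotypes[tr, ], expr,
                                  use = "pairwise.complete.obs"))
    data.frame(trait = tr, peak_marker = pk$marker, peak_mb = pk$mb,
               peak_lrs = pk$lrs, direction = pk$direction,
               r_expression = r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Read / write GeneNetwork-style genotype tables
#'
#' Layout: columns `marker`, `chr`, `mb`, then one column per strain with
#' codes `B`/`D`/`U`.
#'
#' @param panel a [strain_panel()]; `path` a file path.
#' @param path file path.
#' @return `read_geno_tsv()` returns a list with `markers` and `genotypes`
#'   ready for [strain_panel()].
#' @export
write_geno_tsv <- function(panel, path) {
  df <- cbind(panel$markers[, c("marker", "chr", "mb")],
              as.data.frame(panel$genotypes, stringsAsFactors = FALSE))
  write_tsv_table(df, path)
}

#' @rdname write_geno_tsv
#' @export
read_geno_tsv <- function(path) {
  df <- read_tsv_table(path)
  geno <- as.matrix(df[, -(1:3), drop = FALSE])
  rownames(geno) <- df$marker
  list(markers = df[, c("marker", "chr", "mb")], genotypes = geno)
}
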