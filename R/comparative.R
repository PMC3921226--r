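#' Coexpression connectivity profile
#'
#' Counts, for each target gene, how many other genes in a genes-by-strains
#' coexpression panel correlate with it above each |r| threshold.  Genes
#' with mean expression below `min_expression` (standardized units) and
#' genes with SNP-overlapping probes are removed first; chromosomal
#' neighbours of the target (same chromosome, within `neighbor_window` Mb)
#' and the target itself are excluded from its counts, since linkage alone
#' inflates local correlations.
#'
#' @param expr numeric matrix, genes in rows (row names = gene ids),
#'   strains in columns; at least 30 strain columns.
#' @param positions data frame `gene_id`, `chr`, `mb`.
#' @param targets character vector of target gene ids.
#' @param thresholds |r| thresholds (default `c(0.75, 0.80, 0.85, 0.90,
#'   0.95)`).
#' @param min_expression mean-expression floor in standardized units
#'   (default 8).
#' @param neighbor_window linkage-exclusion window in Mb (default 5).
#' @param snp_overlap optional logical vector (named by gene id) flagging
#'   genes whose probes overlap segregating SNPs.
#' @return data frame with one row per (target, threshold): `gene_id`,
#'   `threshold`, `n_covariates`; targets dropped by the filters get `NA`
#'   counts with a warning.
#' @export
connectivity_profile <- function(expr, positions, targets,
                                 thresholds = c(0.75, 0.80, 0.85, 0.90, 0.95),
                                 min_expression = 8, neighbor_window = 5,
                                 snp_overlap = NULL) {
  if (ncol(expr) < 30L)
    warning("fewer than 30 strains: correlations will be unstable")
  keep <- rowMeans(expr) >= min_expression
  if (!is.null(snp_overlap))
    keep <- keep & !(snp_overlap[rownames(expr)] %in% TRUE)
  panel <- expr[keep, , drop = FALSE]
  pos <- positions[match(rownames(panel), positions$gene_id), ]
  rows <- list()
  for (g in targets) {
    if (!g %in% rownames(panel)) {
      warning("target ", g, " absent after filtering; null profile")
      rows[[g]] <- data.frame(gene_id = g, threshold = thresholds,
                              n_covariates = NA_integer_)
      next
    }
    r <- as.vector(stats::cor(panel[g, ], t(panel)))
    names(r) <- rownames(panel)
    gp <- pos[pos$gene_id == g, ]
    neighbor <- pos$chr == gp$chr & abs(pos$mb - gp$mb) <= neighbor_window
    r <- r[!neighbor & rownames(panel) != g]
    rows[[g]] <- data.frame(gene_id = g, threshold = thresholds,
                            n_covariates = vapply(thresholds, function(th)
                              sum(abs(r) >= th, na.rm = TRUE), numeric(1)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Top covariates of a target gene
#'
#' Returns the `top_n` genes most correlated (by |r|) with a target in a
#' coexpression panel, applying the same expression-floor, SNP and
#' linkage-neighbour exclusions as [connectivity_profile()].  This is the
#' sample fed into [go_enrichment()].
#'
#' @inheritParams connectivity_profile
#' @param target single target gene id.
#' @param top_n number of covariates to return (default 100).
#' @param absolute rank by |r| (default) or signed r.
#' @return data frame `gene_id`, `r`, ordered by decreasing rank statistic.
#' @export
top_covariates <- function(expr, positions, target, top_n = 100,
                           min_expression = 8, neighbor_window = 5,
                           snp_overlap = NULL, absolute = TRUE) {
  keep <- rowMeans(expr) >= min_expression
  if (!is.null(snp_overlap))
    keep <- keep & !(snp_overlap[rownames(expr)] %in% TRUE)
  panel <- expr[keep, , drop = FALSE]
  if (!target %in% rownames(panel)) {
    warning("target ", target, " absent after filtering")
    return(data.frame(gene_id = character(0), r = numeric(0)))
  }
  r <- as.vector(stats::cor(panel[target, ], t(panel)))
  names(r) <- rownames(panel)
  pos <- positions[match(rownames(panel), positions$gene_id), ]
  gp <- pos[pos$gene_id == target, ]
  neighbor <- pos$chr == gp$chr & abs(pos$mb - gp$mb) <= neighbor_window
  r <- r[!neighbor & rownames(panel) != target]
  stat <- if (absolute) abs(r) else r
  ord <- order(-stat, names(r))
  sel <- ord[seq_len(min(top_n, length(ord)))]
  data.frame(gene_id = names(r)[sel], r = unname(r[sel]),
             stringsAsFactors = FALSE)
}

#' Correlate literature coverage with structural gene features
#'
#' Regresses a per-gene structural feature count (orthologs, paralogs, or
#' protein domains) on `log10(L + 1)` of the literature count.  The OLS
#' slope is directly interpretable as "features per 10-fold increase in
#' literature".
#'
#' @param lit_counts named numeric vector of literature counts `L`.
#' @param feature_counts named numeric vector of feature counts; names are
#'   matched to `lit_counts` (genes present in both are used).
#' @return list with `r` (Pearson), `slope` (features per 10-fold
#'   literature), `intercept`, `r_squared`, `p_value` (two-sided), `n`.
#' @export
literature_structure_correlation <- function(lit_counts, feature_counts) {
  if (is.null(names(lit_counts)) || is.null(names(feature_counts))) {
    if (length(lit_counts) != length(feature_counts))
      stop("unnamed vectors must have equal length")
    x <- log10(lit_counts + 1); y <- feature_counts
  } else {
    genes <- intersect(names(lit_counts), names(feature_counts))
    x <- log10(lit_counts[genes] + 1); y <- feature_counts[genes]
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 genes with both values")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in literature or feature counts")
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       p_value = ct$p.value,
       n = length(x))
}

#' Hypergeometric GO enrichment with FDR control
#'
#' Tests each annotation term for over-representation in a gene sample
#' (typically the top covariates of a core-ignorome gene) relative to a
#' universe, with the upper-tail hypergeometric probability
#' `P(X >= k)` for an urn of `|universe|` genes of which `K` carry the term
#' and `|sample|` are drawn.  Raw p-values are Benjamini-Hochberg adjusted
#' across the tested terms.
#'
#' @param sample character vector of sample gene ids (must be a subset of
#'   `universe`).
#' @param universe character vector of universe gene ids.
#' @param annotations named list mapping term ids to character vectors of
#'   annotated gene ids, or a data frame with columns `term`, `gene_id`.
#' @param fdr significance level on adjusted p (default 0.05).
#' @return data frame `term`, `k` (annotated in sample), `K` (annotated in
#'   universe), `n` (sample size), `N` (universe size), `p`, `p_adj`,
#'   `significant`; terms with no annotated genes in the universe are
#'   skipped.
#' @export
go_enrichment <- function(sample, universe, annotations, fdr = 0.05) {
  if (is.data.frame(annotations))
    annotations <- split(annotations$gene_id, annotations$term)
  sample <- unique(sample); universe <- unique(universe)
  if (!all(sample %in% universe))
    stop("sample must be a subset of the universe")
  N <- length(universe); n <- length(sample)
  rows <- lapply(names(annotations), function(term) {
    ann <- intersect(unique(annotations[[term]]), universe)
    K <- length(ann)
    if (K == 0L) return(NULL)
    k <- length(intersect(ann, sample))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0), significant = logical(0)))
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < fdr
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  out
}
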