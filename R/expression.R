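#' Multi-tissue expression panel
#'
#' Container for a probes-by-tissues intensity matrix from one platform.
#' Exactly one tissue is flagged as the target tissue (brain, in the
#' motivating use case).  `scale` records whether values are raw linear
#' intensities or per-array standardized units (z-scores doubled and offset
#' by 8, i.e. mean 8 / sd 2, roughly log2-comparable).
#'
#' @param values numeric matrix, probes in rows, tissues in columns.  Row
#'   names are probe ids; column names, if present, must equal
#'   `tissue_labels`.
#' @param tissue_labels character vector of distinct tissue names.
#' @param target_tissue the tissue selectivity is computed against.
#' @param platform_id platform label (e.g. array type).
#' @param scale `"linear"` or `"standardized_2z8"`.
#' @return an object of class `expression_panel`.
#' @export
expression_panel <- function(values, tissue_labels, target_tissue,
                             platform_id = "platform1",
                             scale = c("linear", "standardized_2z8")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (ncol(values) != length(tissue_labels))
    stop("`values` must have one column per tissue label")
  if (anyDuplicated(tissue_labels))
    stop("duplicate tissue labels")
  if (anyNA(tissue_labels) || any(!nzchar(tissue_labels)))
    stop("missing tissue labels")
  if (!target_tissue %in% tissue_labels)
    stop("target tissue '", target_tissue, "' absent from tissue labels")
  if (length(tissue_labels) < 3L)
    stop("need at least 3 tissues (one target, >= 2 others)")
  if (nrow(values) < 1L || any(dim(values) <= 0L))
    stop("non-positive panel dimensions")
  if (!all(is.finite(values)))
    stop("expression values must be finite")
  if (scale == "linear" && any(values <= 0))
    stop("linear-scale intensities must be positive")
  colnames(values) <- tissue_labels
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("probe%05d", seq_len(nrow(values)))
  structure(list(platform_id = platform_id,
                 probe_ids = rownames(values),
                 tissue_labels = tissue_labels,
                 target_tissue = target_tissue,
                 values = values,
                 scale = scale),
            class = "expression_panel")
}

#' @export
print.expression_panel <- function(x, ...) {
  cat("expression_panel:", x$platform_id, "-", nrow(x$values), "probes x",
      ncol(x$values), "tissues (target:", x$target_tissue,
      "; scale:", x$scale, ")\n")
  invisible(x)
}

#' Per-array variance-stabilizing transform (2z + 8)
#'
#' Converts one array's intensities to doubled z-scores offset by 8 units:
#' `2 * (x - mean(x)) / sd(x) + 8`.  The output has mean 8 and standard
#' deviation 2 under the same sd convention used to compute it, avoiding the
#' two drawbacks of plain z-scores (half the values negative, range detached
#' from the log2 scale).
#'
#' @param x numeric vector of length >= 2 (one array).
#' @param sd_type `"sample"` (divide by n-1, default) or `"population"`.
#' @return the standardized vector.
#' @export
standardize_2z8 <- function(x, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(x) < 2L) stop("need at least 2 values per array")
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite values in array")
  s <- stats::sd(x)
  if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
  if (!is.finite(s) || s == 0)
    stop("zero variance array: 2z+8 transform undefined")
  2 * (x - mean(x)) / s + 8
}

#' Standardize every array of a panel
#'
#' Log2-transforms linear intensities and applies [standardize_2z8()]
#' column-wise (each tissue column is one array), so one standardized unit
#' corresponds roughly to a two-fold difference in mRNA concentration.  An
#' error is raised if the panel is already standardized.
#'
#' @param panel an [expression_panel()].
#' @inheritParams standardize_2z8
#' @return a standardized `expression_panel`.
#' @export
standardize_panel <- function(panel, sd_type = c("sample", "population")) {
  stopifnot(inherits(panel, "expression_panel"))
  if (panel$scale != "linear") stop("panel is already standardized")
  v <- apply(log2(panel$values), 2L, standardize_2z8,
             sd_type = match.arg(sd_type))
  rownames(v) <- panel$probe_ids
  expression_panel(v, panel$tissue_labels, panel$target_tissue,
                   panel$platform_id, scale = "standardized_2z8")
}

# Convert a standardized matrix to the linear scale on which fold ratios are
# meaningful.  One standardized unit ~ one log2 unit, so linear = 2^x after
# clamping values below the background floor (default 6 units).
linearize_values <- function(values, scale, floor = 6) {
  if (scale == "linear") return(values)
  if (!is.null(floor)) values[values < floor] <- floor
  2^values
}

#' Selectivity screen for intense and selective expression (ISE)
#'
#' For each probe computes the target-tissue selectivity score `S`: linear
#' target intensity divided by the mean linear intensity of the non-target
#' tissues, after excluding the `max_exempt` highest non-target tissues from
#' that mean (allowing limited expression in a few tissues such as testis or
#' retina).  A probe passes when `S` strictly exceeds `fold_threshold` *and*
#' the per-tissue fold change target/tissue reaches `fold_threshold` in all
#' but at most `max_exempt` non-target tissues.
#'
#' Standardized panels are converted to the linear scale via `2^x` after
#' clamping values below `floor` (background noise level); set
#' `floor = NULL` to disable clamping, or `linearize = FALSE` to ratio the
#' stored values directly.
#'
#' @param panel an [expression_panel()].
#' @param fold_threshold linear fold-change threshold (default 8).
#' @param max_exempt maximum number of non-target tissues allowed to violate
#'   the per-tissue fold rule; the same number of top non-target tissues is
#'   excluded from the mean (default 5).
#' @param floor background clamp applied to standardized values before
#'   linearization, in standardized units (default 6).
#' @param linearize convert standardized values to linear scale (default
#'   `TRUE`; ignored for linear panels).
#' @return a data frame with one row per probe: `probe_id`, `selectivity`
#'   (`S`), `n_exempt_tissues`, `passed`, `platform_id`.
#' @export
selectivity_screen <- function(panel, fold_threshold = 8, max_exempt = 5,
                               floor = 6, linearize = TRUE) {
  stopifnot(inherits(panel, "expression_panel"), fold_threshold > 0,
            max_exempt >= 0)
  non_target <- setdiff(panel$tissue_labels, panel$target_tissue)
  if (length(non_target) < max_exempt + 1L)
    stop("need more than `max_exempt` non-target tissues")
  vals <- panel$values
  if (panel$scale == "standardized_2z8" && linearize)
    vals <- linearize_values(vals, panel$scale, floor)
  tgt <- vals[, panel$target_tissue]
  oth <- vals[, non_target, drop = FALSE]

  s <- numeric(nrow(vals))
  n_exempt <- integer(nrow(vals))
  for (i in seq_len(nrow(vals))) {
    v <- oth[i, ]
    keep <- sort(v)[seq_len(length(v) - max_exempt)]
    s[i] <- tgt[i] / mean(keep)
    n_exempt[i] <- sum(tgt[i] / v < fold_threshold)
  }
  data.frame(probe_id = panel$probe_ids,
             selectivity = s,
             n_exempt_tissues = n_exempt,
             passed = s > fold_threshold & n_exempt <= max_exempt,
             platform_id = panel$platform_id,
             stringsAsFactors = FALSE)
}

#' Filter probes and collapse to gene level
#'
#' Applies the probe-level quality filters and deduplicates probes per gene.
#' Annotation overrides (manual re-annotations, e.g. probes that actually
#' map to the distal 3' UTR of another gene) are applied first.  Probes
#' flagged multi-mapping, non-coding, or SNP-overlapping are dropped, as are
#' probes with no gene assignment.  Among probes sharing a gene the one with
#' the highest selectivity is retained (ties broken by lexicographically
#' smallest probe id).
#'
#' @param results probe-level data frame from [selectivity_screen()].
#' @param annotation data frame with columns `probe_id`, `gene_id`, and
#'   logical `multi_mapping`, `non_coding`, `snp_overlap`; optional
#'   `annotation_override` column with corrected gene ids (NA where absent).
#' @return gene-level data frame (`gene_id`, `selectivity`,
#'   `n_exempt_tissues`, `passed`, `probe_id`, `platform_id`), with a
#'   `filter_log` attribute recording counts removed per filter reason.
#' @export
filter_and_deduplicate <- function(results, annotation) {
  missing_probes <- setdiff(results$probe_id, annotation$probe_id)
  if (length(missing_probes))
    stop("unannotated probes: ", paste(utils::head(missing_probes), collapse = ", "))
  ann <- annotation[match(results$probe_id, annotation$probe_id), ]
  gene <- ann$gene_id
  if (!is.null(ann$annotation_override)) {
    ov <- !is.na(ann$annotation_override) & nzchar(ann$annotation_override)
    gene[ov] <- ann$annotation_override[ov]
  }
  drop_multi <- isTRUE_vec(ann$multi_mapping)
  drop_nc <- isTRUE_vec(ann$non_coding)
  drop_snp <- isTRUE_vec(ann$snp_overlap)
  drop_nogene <- is.na(gene) | !nzchar(gene)
  keep <- !(drop_multi | drop_nc | drop_snp | drop_nogene)
  log <- c(multi_mapping = sum(drop_multi), non_coding = sum(drop_nc),
           snp_overlap = sum(drop_snp), unassigned = sum(drop_nogene & !(drop_multi | drop_nc | drop_snp)))

  out <- results[keep, , drop = FALSE]
  out$gene_id <- gene[keep]
  # order so that the max-S (then smallest probe_id) row comes first per gene
  out <- out[order(out$gene_id, -out$selectivity, out$probe_id), ]
  dup <- duplicated(out$gene_id)
  log <- c(log, duplicate_probe = sum(dup))
  out <- out[!dup, c("gene_id", "selectivity", "n_exempt_tissues",
                     "passed", "probe_id", "platform_id")]
  rownames(out) <- NULL
  attr(out, "filter_log") <- log
  out
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & as.logical(x)

#' Merge platform ISE sets on relative selectivity
#'
#' Within each platform, selectivity scores are rescaled to relative
#' selectivity `R = S / max(S)` so the most brain-selective gene on every
#' array scores exactly 1; platforms are then merged by gene union, keeping
#' each shared gene's highest relative score.
#'
#' @param per_platform list of gene-level data frames from
#'   [filter_and_deduplicate()] (or any frame with `gene_id`, `selectivity`,
#'   `platform_id`; rows should already be restricted to the genes of
#'   interest, typically `passed` genes).
#' @return data frame `gene_id`, `relative_selectivity`, `selectivity`,
#'   `platform_id` (platform contributing the retained score).
#' @export
merge_platforms <- function(per_platform) {
  if (is.data.frame(per_platform)) per_platform <- list(per_platform)
  if (length(per_platform) < 1L) stop("need at least one platform")
  scored <- lapply(per_platform, function(d) {
    if (nrow(d) == 0L) stop("empty platform after filtering")
    d$relative_selectivity <- d$selectivity / max(d$selectivity)
    d
  })
  all <- do.call(rbind, lapply(scored, function(d)
    d[, c("gene_id", "relative_selectivity", "selectivity", "platform_id")]))
  all <- all[order(all$gene_id, -all$relative_selectivity, all$platform_id), ]
  out <- all[!duplicated(all$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Read / write a probes-by-tissues expression matrix as TSV
#'
#' The TSV layout is a `probe_id` column followed by one column per tissue.
#'
#' @param panel an [expression_panel()]; `path` a file path.
#' @inheritParams expression_panel
#' @return `read_expression_panel()` returns an `expression_panel`.
#' @export
write_expression_panel <- function(panel, path) {
  df <- data.frame(probe_id = panel$probe_ids, panel$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_table(df, path)
}

#' @rdname write_expression_panel
#' @param path file path.
#' @export
read_expression_panel <- function(path, target_tissue,
                                  platform_id = "platform1",
                                  scale = c("linear", "standardized_2z8")) {
  df <- read_tsv_table(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_panel(m, colnames(m), target_tissue, platform_id,
                   match.arg(scale))
}
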