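#' Harmonic-mean ignorome scores
#'
#' For each gene in an ISE set of size `N`, two inclusive fractional ranks
#' are computed: `f_sel`, the fraction of ISE genes whose relative
#' selectivity is at most the gene's own (`|{h : R_h <= R_g}| / N`), and
#' `f_lit`, the fraction with at least the gene's literature count
#' (`|{h : L_h >= L_g}| / N`).  The ignorome score is their harmonic mean
#' `I = 2 f_sel f_lit / (f_sel + f_lit)`.  Both fractions include the gene
#' itself, so scores are strictly positive; a gene with the uniquely highest
#' selectivity and uniquely smallest literature scores exactly 1 (relatively
#' unknown), while a heavily studied gene scores near 0 (relatively well
#' known).
#'
#' @param genes data frame with columns `gene_id`, `relative_selectivity`
#'   (`R`, in (0, 1]) and `literature_count` (`L`, non-negative integers).
#' @return data frame with columns `gene_id`, `relative_selectivity`,
#'   `literature_count`, `f_sel`, `f_lit`, `score`, `core` (`L <= 1`),
#'   `absolute` (`L == 0`).
#' @export
ignorome_scores <- function(genes) {
  if (!nrow(genes)) stop("empty gene table")
  r <- genes$relative_selectivity
  l <- genes$literature_count
  stopifnot(all(r > 0), all(l >= 0))
  n <- length(r)
  f_sel <- vapply(r, function(x) sum(r <= x), numeric(1)) / n
  f_lit <- vapply(l, function(x) sum(l >= x), numeric(1)) / n
  score <- 2 * f_sel * f_lit / (f_sel + f_lit)
  data.frame(gene_id = genes$gene_id,
             relative_selectivity = r,
             literature_count = l,
             f_sel = f_sel, f_lit = f_lit, score = score,
             core = l <= 1, absolute = l == 0,
             stringsAsFactors = FALSE)
}

#' Call the core and absolute ignorome
#'
#' The core ignorome holds ISE genes with at most `max_articles` domain
#' articles (default 1); the absolute ignorome is the zero-literature
#' subset.
#'
#' @param records scored data frame from [ignorome_scores()].
#' @param max_articles core inclusion threshold (default 1).
#' @return `records` restricted to the core, with the `core`/`absolute`
#'   flags recomputed at the requested threshold.
#' @export
call_core <- function(records, max_articles = 1) {
  out <- records[records$literature_count <= max_articles, , drop = FALSE]
  out$core <- rep(TRUE, nrow(out))
  out$absolute <- out$literature_count == 0
  rownames(out) <- NULL
  out
}

#' Ignorome shrinkage time series
#'
#' Tracks, per calendar year, how many ISE genes still have zero qualifying
#' domain articles dated at or before that year (the ignorome of that
#' moment), the cumulative number of domain articles, a trailing-window
#' elimination rate (genes removed from the ignorome per year), and the
#' number of domain articles "spent" per eliminated gene over the window.
#'
#' @param gene_articles named list mapping each ISE gene id to the ids of
#'   its qualifying articles (same query/noisy-exclusion semantics as
#'   [count_literature()]; genes with no articles map to empty vectors).
#'   Typically the `article_ids` column of [count_literature_all()].
#' @param articles article data frame with `article_id`, `year`,
#'   `journal_class`.
#' @param years integer vector of evaluation years (default: the article
#'   year range).
#' @param window trailing window in years for the rate estimates
#'   (default 5).
#' @return data frame with columns `year`, `ignorome_size`,
#'   `ignorome_fraction`, `cumulative_articles`, `elimination_rate`,
#'   `articles_per_elimination` (`NA` where no gene was eliminated in the
#'   window).
#' @export
shrinkage_timeseries <- function(gene_articles, articles, years = NULL,
                                 window = 5) {
  year_of <- articles$year
  names(year_of) <- articles$article_id
  if (is.null(years))
    years <- seq(min(articles$year), max(articles$year))
  if (window >= length(years))
    stop("window larger than the year range")
  first_year <- vapply(gene_articles, function(ids) {
    ys <- year_of[as.character(ids)]
    if (!length(ys) || all(is.na(ys))) Inf else min(ys, na.rm = TRUE)
  }, numeric(1))
  n <- length(first_year)
  domain_years <- articles$year[articles$journal_class == "domain"]
  size <- vapply(years, function(y) sum(first_year > y), numeric(1))
  cum_art <- vapply(years, function(y) sum(domain_years <= y), numeric(1))
  elim_rate <- rep(NA_real_, length(years))
  art_per_elim <- rep(NA_real_, length(years))
  for (i in seq_along(years)) {
    j <- which(years == years[i] - window)
    if (!length(j)) next
    d_elim <- size[j] - size[i]
    d_art <- cum_art[i] - cum_art[j]
    elim_rate[i] <- d_elim / window
    art_per_elim[i] <- if (d_elim > 0) d_art / d_elim else NA_real_
  }
  data.frame(year = years, ignorome_size = size,
             ignorome_fraction = size / n,
             cumulative_articles = cum_art,
             elimination_rate = elim_rate,
             articles_per_elimination = art_per_elim)
}

#' Compare discovery years of two gene sets
#'
#' One-sided Welch two-sample t-test of the hypothesis that well-studied
#' genes entered sequence databases earlier than ignorome genes.
#'
#' @param well_studied,ignorome numeric vectors of discovery years (NAs are
#'   dropped with a warning).
#' @return list with `median_well_studied`, `median_ignorome`,
#'   `t_statistic`, `p_value` (one-sided, alternative: well-studied
#'   earlier).
#' @export
discovery_year_comparison <- function(well_studied, ignorome) {
  drop_na <- function(x, label) {
    if (anyNA(x)) {
      warning(sum(is.na(x)), " missing years dropped from ", label)
      x <- x[!is.na(x)]
    }
    x
  }
  well_studied <- drop_na(well_studied, "well-studied set")
  ignorome <- drop_na(ignorome, "ignorome set")
  if (length(well_studied) < 2L || length(ignorome) < 2L)
    stop("each group needs at least 2 genes with years")
  tt <- stats::t.test(well_studied, ignorome, alternative = "less",
                      var.equal = FALSE)
  list(median_well_studied = stats::median(well_studied),
       median_ignorome = stats::median(ignorome),
       t_statistic = unname(tt$statistic),
       p_value = tt$p.value)
}
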