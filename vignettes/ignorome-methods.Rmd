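---
title: "Defining tissue ignoromes: models, parameters, and design choices"
author: "ignoromics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining tissue ignoromes: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ignoromics)
```

# The problem

A gene can be intensely and selectively expressed in a tissue — a strong
prior that it matters there — and still have no literature about its
function in that tissue. `ignoromics` quantifies this mismatch. It scores
every gene in an *intensely and selectively expressed* (ISE) set by
combining two fractional ranks, one for expression selectivity and one for
(inverse) literature coverage, and calls the resulting high-scoring,
low-literature subset an *ignorome*. The package then asks what
distinguishes ignorome genes from well-studied ones (coexpression
connectivity, homolog/paralog/domain counts, discovery dates) and uses
reverse complex trait analysis to attach candidate phenotypes to them.

This vignette documents the models and the choices behind them. It states
no empirical claims beyond what the test suite and `scripts/acceptance.R`
compute on simulated data.

# Expression selectivity

## The 2z+8 transform

Arrays are standardized one at a time: `z = (x − x̄)/s` on log2
intensities, then doubled and offset, `2z + 8`. The output has mean 8 and
sd 2 by construction, all but a negligible fraction of values are
positive, and one unit corresponds roughly to a two-fold difference in
mRNA concentration, which keeps downstream fold thresholds interpretable.
`standardize_2z8()` errors on zero-variance input rather than emitting
NaNs. The sd convention (sample, `÷(n−1)`) is configurable; either
convention satisfies the mean-8/sd-2 contract under its own definition.

## The ISE screen

Fold ratios are meaningful on the linear scale, so standardized values are
linearized as `2^x` before ratios are formed; "eight-fold" has no fixed
meaning on a z-score scale. Values below 6 standardized units are clamped
to 6 first (`floor` argument): intensities below that level are background
noise, and ratios into the noise floor would be arbitrary. Both behaviours
are configurable (`floor = NULL`, `linearize = FALSE`).

For each probe, the selectivity score `S` is the linear target-tissue
intensity divided by the mean of the non-target tissues after excluding
the `max_exempt = 5` highest ones, and a probe passes when

* `S > 8` (strict), and
* the per-tissue ratio target/tissue reaches 8 in all but at most 5
  non-target tissues.

The exemption accommodates tissues that legitimately share expression with
the target (for brain: testis, retina, pituitary). Both criteria are
applied conjunctively; the overall-mean and per-tissue rules are distinct
because a probe can pass a trimmed-mean ratio while being broadly
expressed at half-threshold everywhere. Exempting *more* tissues can only
grow the passed set (tested as a property). Probe-level quality filters
(multi-mapping, non-coding, SNP overlap, unassigned) run after an optional
re-annotation override table — mis-annotated probes are the main source of
false ignorome nominations in practice. Duplicate probes per gene keep the
highest `S`, ties broken by smallest probe id so reruns are deterministic.

Relative selectivity `R = S / max(S)` is computed per platform so that
each array technology contributes one gene at `R = 1`, and platforms merge
by gene union keeping the maximal `R`. This makes selectivities comparable
across platforms with different dynamic ranges without cross-platform
normalization.

# Literature estimation

## Name ambiguity

Aliases are classified into `english_word` (case-insensitive membership in
a common-word list), `acronym_multisense` (more than one sense in a
supplied acronym table), and `short` (≤ 3 characters after stripping
hyphens — short enough that retrieval is hopeless). Precedence is
english > acronym > short: a known multi-sense acronym is more informative
than the bare length rule, and three-letter acronyms are common. The
cutoff of 3 and the precedence are configurable; the acronym table is a
static TSV, so sense provenance is the caller's responsibility.

## Informative keywords

For every gene the compound full names (across species variants) are
tokenized; stopwords ("protein", "factor", "family", "binding", …), pure
numbers, and words occurring more than 20 times in the whole collection
are dropped; the lowest-frequency surviving constituent becomes the
gene's keyword (ties: longest word, then lexicographic — rarer and longer
means more specific). A candidate equal to one of the gene's own ambiguous
aliases is skipped, since it could not disambiguate anything. Queries
conjoin each ambiguous alias with the keyword (`NSE[TIAB] AND
enolase[TIAB]`); ambiguous aliases without a keyword are dropped from the
query with a message rather than silently polluting counts.

## Domain keywords and the query engine

Domain (e.g. neuroscience) keywords are MeSH terms with document frequency
strictly above 20% in a domain corpus and strictly below 1% in a contrast
corpus, plus a fixed generic list (bundled: 26 terms, trailing `*` =
prefix wildcard). Document frequency — the fraction of articles carrying
the term — is used rather than raw term counts; the thresholds are
configurable.

The local evaluator defines the matching contract precisely, because no
remote search engine's tokenization can be replicated: alias terms match
case-insensitive whole tokens in title+abstract (multiword aliases as
consecutive token phrases; hyphens and punctuation are token separators),
domain keywords match title/abstract tokens or MeSH entries, the species
clause matches article species metadata, and `term*` matches token
prefixes (`hippocamp*` → hippocampus/hippocampal, never "hippo"). Articles
linked to more than 50 distinct genes are flagged noisy — the signature of
genome-wide surveys whose mentions carry no functional information — and
excluded by default. The serialized query string is byte-stable; tests pin
it. On corpora of a few hundred articles the indexed evaluator is verified
against an independent naive per-article scan.

# The ignorome score

Over the `N` ISE genes, each gene gets `f_sel = |{h : R_h ≤ R_g}|/N` and
`f_lit = |{h : L_h ≥ L_g}|/N`, and the score is the harmonic mean
`I = 2·f_sel·f_lit/(f_sel + f_lit)`. Comparisons are inclusive and count
the gene itself, so both fractions are ≥ 1/N and the harmonic mean is
always defined; ties share the same value. The orientation is chosen so
that the jointly extreme gene — uniquely most selective, uniquely least
studied — scores exactly 1, and a maximally studied gene scores
`≈ 2/N`: 0 means relatively well known, 1 relatively unknown. (Reading
the two fractions as "strictly higher selectivity" and "strictly less
literature" would send *both* archetypes to 0 and break that range; the
inclusive-rank orientation is the one consistent with the stated 0→1
semantics.) The harmonic mean punishes imbalance: a gene must be both
selective and neglected to score high. Properties tested: scores in
(0, 1], the min/max sandwich around the two fractions, monotonicity in
each input, and permutation invariance.

The core ignorome is `L ≤ 1` (default; `call_core(max_articles = 5)`
yields the defensible looser set) and the absolute ignorome `L = 0`.

## Shrinkage time series

For each year, `shrinkage_timeseries()` counts genes whose qualifying
articles all post-date that year (the ignorome as of then), cumulative
domain articles, a trailing-window elimination rate (window default
5 years, configurable rather than hard-coding period averages), and
articles spent per eliminated gene (`NA` when nothing was eliminated,
avoiding a spurious ∞). The series is non-increasing by construction
since a gene's first article date is fixed.

Discovery-year comparisons use a one-sided Welch *t*-test (unequal
variances; the safer default when group sizes and spreads differ) with
the alternative "well-studied genes were discovered earlier".

# Comparative analyses

Connectivity profiles count covariates above each |r| ∈ {0.75, 0.80,
0.85, 0.90, 0.95} after removing genes with mean expression below 8
standardized units, SNP-overlap genes, the target itself, and
same-chromosome genes within 5 Mb (linkage alone produces high local
correlations in recombinant-inbred panels). "Top covariates" for
enrichment are ranked by |r| (configurable to signed r). Correlations of
structural features with literature use `log10(L + 1)` — the offset
handles zero-literature genes, and base 10 makes the OLS slope read as
"features per 10-fold increase in literature". Enrichment uses the
upper-tail hypergeometric `P(X ≥ k)` with Benjamini–Hochberg adjustment
("FDR-corrected" without a named procedure is taken as BH); the tail is
verified against exhaustive enumeration for small urns.

# Reverse complex trait analysis

The mapping statistic is the marker-regression likelihood ratio,
`LRS = n·ln(RSS₀/RSS₁)` with allele codes B = −1, D = +1 and pairwise
deletion of missing data; `LRS = 4.61·LOD`. This is a deliberate
simplification — no kinship correction, no interval mapping, no
permutation thresholds — adequate for marker-dense panels and verified to
be null-calibrated against χ²₁ at n = 30 strains. Monomorphic markers get
LRS 0 with a warning; perfect fits (noiseless simulations) are capped at
46.05 (~LOD 10) and flagged, since the raw ratio is unbounded.

A gene is *cis*-modulated when its peak LRS > 12 falls within ±5 Mb of
the gene (the same window the phenome scan uses; gene position = annotated
midpoint), mean expression > 7 units, and it carries a moderate/high
impact variant — all strict inequalities. The phenome scan restricts each
phenotype's scan to markers within ±5 Mb of the gene and returns traits
with in-window LRS > 10 plus the trait–expression Pearson correlation,
the local equivalent of a position-filtered phenome query.

# The synthetic-data generators

The simulators define the study conditions; their defaults are fixed
realistic choices, not tuning knobs.

* **Expression**: per-gene baselines U(6, 11) on log2, planted genes get
  `+log2(fold)` in the target tissue (default fold 16), Gaussian log2
  noise (default sd 0.25), emitted on the linear scale per platform. With
  zero noise planted ratios are exactly `fold`. The pipeline default
  plants 12 selective genes in 200 (6%): real ISE sets are a few percent
  of a transcriptome, and at implausibly high planted fractions the
  planted subpopulation itself inflates the target array's variance under
  per-array standardization, compressing marginal planted genes below the
  8-fold screen — a property of the transform, not a detector failure.
* **Literature**: gene ranks get Zipf weights `r^(−s)` (default exponent
  1.0, truncated at the gene count — the simplest law matching the
  observed rank–frequency skew of gene literatures); each ordinary
  article links to one weighted-sampled gene, carries a uniform year, a
  domain/non-domain journal class, class-specific MeSH, species metadata,
  and template title/abstract text embedding the gene's alias. Noisy
  articles (default 2%) link to 51–80 genes. Optionally a share of
  articles mention a planted ambiguous alias as plain prose without a
  link, giving ground truth for disambiguation tests. Template text
  supports whole-token query evaluation, not NLP realism.
* **Nomenclature**: synthetic symbols, compound full names with one rare
  informative constituent, 0–3 harmless aliases, and planted ambiguous
  aliases cycling through the three categories; planted acronyms are
  emitted in the acronym-sense table with ≥ 2 senses. The detector
  recovers planted categories deterministically.
* **Strain panel**: per-chromosome Markov genotypes with switch
  probability 0.3 between adjacent markers (mimicking RI-strain block
  structure), default map of 1 Mb-spaced markers in 20-marker
  chromosomes. Effects are additive allele effects `a` (trait =
  `baseline + a·code + N(0, noise_sd)`), the standard QTL convention in
  which the planted B-vs-D line difference is `2a`; with the default
  `noise_sd = 1`, `a` is in within-strain SD units. Planted-eQTL genes
  sit at their marker with high-impact variants.
* **Annotation tables**: ortholog counts bounded by 21 species,
  paralog/domain counts, discovery years; a Gaussian-copula parameter
  couples them to a supplied literature vector (discovery year with
  opposite sign — more literature, earlier discovery), 0 = independent.

All randomness flows from one master seed through named substreams, so
generating an additional table never perturbs existing ones and
identical calls are byte-identical.

What the simulations do **not** emulate: realistic linkage maps and
population structure, MeSH ontology structure, real tokenizer quirks of
remote search engines, annotation error, or the actual parameter values of
any real atlas/corpus — the generators' laws are structural stand-ins.
Passing tests therefore demonstrate correctness of the machinery and its
calibration under the stated laws, not performance on real data.

# Numerical choices and degenerate inputs

* Strict inequalities at every published threshold (8-fold, >20
  occurrences, 20%/1%, >50 genes, LRS >12/>10, expression >7).
* Zero-variance arrays, empty gene tables, empty corpora, genes with no
  usable names, monomorphic markers, windows without markers: explicit
  errors or warnings, never silent NaN.
* Tie-breaks (duplicate probes, keyword candidates, equal correlations)
  are lexicographic after the scientific criterion, making all outputs
  order-independent and reproducible.
* Problem sizes in the test suite (panels of 10²–10³ genes, corpora of
  150–10,000 articles, 200-replicate power estimates, 500-trait null
  calibrations) were chosen as the smallest sizes at which the measured
  properties are stable across seeds.

# Known limitations

* Literature counts depend entirely on the supplied corpus and link
  table; the package recomputes noisy-article lists and keyword sets from
  whatever snapshot is provided rather than shipping frozen lists.
* The query evaluator's semantics are a local contract; a remote search
  engine will tokenize differently, so live counts will differ from local
  ones in edge cases (an optional verbatim submission of the serialized
  query is the intended bridge).
* Marker regression without kinship or interval mapping overstates
  precision near sparse markers; printed LRS values from heavier mappers
  are not comparable beyond threshold behaviour.
* The harmonic-mean score ranks genes *within* an ISE set; scores are not
  comparable across sets of different size or literature depth.

```{r session}
sessionInfo()
```
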