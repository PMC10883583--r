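---
title: "Methods: constituent-level super-enhancer fingerprinting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constituent-level super-enhancer fingerprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedure implemented by
`SEfingerprint`, its assumptions, the tunable parameters, the numerical
choices, and what the synthetic validation does and does not demonstrate.

## Input model

The package assumes a panel of cell lines grouped into cancer types, each
profiled by H3K27Ac ChIP-seq in one or more replicates, with per-sample
super-enhancer (SE) and constituent-enhancer (CE) calls produced upstream
(peak calling and ROSE-style stitching are out of scope). Activity is the
total read coverage within a region. Internally regions live in `GRanges`
(1-based, closed intervals, the Bioconductor convention); BED input/output
converts coordinates at the boundary. Strand is ignored for SEs and CEs —
H3K27Ac is unstranded — and used only to orient promoter exclusion windows.

## Unified region lists

Per-sample regions are merged into one cross-sample candidate list with
`merge_regions()`: two regions merge when their intersection covers at
least `min_overlap` (default 0.25) of a reference width, and the relation
is closed transitively so the output partitions the input. Closure is the
only order-independent choice: any "merge as you go" scheme depends on
input order, while single-linkage closure over the original pairwise
overlaps is permutation-invariant and idempotent (both properties are
tested, together with equivalence to a brute-force union–find oracle).

The reference width is a genuine free choice; the fraction of the
*smaller* region is the default because it is symmetric and maximizes
merging, and because the merged lists are empirically insensitive to the
cutoff in this range. `denom = "reciprocal"` (fraction of the larger
region, i.e. both regions must be covered) is stricter; `"either"` is the
same rule as `"smaller"` stated per-region and is kept as an alias. Note
one subtlety of the smaller-width rule: in a chain like
`[0,100) – [70,200) – [170,300)` the second pair shares 30 bp against a
smaller width of 130, a fraction of 0.23, so at a 0.25 cutoff the chain
does *not* fully merge; chains merge only through pairs that individually
clear the cutoff.

Each unified CE is assigned to the SE with which it shares the most bases
(`assign_ce_to_se()`); ties go deterministically to the SE with the
smaller start, and CEs touching no SE are flagged unassigned.

## Activity matrix

`aggregate_replicates()` sums replicate columns (sums preserve count
semantics for the size-factor model; `fun = "mean"` is available).
`rle_normalize()` computes median-of-ratios (RLE) size factors: for column
$j$, $s_j = \operatorname{median}_r \, m_{rj} / g_r$ over rows $r$ whose
values are positive in every column, where $g_r$ is the row geometric
mean. The median of the ratios is taken on the log scale (geometric
interpolation between the two central ratios when the count is even),
matching the reference RLE implementation; tests verify agreement with an
independent oracle and with `DESeq2::estimateSizeFactorsForMatrix()`.
Because size factors are referenced to the row geometric means, the
normalized matrix is invariant under per-column depth scaling exactly when
the scale vector has geometric mean 1; a global depth change rescales the
common reference, which is immaterial downstream (the mixture model only
sees relative structure).

Normalization is computed over the full (genome-wide) enhancer set, while
per-CE modeling downstream is restricted to CEs passing the contribution
filter — the wider set stabilizes the size factors. Zeros are imputed per
cell line as half the minimum positive value of that column
(`impute_zeros()`), after recording the zero mask so pre-imputation zeros
can be excluded from prior fitting. The log2 transform follows imputation,
with no pseudocount (all values are positive by then).

`se_contribution_filter()` drops lowly-active CEs: a CE passes in a cell
line when it contributes strictly more than 3% of its SE's total coverage
there, and is retained if it passes in at least one cell line. The
per-cell-line scope (rather than a pooled ratio) keeps a CE that is a
major contributor in even a single cancer; the filter's intent is to
remove coverage noise, not rare specificity. `activity_per_kb()`
(signal / width × 1000) supports width-adjusted activity comparisons,
since enhancer width reflects the complexity of the locus more than its
strength and unadjusted coverage over-weights wide CEs.

## Per-CE mixture model

Each CE's log2 activities across cell lines are modeled as
$\pi_i N(\mu_i, \sigma_i^2) + \pi_a N(\mu_a, \sigma_a^2)$ and fit by EM
(`em_fit()`), stopping when the log-likelihood changes by at most `tol`
(default 1e-8) or at `max_iter` (default 1000; hitting it is a warning,
not an error). The E-step is computed in log space, and the trace is
asserted non-decreasing on every fit in the tests.

**Priors as initialization.** Genome-wide priors are fit per cell line
(excluding pre-imputation zeros), the higher-mean component labeled
active, and the means/SDs averaged unweighted across cell lines
(`fit_global_priors()`). These priors initialize each per-CE EM with equal
weights. Implementing the priors as initialization (rather than as a MAP
penalty on the per-CE likelihood) is the minimal reading of "applied as
priors"; it leaves each CE free to place its own boundary, which is the
point of per-CE modeling. The per-cell-line global fit itself is
initialized deterministically at the 25th/75th percentiles, so the whole
pipeline is deterministic — no random restarts by default.

**Degeneracy.** A per-CE fit is declared degenerate when the data cannot
support two components: fewer than two distinct values; a component
variance below the floor 1e-3 (log2 units squared, preventing singular
likelihoods — the floor triggers a fallback rather than a clamped fit, so
the monotone trace is never broken); a component claiming fewer than one
expected observation ($\min(\pi) n < 1$); or post-fit means closer than
half the pooled SD. Degenerate CEs are exactly the uniformly
active/inactive class: each cell line is assigned to whichever *global*
prior mean is nearer its value (`assign_states()`), which resolves
pan-cancer-active and never-active CEs without forcing a spurious split.

**State rule.** For clean fits a cell line is active iff its posterior
probability of the active component is strictly greater than 0.5; a
posterior of exactly 0.5 is inactive. With equal SDs and weights the
posterior-0.5 boundary is analytically the midpoint of the means (tested);
in general `activity_cutoff()` locates it between the two means.
`classify_ce()` then gives the three-way class per CE: `all_active`,
`all_inactive`, or `mixed`.

## Specificity and the prevalence threshold

`compute_prevalence()` gives each CE's active prevalence (fraction of
active cell lines) and its complement. The threshold below which a
prevalence counts as "specific" is selected by `select_threshold()`:

* cutoff grid 0 to 0.5 in steps of 0.01 (0.5 is the natural ceiling — above
  it "minority" loses meaning);
* at each cutoff, cell lines are clustered on the log2 activities of the
  CEs with active prevalence strictly below the cutoff — Euclidean
  distance, Ward linkage (`ward.D2`), tree cut at k = number of distinct
  cancer types; all three are configurable since no single clustering
  configuration is canonical for this data;
* the clustering is scored against the true cancer-type labels with the
  variation of information, VI = H(A) + H(B) − 2 I(A;B), in natural-log
  units (the base cancels after scaling). A cutoff selecting zero CEs
  scores the VI of the single-cluster partition, the maximally
  uninformative clustering, so the curve is defined everywhere;
* both axes are min–max scaled to [0, 1], the VI curve is smoothed with a
  local quadratic (Savitzky–Golay) filter over 11 grid points, and the
  selected threshold is the largest cutoff at which the smoothed slope is
  still ≤ −1. On a scaled plot, slope −1 is where one more unit of
  prevalence stops buying a unit of clustering quality — the inflection
  balancing specificity against identity encoding. If the slope never
  reaches −1 (e.g. a flat curve), the fallback picks the cutoff minimizing
  scaled VI + scaled cutoff (closest to the ideal corner) with a warning.

The same selected threshold applies to both the active and the inactive
prevalence scans. Calls are strict (`prevalence < threshold`) and require
a non-empty minority cell set, i.e. prevalence strictly above 0: a CE with
prevalence exactly 0 has no carrier cells and belongs to the uniform
classes, not the specific table. `call_cancer_specific()` promotes a
cell-specific CE to cancer-specific for every cancer with at least two
cell lines carrying the minority state, or a single-cell-line cancer whose
line carries it; calls attaching to no cancer stay cell-specific only.
`summarize_cancer_specific_se()` lists each SE once per attached cancer
and mode, and categorizes SEs overall as `active_only`, `inactive_only`,
`both`, or `none`.

## Fingerprint database

`build_fingerprint_db()` bundles regions, the CE→SE map, states, calls,
summaries, the sample sheet and parameters into one integrity-checked
object; dangling references are rejected with the offending ids. Storage
is a plain JSON + TSV bundle with deterministic field order — identical
inputs serialize byte-identically — chosen over a binary store for
inspectability and language portability. Queries cover cancer type, cell
line, gene and location. The gene rule is an explicit stand-in for "any
nearby SE": an SE within a configurable window (default 50 kb, a common
enhancer–promoter interaction scale) of the gene's TSS, or overlapping the
gene body when gene bounds are provided.

## Synthetic data: what it emulates and what it does not

`simulation_config()` defaults describe the study conditions the package
is validated under: 10 cancers × 3 cell lines × 2 replicates, 200 SEs with
1 + Poisson(4) CEs each (widths 800–3000 bp, gaps 500–2000 bp, SEs 200 kb
apart), log2 activity components N(9, 1) active and N(3, 1) inactive, 30%
of CEs planted cancer-specific-active and 10% cancer-specific-inactive at
target minority prevalence 0.15 (the planted cancer's cells plus sporadic
single extras in *distinct* other cancers, so the planted cancer is the
only coherent signal), 1% each uniformly active/inactive, background CEs
active per cell line with probability 0.5, replicate noise SD 0.25 (log2),
lognormal per-sample depth factors (sdlog 0.3), 5% dropout among inactive
occurrences, and per-sample boundary jitter with SD 5% of region width.
Counts are rounded continuous signal rather than Poisson draws, keeping
closed-form expectations for the size-factor recovery checks. Generators
are pure functions of (config, seed) and restore the caller's RNG state.

The validation runs use: the default design (~1000 CEs × 30 cell lines)
for threshold selection and specificity recovery; a 30-cancer ×
2-cell-line design (~500 CEs × 60 cell lines) for state-call accuracy and
component recovery; and ≤ 200-interval instances for the merge oracle.
All complete in seconds.

What passing these tests shows: the estimators recover the structure they
model — well-separated bimodal activities, coherent planted specificity,
depth variation, dropout — and every oracle-checkable primitive (merge,
RLE, VI, EM monotonicity) is exact. What they do not show: performance
under ChIP-seq realities the generator omits — GC and mappability biases,
input-dependent background, copy-number-driven coverage, correlated
replicates, partially overlapping CE boundaries across samples, component
separations much below 3 pooled SDs, and cancers whose cell lines are
epigenomically heterogeneous. On real panels the active/inactive
separation per CE is the binding assumption; CEs violating bimodality
land in the degenerate class and inherit the global consensus, which is
conservative but can mask genuinely graded activity.

## Known limitations

* The selected prevalence threshold depends on the clustering
  configuration behind the VI curve; it is data- and configuration-
  dependent, not a universal constant.
* Cancers represented by a single cell line inherit that line's
  specificity wholesale; such calls confound cell- and cancer-specific
  signal by construction.
* Replicate-level modeling, >2 mixture components, and non-Gaussian
  activity distributions are out of scope.
* The per-CE EM is deterministic given the prior initialization and
  performs no random restarts; a likelihood with well-separated local
  optima could in principle trap it, though the global-prior start makes
  that unlikely for the bimodal structure modeled here.
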