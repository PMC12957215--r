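---
title: "Stage-resolved immune scoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-resolved immune scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cldimmune)
```

`cldimmune` quantifies macrophage and T-cell programs across the stages of
chronic liver disease (healthy liver, MASH, cirrhosis, HCC) and links them to
prognosis. This vignette explains each statistical component, the parameters
that matter, what the synthetic-data generators do and do not emulate, and the
design decisions taken where the methodology was genuinely open.

## 1. Quality control and signature genes

`qc_filter()` keeps cells with a mitochondrial fraction strictly below 10%,
between 200 and 4000 detected genes (both bounds inclusive), and then genes
detected in strictly more than 3 cells. The boundary conventions are
deliberate and tested: a cell at exactly 10% mitochondrial content is removed,
a cell with exactly 200 or 4000 detected genes is kept, a gene seen in exactly
3 cells is removed. The per-cell detected-gene count is treated as a recorded
QC metric: it is not recomputed after the gene filter, which makes the filter
idempotent (filtering twice equals filtering once).

`de_stats()` computes one-vs-rest differential expression per cluster on
counts-per-10k normalized expression. The test is the Wilcoxon rank-sum with
the large-sample normal approximation, tie correction and continuity
correction (the same formulae as `stats::wilcox.test(exact = FALSE)`),
vectorized over genes; the statistic is checked against brute-force pair
counting in the tests. `avg_log2FC` is `log2((m1 + 1)/(m2 + 1))` on normalized
means — the common one-vs-rest convention — and p-values are
Benjamini–Hochberg adjusted across genes within each cluster.

Cluster specificity uses an entropy difference. For a gene with per-cluster
mean expression \(m_1,\dots,m_K\), let \(p_k = (m_k+\varepsilon)/\sum_j (m_j+\varepsilon)\);
the score is

\[ D \;=\; \log_2 K - H(p), \qquad H(p) = -\sum_k p_k \log_2 p_k . \]

\(D = 0\) for a uniform profile and \(\log_2 K\) for a one-hot profile, so
larger values mean more cluster-specific expression. The published description
of the entropy-based gene selection does not print its formula; \(D\) is this
package's operational definition, chosen so that the direction (greater =
more specific) matches the published usage. \(\varepsilon\) is \(10^{-9}\)
relative to the profile total — small enough that boundary examples evaluate
at their \(\varepsilon \to 0\) limits to within \(10^{-6}\) bits.

`select_signatures()` applies the class rules with strict inequalities exactly
as printed in the underlying methodology: macrophage signatures require
`p_adj < 0.01`, `pct1 > 0.5`, `pct2 < 0.5` and `avg_log2FC > 1`; T-cell
signatures require `p_adj < 0.01` and `avg_log2FC > 0.5` with no
detection-fraction rule. The hepatocyte/housekeeping contaminants ALB and
ATP5F1E are excluded by default, survivors are ranked by \(D\), and an
optional `min_pct` prefilter is exposed for marker discovery workflows where
the class thresholds do not already supersede it.

## 2. Cell-state scoring by recovery-curve AUC

`build_rankings()` orders each cell's genes by decreasing expression;
`auc_score()` integrates the recovery curve (cumulative count of gene-set
members versus rank position) over the top 5% of the ranking and normalizes
by the maximum achievable area, so a score of 1 is attainable and all scores
lie in [0, 1]. The window fraction of 0.05 is the reference default for this
family of scores; it is exposed as `top_fraction`. Being rank-based, scores
are invariant to any strictly monotone transform of a cell's expression.

Ties are broken by a random permutation drawn once from `tie_seed` and keyed
to gene *identities* (assigned over the lexicographically sorted gene names),
not storage positions. This preserves exchangeability without biasing toward
input order, and makes scores invariant to permuting the rows of the matrix.

A panel of editable curated state sets (M1, M2, angiogenesis, phagocytosis;
naive, activation, cytotoxicity, exhaustion) ships as a GMT fixture in
`system.file("extdata", "cell_state_sets.gmt", package = "cldimmune")`; it is
a convenience default assembled from canonical markers of each program, not a
frozen reference.

## 3. Cohort scores: ES, IS, CA, Mscore, Tscore

`ssgsea_es()` is the single-sample GSEA statistic: per sample, genes are
ranked by expression and the score sums, over ranking positions, the
difference between the weighted in-set ECDF (weights \(|r|^\alpha\),
\(\alpha = 0.25\)) and the unweighted out-set ECDF. Raw scores are invariant
to per-sample monotone transforms; they are then min–max rescaled across the
cohort to \([\varepsilon, 1]\) with \(\varepsilon = 0.01\).

The composite scores correct a subtype signature's enrichment (ES) for
overall immune abundance (IS) and, for T cells, for cytotoxic T-cell
abundance (CA):

\[ \mathrm{Mscore} = \frac{ES}{IS}, \qquad
   \mathrm{Tscore} = \frac{ES \cdot CA}{IS}. \]

Three conventions are this package's own, because the source methodology
names the ingredients without fixing them:

* **IS** is operationalized as the mean rescaled enrichment over a
  user-supplied panel of immune cell-type signature sets. Any strictly
  positive, monotone proxy of immune abundance serves the correction; the
  panel is configurable rather than tied to one deconvolution tool.
* **Rescaling before forming ratios** (with the \(\varepsilon\) floor)
  guarantees the ratios are defined and strictly positive; scores are
  therefore comparable within one cohort only, and outputs should not be
  compared across cohorts.
* \(\alpha = 0.25\) is the reference exponent of the ssGSEA family.

## 4. Survival analysis

`stratify_and_test()` splits samples at the cohort median of a score (ties to
the low group; a fixed cutpoint can be supplied instead — the median is the
default because no cutpoint rule is published for the score-based KM
contrasts), computes Kaplan–Meier curves and the log-rank test, and reports
the high-vs-low hazard ratio from a Cox proportional-hazards fit with age as
a covariate. "Correcting for patient age" is interpreted as exactly that
covariate adjustment — the standard operationalization alongside a KM
display. `univariate_screen()` fits one Cox model per gene on standardized
expression, BH-adjusts the Wald p-values and flags risk versus protective
directions. Penalized multigene model construction is intentionally out of
scope; the univariate screen plus score stratification is the supported
surface.

## 5. Composition with BCa bootstrap intervals

`bca_ci()` implements the bias-corrected and accelerated bootstrap: the bias
correction \(z_0\) is estimated from the fraction of bootstrap statistics
below the point estimate and the acceleration \(a\) from jackknife skewness;
the adjusted percentile endpoints are

\[ \alpha_{lo/hi} = \Phi\!\left(z_0 + \frac{z_0 + z_{\alpha}}{1 - a (z_0 + z_{\alpha})}\right). \]

Because cell-type proportions are discrete statistics, ties of bootstrap
replicates with the point estimate are counted with half weight in \(z_0\)
(the midrank convention); with the plain convention the tie mass biases
\(z_0\) and degrades coverage for proportions. Setting `z0 = 0, accel = 0`
reduces the interval exactly to the percentile interval, which the tests use
as an oracle; `boot::boot.ci(type = "bca")` is the independent cross-check on
continuous statistics. The resampling unit is the cell within its stage,
matching data pooled per stage; `stage_contrast()` resamples the two stages
independently and uses a pooled analytic jackknife for the acceleration.
Defaults are 1000 resamples and two-sided 95% intervals, with a mandatory
seed.

## 6. FISH quantification

`segment_channel()` thresholds a channel (Otsu's method by default — the
published pipeline's exact HSV thresholds are not printed, so the threshold
is a required, defaulted parameter), labels 8-connected components, discards
components below `min_component_px` (default 5 px) and returns
intensity-weighted centroids. The module ingests channel-separated rasters;
per-channel intensity thresholding plays the role that HSV masking plays for
RGB micrograph exports, and is strictly more general.

`call_cells()` types each nucleus by the marker spots within its class
radius: "within a diameter of 20 µm" (macrophages) and 10 µm (T cells) is
interpreted as a disc of radius diameter/2 centered on the nucleus centroid,
boundary inclusive. When both a subtype and a lineage marker are assigned,
the subtype wins (a Clec4f + Spp1 nucleus is an SPP1⁺ macrophage, not a
generic macrophage) and the nucleus is flagged double-positive; conflicts
among subtype markers resolve to the nearest one, and every assignment is
retained for audit. Tumor calls come only from the tumor channel. The pixel
size must be supplied; magnification is never inferred.

`distance_report()` computes the full pairwise distance matrix in
micrometres, each immune call's nearest-tumor distance, per-type medians, and
double-positive pair distances (0 when both markers share a nucleus).

## 7. What the generators emulate — and what they do not

The three generators define the conditions under which every downstream claim
is tested; their defaults are fixed, not tuned per run.

**Single-cell counts** (`simulate_sc()`): negative-binomial counts
(variance \(\mu + \mu^2/\phi\), default dispersion \(\phi = 0.5\)) with a
log-normal library-size factor (\(\sigma = 0.3\)), log-normal baseline gene
abundances, and disjoint planted marker sets whose means are multiplied by
\(2^{\mathrm{log2FC}}\) (default 8×) within their own type. Marker genes are
assigned a fixed moderate baseline weight so their out-of-type detection
fraction sits below one half — without this the `pct2 < 0.5` rule would be
unsatisfiable for high-abundance genes regardless of method quality. Default
scale: 3 types × 200 cells × 1000 genes, 10 markers/type, mean library 5000.
Not emulated: doublets, ambient RNA, batch effects. Passing tests therefore
demonstrate correctness of the statistics, not robustness to droplet
artifacts.

**Survival cohort** (`simulate_cohort()`): per sample, a standardized
signature burden \(z \sim N(0,1)\) and an immune-abundance latent
\(u \sim N(0,1)\). Signature genes respond to \(z + u\) (in bulk tissue a
subtype signature is confounded by total immune infiltration — precisely the
bias the IS correction addresses), immune-panel genes to \(u\), the Tc set to
its own latent. Effects are 1.5 log2 units per SD against residual noise of
SD 1. Survival is exponential with hazard
\(h_0 \cdot \mathrm{HR}^{z}\) (defaults \(h_0 = 0.1\), HR = 2 per SD) and
independent exponential censoring tuned numerically to a 30% expected
censored fraction; ages are uniform on 30–80 and independent of hazard. This
confounded design is what makes the correction measurable: across seeds the
Spearman correlation with the true burden is ≈ 0.9 for Mscore versus ≈ 0.7
for uncorrected ES. The exponential model keeps every recovery check
closed-form; non-proportional hazards and informative censoring are not
emulated.

**FISH scenes** (`simulate_fish()`): nuclei, spots and tumor cells are
rendered as filled discs with Gaussian pixel noise of SD
`noise_level` × max intensity; ground truth (types and nearest-tumor
distances) is computed analytically from the configuration, never from the
rendering, so at zero noise the segmentation oracle is exact. Point-spread
functions, z-stacks and autofluorescence are not modeled.

## 8. Numerical choices and problem sizes

Tolerances used by the test suite follow the quantity's nature: oracle
equivalences at 1e-12 (AUC, ssGSEA) and 1e-9 (distances); analytic limits at
1e-6 where an \(\varepsilon\) enters and 1e-12 otherwise. Statistical checks
run at sizes chosen to make Monte-Carlo error small relative to the assertion
band: 500 simulations for BCa coverage (n = 200, p = 0.3) and log-rank
type-I error, 50 seeds at n = 300 for hazard-ratio recovery, 20 seeds for
marker-recovery rates, 10 seeds for null p-value uniformity. Degenerate
inputs are handled explicitly: all-zero entropy profiles return 0,
constant genes get p = 1 and log-fold-change 0, degenerate bootstrap
distributions collapse to a point interval with a warning, empty masks yield
empty component tables, and an all-cells-removed QC result warns rather than
errors.

## 9. Known limitations

* Cohort scores are cohort-relative; there is no cross-cohort calibration.
* IS depends on the supplied immune panel; a poorly chosen panel weakens the
  correction (the package does not ship a reference deconvolution).
* The Wilcoxon DE p-values use the normal approximation; for very small
  clusters (a handful of cells) exact tests would differ.
* FISH typing assumes channel-separated input and a known pixel size; 3-D
  stacks and probe chemistry are out of scope.
* The entropy-difference formula is a declared stand-in for an unpublished
  reference implementation; rankings, not absolute values, are what the
  selection uses.
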