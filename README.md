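# cldimmune

Stage-resolved immune scoring and spatial quantification for chronic liver
disease (CLD).

Chronic liver disease progresses from healthy liver through metabolic
dysfunction-associated steatohepatitis (MASH) and cirrhosis to hepatocellular
carcinoma (HCC), and macrophage subtypes (C1QA⁺ Mac, CXCL3⁺/CXCL10⁺ Mac,
scar-associated TREM2⁺ macrophages, SPP1⁺ Mac) shift with stage alongside
cytotoxic T cells (Tc). `cldimmune` is for computational biologists who want
to quantify those programs from labeled single-cell count matrices, link them
to prognosis in bulk cohorts, and validate them spatially in FISH
micrographs. It implements:

* **QC and signature genes** — the cell filters (mito < 10%, 200–4000
  detected genes, genes in > 3 cells), one-vs-rest Wilcoxon differential
  expression with detection fractions and `avg_log2FC`, and
  entropy-difference specificity ranking
  (`D = log2 K − H(p)`, in bits) for marker selection.
* **Cell-state scoring** — per-cell recovery-curve AUC of curated gene sets
  (M1/M2/angiogenesis/phagocytosis, naive/activation/cytotoxicity/exhaustion)
  over the top 5% of each cell's ranking.
* **Cohort scores** — single-sample GSEA enrichment (ES) corrected by an
  immune-abundance score (IS) and cytotoxic T-cell abundance (CA):
  `Mscore = ES/IS`, `Tscore = ES·CA/IS`.
* **Survival** — Kaplan–Meier stratification at a score cutpoint, log-rank
  tests, age-adjusted Cox hazard ratios, and a univariate Cox screen over
  signature genes.
* **Composition** — cell-type proportions per stage with bias-corrected and
  accelerated (BCa) bootstrap confidence intervals and stage contrasts.
* **FISH quantification** — channel segmentation (Otsu threshold,
  8-connected components, size filter), radius-based cell typing (macrophage
  markers within a 20 µm diameter of the nucleus, T-cell markers 10 µm),
  pairwise and nearest-tumor-cell distances, double-positive pairs.
* **Synthetic data** — generators for all three input classes
  (negative-binomial single-cell counts with planted markers, survival
  cohorts with a planted hazard tied to signature burden, FISH scenes with
  exact geometry) so the whole pipeline is testable with known ground truth.

## Worked example

```r
library(cldimmune)

# 1. synthetic single-cell data with planted markers -> signature genes
sc  <- simulate_sc(sc_sim_config(seed = 42))
sc  <- qc_filter(sc, min_genes = 0, max_genes = Inf)
sig <- select_signatures(de_stats(sc), cell_class = "macrophage")
str(sig[1])
#> List of 1
#>  $ type1: chr [1:10] "g0008" "g0003" "g0007" "g0005" ...
```

The ten genes planted as `type1` markers are recovered, ordered by decreasing
entropy-difference specificity.

```r
# 2. bulk cohort with a planted prognostic burden -> Mscore -> survival
co <- simulate_cohort(cohort_sim_config(seed = 42))
gs <- attr(co, "truth")$gene_sets
scores <- score_cohort(co, gs$signature, gs$immune, gs$tc)
head(scores[, c("sample", "ES", "IS", "Mscore", "Tscore")], 3)
#>   sample        ES        IS    Mscore    Tscore
#> 1  s0001 0.7455504 0.5252807 1.4193372 0.6713871
#> 2  s0002 0.6021721 0.7102802 0.8477952 0.4779145
#> 3  s0003 0.6214704 0.5607957 1.1081939 0.7649314

res <- stratify_and_test(co, setNames(scores$Mscore, scores$sample))
res
#> survival_result: high/low split at 0.9988 (median cutpoint)
#>   log-rank chisq = 31.393, p = 2.11e-08
#>   age-adjusted HR (high vs low) = 2.145 [1.634, 2.817]
```

Samples above the cohort-median Mscore carry roughly twice the death hazard
of the low group after age adjustment — recovering the hazard ratio of 2 per
burden SD planted by the generator — and the Kaplan–Meier curves separate at
p ≈ 2×10⁻⁸ by the log-rank test.

```r
# 3. composition contrast with BCa intervals
scc <- matrix(c(200, 300, 60, 440), 2, byrow = TRUE,
              dimnames = list(c("HCC", "healthy"), NULL))
cells <- simulate_sc(sc_sim_config(n_types = 2, stage_cell_counts = scc, seed = 7))
stage_contrast(cells, "HCC", "healthy", "type1", seed = 1)
#> stage_contrast: P(type1 | HCC) - P(type1 | healthy) = 0.2800 [0.2280, 0.3260] (95% BCa)
```

The planted enrichment (40% vs 12% of cells) is estimated at +0.28 with a
95% BCa interval that excludes zero.

For FISH scenes, `simulate_fish()` → `fish_quantify()` segments every
channel, types nuclei by their marker spots and reports nearest-tumor-cell
distance medians per cell type; see `?fish_quantify` and the vignette in
`vignettes/stage-resolved-immune-scoring.Rmd` for the full model
descriptions, parameter defaults and design rationale.

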