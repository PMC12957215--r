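# Cell quality control and cluster signature-gene derivation:
# Wilcoxon one-vs-rest DE, pct thresholds, and entropy-difference specificity.

#' Quality-control filter for labeled single-cell data
#'
#' Retains cells whose mitochondrial fraction is strictly below `max_mito` and
#' whose detected-gene count lies in `[min_genes, max_genes]` (both ends
#' inclusive), then retains genes detected in strictly more than
#' `min_cells_per_gene` of the surviving cells. Cell and gene order are
#' preserved. The per-cell `n_detected_genes` metadata is the recorded QC
#' metric and is not recomputed after gene filtering, so the filter is
#' idempotent.
#'
#' @param expr a [labeled_expression()].
#' @param min_genes,max_genes inclusive bounds on detected genes per cell.
#' @param max_mito exclusive upper bound on the mitochondrial fraction.
#' @param min_cells_per_gene exclusive lower bound on the number of cells a
#'   gene must be detected in.
#' @return filtered `labeled_expr`; warns (rather than erroring) when all
#'   cells are removed.
#' @export
qc_filter <- function(expr, min_genes = 200, max_genes = 4000, max_mito = 0.10,
                      min_cells_per_gene = 3) {
  if (!inherits(expr, "labeled_expr")) stopf("expr must be a labeled_expr")
  meta <- expr$cell_meta
  keep_cells <- meta$mito_fraction < max_mito &
    meta$n_detected_genes >= min_genes & meta$n_detected_genes <= max_genes
  if (!any(keep_cells)) {
    warnf("qc_filter removed all %d cells; returning an empty object", nrow(meta))
    return(subset_labeled(expr, genes = rep(FALSE, nrow(expr$counts)),
                          cells = keep_cells))
  }
  out <- subset_labeled(expr, cells = keep_cells)
  detected_in <- rowSums(out$counts > 0)
  subset_labeled(out, genes = detected_in > min_cells_per_gene)
}

#' Entropy-difference specificity of a gene's cluster profile
#'
#' For per-cluster mean expression m over K clusters, forms
#' `p_k = (m_k + eps) / sum(m + eps)` and returns `D = log2(K) - H(p)` with H
#' the Shannon entropy in bits. D is 0 for a uniform profile and `log2 K` for
#' a one-hot profile: larger D means more cluster-specific. An all-zero
#' profile returns 0 by convention.
#'
#' @param mean_expr_by_cluster non-negative numeric vector of length K >= 2,
#'   or a genes x K matrix (one value per gene is returned).
#' @param eps_rel additive pseudo-mass, expressed relative to the profile
#'   total (guards `log 0` without measurably moving scores).
#' @return specificity in bits, in `[0, log2 K]`.
#' @export
entropy_specificity <- function(mean_expr_by_cluster, eps_rel = 1e-9) {
  m <- mean_expr_by_cluster
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  K <- ncol(m)
  if (K < 2L) stopf("need K >= 2 clusters")
  if (any(m < 0)) stopf("mean expression must be non-negative")
  tot <- rowSums(m)
  eps <- eps_rel * ifelse(tot > 0, tot, 1)
  p <- (m + eps) / (tot + K * eps)
  H <- -rowSums(p * log2(p))
  D <- pmax(0, log2(K) - H)
  D[tot == 0] <- 0
  if (is.null(dim(mean_expr_by_cluster))) D[[1]] else D
}

# Vectorized one-vs-rest Wilcoxon rank-sum over the rows of `x` (genes x
# cells): normal approximation with tie correction and continuity correction,
# the large-sample path of stats::wilcox.test. Returns the Mann-Whitney U of
# the in-group and the two-sided p. Constant rows get p = 1.
row_wilcox <- function(x, in_group) {
  n1 <- sum(in_group); n2 <- sum(!in_group); N <- n1 + n2
  rk <- t(apply(x, 1L, rank))                      # average ranks, ties kept
  W <- rowSums(rk[, in_group, drop = FALSE]) - n1 * (n1 + 1) / 2
  ties <- apply(x, 1L, function(v) {
    t <- table(v); sum(t^3 - t)
  })
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - ties / (N * (N - 1)))
  z <- W - n1 * n2 / 2
  z <- z - sign(z) * 0.5                           # continuity correction
  p <- rep(1, nrow(x))
  ok <- sigma2 > 0
  p[ok] <- pmin(1, 2 * stats::pnorm(abs(z[ok]) / sqrt(sigma2[ok]), lower.tail = FALSE))
  list(statistic = W, p = p, constant = !ok)
}

#' Per-cluster differential-expression statistics
#'
#' One-vs-rest Wilcoxon rank-sum on counts-per-10k normalized expression, BH
#' adjustment across genes within each cluster, detection fractions inside
#' (`pct1`) and outside (`pct2`) the cluster, `avg_log2FC =
#' log2((m1 + 1) / (m2 + 1))` on normalized means, and the
#' entropy-difference specificity of each gene's cluster-mean profile.
#'
#' @param expr a [labeled_expression()].
#' @param cluster_key name of the `cell_meta` column holding cluster labels.
#' @return data.frame of class `signature_table` with one row per
#'   (cluster, gene): `cluster`, `gene`, `avg_log2FC`, `pct1`, `pct2`,
#'   `p_adj` (and raw `p`), `entropy_diff`, `passed` (NA until
#'   [select_signatures()] applies a rule set).
#' @export
de_stats <- function(expr, cluster_key = "type") {
  if (!inherits(expr, "labeled_expr")) stopf("expr must be a labeled_expr")
  cl <- as.character(expr$cell_meta[[cluster_key]])
  if (is.null(cl)) stopf("cell_meta has no column '%s'", cluster_key)
  clusters <- sort(unique(cl))
  if (length(clusters) < 2L) stopf("need >= 2 clusters")
  sizes <- table(cl)
  if (any(sizes < 3L)) stopf("every cluster needs >= 3 cells")

  norm <- normalize_cp10k(as.matrix(expr$counts))
  det <- norm > 0
  cluster_means <- vapply(clusters, function(k)
    rowMeans(norm[, cl == k, drop = FALSE]), numeric(nrow(norm)))
  ed <- entropy_specificity(cluster_means)

  res <- lapply(clusters, function(k) {
    ing <- cl == k
    wt <- row_wilcox(norm, ing)
    m1 <- cluster_means[, k]
    m2 <- rowMeans(norm[, !ing, drop = FALSE])
    lfc <- log2((m1 + 1) / (m2 + 1))
    lfc[wt$constant] <- 0
    data.frame(cluster = k, gene = rownames(norm),
               avg_log2FC = lfc,
               pct1 = rowMeans(det[, ing, drop = FALSE]),
               pct2 = rowMeans(det[, !ing, drop = FALSE]),
               p = wt$p, p_adj = stats::p.adjust(wt$p, "BH"),
               entropy_diff = ed, statistic = wt$statistic,
               passed = NA, stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  class(out) <- c("signature_table", "data.frame")
  out
}

#' Select cluster signature genes
#'
#' Applies the class-specific thresholds and ranks survivors by
#' entropy-difference specificity. Macrophage rule: `p_adj < 0.01`,
#' `pct1 > 0.5`, `pct2 < 0.5`, `avg_log2FC > 1`. T-cell rule: `p_adj < 0.01`,
#' `avg_log2FC > 0.5` (no detection-fraction requirement). All inequalities
#' are strict. Genes in `exclude` are removed (defaults to the
#' hepatocyte/housekeeping contaminants ALB and ATP5F1E); the top
#' `top_n_by_entropy` genes per cluster by `entropy_diff` are kept.
#'
#' @param table a `signature_table` from [de_stats()].
#' @param cell_class `"macrophage"` or `"tcell"`.
#' @param exclude gene identifiers to drop regardless of statistics.
#' @param top_n_by_entropy per-cluster cap after entropy ranking (`Inf` keeps
#'   all survivors).
#' @param min_pct optional additional detection prefilter `pct1 > min_pct`
#'   (off by default; the class thresholds usually supersede it).
#' @return named list (one element per cluster) of character vectors of
#'   signature genes, ordered by decreasing `entropy_diff`; the input table
#'   with its `passed` flag filled is attached as attribute `"table"`. Warns
#'   for clusters with no surviving gene.
#' @export
select_signatures <- function(table, cell_class = c("macrophage", "tcell"),
                              exclude = c("ALB", "ATP5F1E"),
                              top_n_by_entropy = Inf, min_pct = NULL) {
  cell_class <- match.arg(cell_class)
  if (!all(c("cluster", "gene", "avg_log2FC", "pct1", "pct2", "p_adj",
             "entropy_diff") %in% names(table)))
    stopf("table must be a signature_table from de_stats()")
  ok <- table$p_adj < 0.01
  ok <- ok & if (cell_class == "macrophage")
    table$pct1 > 0.5 & table$pct2 < 0.5 & table$avg_log2FC > 1
  else table$avg_log2FC > 0.5
  if (!is.null(min_pct)) ok <- ok & table$pct1 > min_pct
  ok <- ok & !(table$gene %in% exclude)
  table$passed <- ok

  clusters <- unique(table$cluster)
  sigs <- lapply(clusters, function(k) {
    sub <- table[table$cluster == k & ok, , drop = FALSE]
    sub <- sub[order(-sub$entropy_diff, sub$gene), , drop = FALSE]
    head(sub$gene, top_n_by_entropy)
  })
  names(sigs) <- clusters
  empty <- clusters[vapply(sigs, length, integer(1)) == 0L]
  if (length(empty))
    warnf("no signature genes survived for cluster(s): %s", paste(empty, collapse = ", "))
  attr(sigs, "table") <- table
  sigs
}
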