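# Per-sample gene-set enrichment on bulk cohorts: single-sample GSEA (ES),
# immune-abundance score (IS), cytotoxic T-cell abundance (CA) and the
# composite Mscore = ES/IS and Tscore = ES*CA/IS.

# Raw single-sample GSEA enrichment statistic for one sample (Barbie-style
# weighted running sum): genes ordered by decreasing expression; at each
# position the in-set ECDF weighted by |rank value|^alpha minus the out-set
# ECDF; ES is the sum of the differences over all positions.
ssgsea_sample <- function(x, set_idx, alpha) {
  n <- length(x)
  rnk <- rank(x, ties.method = "average")      # highest expression -> rank n
  ord <- order(x, decreasing = TRUE)
  inset <- ord %in% set_idx
  w <- abs(rnk[ord])^alpha
  w[!inset] <- 0
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!inset) / (n - length(set_idx))
  sum(p_in - p_out)
}

# Cohort-relative min-max rescaling to [eps, 1]; a constant vector maps to 1.
rescale_unit <- function(es, eps = 0.01) {
  rng <- range(es)
  if (rng[2] == rng[1]) return(stats::setNames(rep(1, length(es)), names(es)))
  eps + (1 - eps) * (es - rng[1]) / (rng[2] - rng[1])
}

#' Single-sample GSEA enrichment score (ES)
#'
#' Per sample, genes are ranked by decreasing expression and the enrichment
#' score is the weighted Kolmogorov-Smirnov-style running-sum statistic
#' (weight `|rank value|^alpha` for in-set genes). By default scores are then
#' rescaled cohort-wide to `[eps, 1]` by min-max so that downstream ratio
#' scores are defined and strictly positive; rescaled scores are comparable
#' within one cohort only.
#'
#' @param expression genes x samples numeric matrix with gene rownames.
#' @param set character vector of gene identifiers; must overlap the matrix.
#' @param alpha rank-weight exponent.
#' @param rescale rescale cohort-wide to `[eps, 1]`? Pre-rescaling scores are
#'   invariant to any per-sample monotone transform of expression.
#' @param eps floor of the rescaled score.
#' @param set_name label used in error messages.
#' @return named per-sample numeric vector.
#' @export
ssgsea_es <- function(expression, set, alpha = 0.25, rescale = TRUE,
                      eps = 0.01, set_name = deparse(substitute(set))) {
  if (!is.matrix(expression) || is.null(rownames(expression)))
    stopf("expression must be a matrix with gene rownames")
  if (nrow(expression) < 2L) stopf("need >= 2 genes")
  set_idx <- which(rownames(expression) %in% set)
  if (!length(set_idx))
    stopf("gene set '%s' has no overlap with the expression matrix", set_name)
  if (length(set_idx) >= nrow(expression))
    stopf("gene set '%s' covers the whole gene universe", set_name)
  es <- apply(expression, 2L, ssgsea_sample, set_idx = set_idx, alpha = alpha)
  if (rescale) rescale_unit(es, eps) else es
}

#' Immune-abundance enrichment score (IS)
#'
#' Mean of the rescaled [ssgsea_es()] scores over a panel of immune cell-type
#' signature sets. Used as a strictly positive per-sample correction for
#' overall immune infiltration; the floor `eps` guarantees IS > 0.
#'
#' @param expression genes x samples matrix.
#' @param immune_sets named list of immune cell-type gene sets.
#' @param alpha,eps passed to [ssgsea_es()].
#' @return named per-sample numeric vector, every entry >= `eps`.
#' @export
immune_infiltration_is <- function(expression, immune_sets, alpha = 0.25, eps = 0.01) {
  if (!length(immune_sets)) stopf("need >= 1 immune gene set")
  if (is.character(immune_sets)) immune_sets <- list(immune = immune_sets)
  es <- vapply(seq_along(immune_sets), function(i)
    ssgsea_es(expression, immune_sets[[i]], alpha = alpha, eps = eps,
              set_name = names(immune_sets)[i] %||% sprintf("immune_sets[[%d]]", i)),
    numeric(ncol(expression)))
  if (is.null(dim(es))) es <- matrix(es, nrow = 1)
  stats::setNames(rowMeans(es), colnames(expression))
}

#' Cytotoxic T-cell abundance score (CA)
#'
#' Rescaled [ssgsea_es()] of the Tc signature set — the same machinery as the
#' subtype ES, applied to the cytotoxic T-cell reference signature (e.g. GNLY,
#' GZMB, PRF1, KLF2). Enters [tscore()] as a deviation correction for
#' hepatocyte-driven impairment of T-cell function.
#'
#' @param expression genes x samples matrix.
#' @param tc_set Tc signature gene identifiers.
#' @param alpha,eps passed to [ssgsea_es()].
#' @return named per-sample numeric vector.
#' @export
tc_abundance_ca <- function(expression, tc_set, alpha = 0.25, eps = 0.01) {
  ssgsea_es(expression, tc_set, alpha = alpha, eps = eps, set_name = "tc_set")
}

#' Composite enrichment scores
#'
#' `mscore` is the macrophage-subtype gene-set enrichment score corrected for
#' immune abundance, `Mscore = ES / IS`. `tscore` additionally corrects by the
#' cytotoxic T-cell abundance, `Tscore = ES * CA / IS`. Both are exact ratios.
#'
#' @param es per-sample enrichment score of the subtype signature.
#' @param is_ per-sample immune-abundance score; must be strictly positive.
#' @param ca per-sample Tc abundance score.
#' @return per-sample numeric vector.
#' @export
mscore <- function(es, is_) {
  if (any(is_ <= 0)) stopf("IS must be strictly positive")
  es / is_
}

#' @rdname mscore
#' @export
tscore <- function(es, ca, is_) {
  if (any(is_ <= 0)) stopf("IS must be strictly positive")
  es * ca / is_
}

#' Score a bulk cohort
#'
#' Computes per-sample ES (subtype signature), IS (immune panel), CA (Tc set),
#' Mscore and Tscore, joined to the clinical table.
#'
#' @param cohort a [bulk_cohort()].
#' @param signature_set subtype signature genes (e.g. the SPP1+ macrophage
#'   signature for Mscore, or the Tc signature for Tscore).
#' @param immune_sets named list of immune cell-type sets for IS.
#' @param tc_set Tc signature genes for CA.
#' @param alpha,eps passed to [ssgsea_es()].
#' @return data.frame of class `cohort_scores`: `sample`, `ES`, `IS`, `CA`,
#'   `Mscore`, `Tscore` plus the clinical columns. Scores are cohort-relative
#'   (min-max rescaled within this cohort).
#' @export
score_cohort <- function(cohort, signature_set, immune_sets, tc_set,
                         alpha = 0.25, eps = 0.01) {
  if (!inherits(cohort, "bulk_cohort")) stopf("cohort must be a bulk_cohort")
  x <- cohort$expression
  es <- ssgsea_es(x, signature_set, alpha = alpha, eps = eps, set_name = "signature_set")
  is_ <- immune_infiltration_is(x, immune_sets, alpha = alpha, eps = eps)
  ca <- tc_abundance_ca(x, tc_set, alpha = alpha, eps = eps)
  out <- data.frame(sample = colnames(x), ES = es, IS = is_, CA = ca,
                    Mscore = mscore(es, is_), Tscore = tscore(es, ca, is_),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- merge(out, cohort$clinical, by = "sample", sort = FALSE)
  class(out) <- c("cohort_scores", "data.frame")
  out
}
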