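# Rank-based AUC scoring of functional gene sets per cell (recovery-curve
# area over the top-ranked genes of each cell).

#' Build per-cell gene rankings
#'
#' Orders each cell's genes by decreasing expression. Ties are broken by a
#' seeded random permutation assigned to gene *identities* (drawn once over
#' the lexicographically sorted gene names), so rankings — and all downstream
#' scores — are invariant to the storage order of the gene rows.
#'
#' @param expr a [labeled_expression()] or a genes x cells numeric matrix with
#'   gene rownames.
#' @param tie_seed seed for the tie-breaking permutation.
#' @return object of class `cell_rankings`: an integer genes x cells matrix
#'   where entry (g, c) is gene g's rank position in cell c (1 = highest
#'   expression).
#' @export
build_rankings <- function(expr, tie_seed = 0L) {
  x <- if (inherits(expr, "labeled_expr")) as.matrix(expr$counts) else as.matrix(expr)
  if (nrow(x) < 2L) stopf("need >= 2 genes to rank")
  if (is.null(rownames(x))) stopf("expression must have gene rownames")
  tb <- with_seed(tie_seed, sample.int(nrow(x)))
  names(tb) <- sort(rownames(x))               # keyed to gene identity
  tb <- tb[rownames(x)]
  pos <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  idx <- seq_len(nrow(x))
  for (j in seq_len(ncol(x))) {
    ord <- order(-x[, j], tb)
    pos[ord, j] <- idx
  }
  structure(pos, class = c("cell_rankings", class(pos)), tie_seed = tie_seed)
}

#' AUC recovery-curve score of a gene set
#'
#' For each cell, the recovery curve counts how many members of `gene_set`
#' appear within the top k ranked genes, for k up to the window
#' `W = ceiling(top_fraction * n_genes)`. The score is the area under this
#' step curve divided by the maximum achievable area (all present members
#' packed at the very top), so scores lie in `[0, 1]` and 1 is attainable.
#' Set members absent from the matrix are ignored with a warning.
#'
#' @param rankings a [build_rankings()] result.
#' @param gene_set character vector of gene identifiers (or a single element
#'   of a GMT list).
#' @param top_fraction fraction of the ranking used as the recovery window;
#'   `top_fraction * n_genes` must be >= 2.
#' @return named numeric vector of per-cell scores in `[0, 1]`.
#' @export
auc_score <- function(rankings, gene_set, top_fraction = 0.05) {
  if (!inherits(rankings, "cell_rankings")) stopf("rankings must come from build_rankings()")
  n <- nrow(rankings)
  W <- ceiling(top_fraction * n)
  if (top_fraction * n < 2) stopf("top_fraction * n_genes must be >= 2")
  gene_set <- unique(as.character(gene_set))
  present <- gene_set[gene_set %in% rownames(rankings)]
  if (length(present) < length(gene_set))
    warnf("%d of %d set genes absent from the ranking and ignored",
          length(gene_set) - length(present), length(gene_set))
  if (!length(present)) {
    warnf("gene set entirely absent; returning 0 for every cell")
    return(stats::setNames(rep(0, ncol(rankings)), colnames(rankings)))
  }
  m <- length(present)
  r <- unclass(rankings)[present, , drop = FALSE]
  # area under the step curve = sum over members ranked within the window of
  # (W - rank + 1); maximum area packs the min(m, W) best slots.
  area <- colSums(pmax(W - r + 1, 0))
  mm <- min(m, W)
  max_area <- mm * W - mm * (mm - 1) / 2
  stats::setNames(area / max_area, colnames(rankings))
}

#' Score cells against a panel of functional gene sets
#'
#' Convenience wrapper: builds rankings once and applies [auc_score()] to each
#' set, e.g. the macrophage M1/M2/angiogenesis/phagocytosis and T-cell
#' naive/activation/cytotoxicity/exhaustion panels shipped in
#' `system.file("extdata", "cell_state_sets.gmt", package = "cldimmune")`.
#'
#' @param expr a [labeled_expression()] or genes x cells matrix.
#' @param gene_sets named list of character vectors (see [read_gmt()]).
#' @param top_fraction,tie_seed passed through.
#' @return cells x sets numeric matrix of AUC scores; row order matches the
#'   input cells.
#' @export
score_cell_states <- function(expr, gene_sets, top_fraction = 0.05, tie_seed = 0L) {
  if (!length(gene_sets) || is.null(names(gene_sets)))
    stopf("gene_sets must be a non-empty named list")
  rk <- build_rankings(expr, tie_seed = tie_seed)
  out <- vapply(gene_sets, function(s) auc_score(rk, s, top_fraction),
                numeric(ncol(rk)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(colnames(rk), names(gene_sets)))
  out
}
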