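#' Labeled single-cell expression container
#'
#' Bundles a genes x cells count matrix with per-cell annotations (disease
#' stage, cell type/cluster label, mitochondrial fraction, number of detected
#' genes). All quality-control, marker-selection, cell-state-scoring and
#' composition functions operate on this container.
#'
#' @param counts genes x cells matrix of non-negative integer counts (dense or
#'   `Matrix` sparse); rownames are gene identifiers, colnames cell barcodes.
#' @param cell_meta data.frame with one row per cell. Must contain columns
#'   `cell_id`, `type` and `stage`; columns `mito_fraction` and
#'   `n_detected_genes` are computed from `counts` when absent.
#' @param gene_ids optional character vector of gene identifiers overriding
#'   `rownames(counts)`.
#' @return An object of class `labeled_expr`: a list with elements `counts`,
#'   `gene_ids`, `cell_meta`.
#' @examples
#' m <- matrix(rpois(20, 2), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
#' meta <- data.frame(cell_id = paste0("c", 1:5),
#'                    type = "A", stage = "healthy")
#' le <- labeled_expression(m, meta)
#' @export
labeled_expression <- function(counts, cell_meta, gene_ids = rownames(counts)) {
  if (is.null(gene_ids)) stopf("counts must have rownames (gene identifiers)")
  if (length(gene_ids) != nrow(counts))
    stopf("length(gene_ids) [%d] != nrow(counts) [%d]", length(gene_ids), nrow(counts))
  if (anyDuplicated(gene_ids)) stopf("gene identifiers must be unique")
  if (!is.data.frame(cell_meta)) stopf("cell_meta must be a data.frame")
  if (nrow(cell_meta) != ncol(counts))
    stopf("nrow(cell_meta) [%d] != ncol(counts) [%d]", nrow(cell_meta), ncol(counts))
  for (col in c("cell_id", "type", "stage"))
    if (is.null(cell_meta[[col]])) stopf("cell_meta is missing column '%s'", col)
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (any(!is.finite(as.matrix(counts)))) stopf("counts must be finite")
  if (is.null(cell_meta$mito_fraction)) cell_meta$mito_fraction <- 0
  if (any(cell_meta$mito_fraction < 0 | cell_meta$mito_fraction > 1))
    stopf("mito_fraction must lie in [0, 1]")
  if (is.null(cell_meta$n_detected_genes))
    cell_meta$n_detected_genes <- as.integer(colSums(counts > 0))
  rownames(counts) <- gene_ids
  if (is.null(colnames(counts))) colnames(counts) <- cell_meta$cell_id
  rownames(cell_meta) <- NULL
  structure(list(counts = counts, gene_ids = gene_ids, cell_meta = cell_meta),
            class = "labeled_expr")
}

#' @export
print.labeled_expr <- function(x, ...) {
  cat(sprintf("labeled_expr: %d genes x %d cells\n", nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  types:  %s\n", paste(unique(x$cell_meta$type), collapse = ", ")))
  cat(sprintf("  stages: %s\n", paste(unique(x$cell_meta$stage), collapse = ", ")))
  invisible(x)
}

#' @export
dim.labeled_expr <- function(x) dim(x$counts)

# Subset by logical/integer index vectors, preserving order.
subset_labeled <- function(x, genes = NULL, cells = NULL) {
  counts <- x$counts
  meta <- x$cell_meta
  if (!is.null(cells)) {
    counts <- counts[, cells, drop = FALSE]
    meta <- meta[cells, , drop = FALSE]
    rownames(meta) <- NULL
  }
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  structure(list(counts = counts, gene_ids = rownames(counts), cell_meta = meta),
            class = "labeled_expr")
}
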