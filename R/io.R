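# Readers and writers for the standard interchange formats used by the
# pipeline: GMT gene sets, MatrixMarket single-cell matrices with TSV
# metadata, bulk expression + clinical TSV, and multi-page TIFF FISH scenes
# with a JSON sidecar.

#' Read / write GMT gene-set files
#'
#' @param path file path.
#' @return `read_gmt`: named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stopf("malformed GMT line: '%s'", substr(l, 1, 40))
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param description second GMT column (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (is.null(names(sets))) stopf("sets must be named")
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a labeled single-cell matrix as MTX + TSV
#'
#' Writes `matrix.mtx` (MatrixMarket sparse), `genes.tsv`, `barcodes.tsv` and
#' `cell_meta.tsv` into `dir`.
#'
#' @param expr a [labeled_expression()].
#' @param dir output directory (created if needed).
#' @export
write_sc_mtx <- function(expr, dir) {
  if (!inherits(expr, "labeled_expr")) stopf("expr must be a labeled_expr")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(expr$counts, sparse = TRUE),
                                          "CsparseMatrix"), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(expr$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(colnames(expr$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(expr$cell_meta, file.path(dir, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_sc_mtx
#' @return `read_sc_mtx`: a [labeled_expression()].
#' @export
read_sc_mtx <- function(dir) {
  counts <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(counts) <- readLines(file.path(dir, "genes.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  meta <- utils::read.delim(file.path(dir, "cell_meta.tsv"), stringsAsFactors = FALSE)
  labeled_expression(counts, meta)
}

#' Write / read a bulk cohort as TSV
#'
#' Expression is written genes x samples with a `gene` first column; the
#' clinical table as plain TSV (`sample`, `OS_time`, `event`, `age`, `group`).
#'
#' @param cohort a [bulk_cohort()].
#' @param expr_path,clinical_path file paths.
#' @export
write_bulk_cohort <- function(cohort, expr_path, clinical_path) {
  if (!inherits(cohort, "bulk_cohort")) stopf("cohort must be a bulk_cohort")
  df <- data.frame(gene = rownames(cohort$expression), cohort$expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$clinical, clinical_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(expr_path)
}

#' @rdname write_bulk_cohort
#' @return `read_bulk_cohort`: a [bulk_cohort()].
#' @export
read_bulk_cohort <- function(expr_path, clinical_path) {
  df <- utils::read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- df[[1]]
  clinical <- utils::read.delim(clinical_path, stringsAsFactors = FALSE)
  bulk_cohort(x, clinical)
}

#' Write / read a FISH scene as multi-page TIFF + JSON sidecar
#'
#' One 32-bit float TIFF page per channel (intensities in `[0, 1]`); the
#' sidecar records channel names and order, the channel -> marker map and the
#' pixel size.
#'
#' @param scene a [fish_scene()].
#' @param tiff_path,sidecar_path file paths.
#' @export
write_fish_scene <- function(scene, tiff_path, sidecar_path) {
  if (!inherits(scene, "fish_scene")) stopf("scene must be a fish_scene")
  tiff::writeTIFF(scene$channels, tiff_path, bits.per.sample = 32L)
  jsonlite::write_json(list(channels = names(scene$channels),
                            channel_map = scene$channel_map,
                            pixel_size_um = scene$pixel_size_um),
                       sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

#' @rdname write_fish_scene
#' @return `read_fish_scene`: a [fish_scene()].
#' @export
read_fish_scene <- function(tiff_path, sidecar_path) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (length(pages) != length(side$channels))
    stopf("TIFF has %d pages but sidecar lists %d channels",
          length(pages), length(side$channels))
  names(pages) <- side$channels
  cm <- as.list(side$channel_map)
  fish_scene(pages, side$pixel_size_um, cm)
}
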