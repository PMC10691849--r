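#' Read a 10x-style count directory
#'
#' Expects `matrix.mtx` (MatrixMarket coordinate, genes as rows, 1-based
#' indices), `features.tsv` (gene ids, optionally a second name column) and
#' `barcodes.tsv`. Row/column order is preserved; a matrix written by
#' [write_tenx()] round-trips bit-exactly.
#'
#' @param dir Directory containing the three files.
#' @return A sparse `dgCMatrix` with gene ids as rownames and barcodes as
#'   colnames.
#' @export
read_tenx <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(sprintf("missing input file(s): %s", paste(missing, collapse = ", ")))
  }
  m <- Matrix::readMM(paths[1])
  feats <- utils::read.table(paths[2], sep = "\t", header = FALSE,
                             colClasses = "character")
  bcs <- if (file.size(paths[3]) > 0) readLines(paths[3]) else character()
  if (nrow(feats) != nrow(m)) {
    abort(sprintf("dimension mismatch: matrix has %d rows but features.tsv has %d lines",
                  nrow(m), nrow(feats)))
  }
  if (length(bcs) != ncol(m)) {
    abort(sprintf("dimension mismatch: matrix has %d columns but barcodes.tsv has %d lines",
                  ncol(m), length(bcs)))
  }
  if (length(m@x) && any(m@x != floor(m@x))) {
    abort("matrix.mtx contains non-integer entries")
  }
  dimnames(m) <- list(feats[[1]], bcs)
  assert_count_matrix(as_dgc(m))
}

#' Write a count matrix as a 10x-style directory
#'
#' Emits `matrix.mtx` in MatrixMarket coordinate **integer** format with
#' genes as rows and 1-based indices, plus `features.tsv` (id and name
#' columns) and `barcodes.tsv`.
#'
#' @param counts Sparse or dense integer matrix, genes x cells, with
#'   dimnames.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_tenx <- function(counts, dir) {
  assert_count_matrix(counts)
  m <- as_dgc(counts)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trip <- Matrix::summary(m)
  lines <- c(
    "%%MatrixMarket matrix coordinate integer general",
    sprintf("%d %d %d", nrow(m), ncol(m), nrow(trip)),
    sprintf("%d %d %d", trip$i, trip$j, as.integer(trip$x))
  )
  writeLines(lines, file.path(dir, "matrix.mtx"))
  rn <- rownames(m) %||% character()
  writeLines(paste(rn, rn, sep = "\t")[seq_len(nrow(m))],
             file.path(dir, "features.tsv"))
  writeLines(colnames(m) %||% character(), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Per-cell quality-control metrics
#'
#' Computes, for every cell, the library size (total UMIs), the number of
#' detected genes (count > 0) and the mitochondrial UMI fraction, where
#' mitochondrial genes are identified by a name prefix. Cells with zero
#' library size get `mito_fraction = 0` and are flagged.
#'
#' @param counts Genes x cells count matrix.
#' @param mito_prefix Gene-name prefix marking mitochondrial genes
#'   (default `"MT-"`; annotation conventions differ across genomes).
#' @return A tibble: `barcode`, `library_size`, `n_genes`, `mito_fraction`,
#'   `flagged`.
#' @export
#' @examples
#' fx <- make_fixture("tiny-qc")
#' compute_qc(fx$counts)
compute_qc <- function(counts, mito_prefix = "MT-") {
  assert_count_matrix(counts)
  if (!is.character(mito_prefix) || !nzchar(mito_prefix)) {
    abort("`mito_prefix` must be a non-empty string")
  }
  m <- as_dgc(counts)
  lib <- Matrix::colSums(m)
  ngene <- Matrix::colSums(m > 0)
  mito <- startsWith(rownames(m), mito_prefix)
  if (!any(mito)) {
    warn(sprintf("no gene names start with '%s'; mito_fraction is 0 everywhere",
                 mito_prefix))
  }
  mito_umis <- if (any(mito)) Matrix::colSums(m[mito, , drop = FALSE]) else rep(0, ncol(m))
  frac <- ifelse(lib > 0, mito_umis / lib, 0)
  tibble(
    barcode = colnames(m),
    library_size = as.numeric(lib),
    n_genes = as.integer(ngene),
    mito_fraction = as.numeric(frac),
    flagged = unname(lib == 0)
  )
}

#' Filter cells on QC thresholds
#'
#' Retains cells with at least `min_genes` detected genes **and** a
#' mitochondrial fraction of at most `max_mito` (defaults: 200 genes, 5%).
#' The gene set is unchanged; the operation is idempotent.
#'
#' @param counts Genes x cells count matrix.
#' @param qc Output of [compute_qc()] aligned to `counts` (computed if
#'   omitted).
#' @param cfg An [analysis_config()].
#' @param mito_prefix Passed to [compute_qc()] when `qc` is omitted.
#' @return A list of class `"qc_filter"`: `counts` (filtered matrix),
#'   `report` (tibble with per-rule removal counts), `removed` (tibble of
#'   removed barcodes and reasons).
#' @export
#' @examples
#' fx <- make_fixture("tiny-qc")
#' filt <- filter_cells(fx$counts)
#' filt$report
filter_cells <- function(counts, qc = NULL, cfg = analysis_config(),
                         mito_prefix = "MT-") {
  assert_count_matrix(counts)
  if (is.null(qc)) qc <- compute_qc(counts, mito_prefix)
  if (!identical(qc$barcode, colnames(counts))) {
    abort("`qc` is not aligned with `counts` (barcodes differ)")
  }
  low_genes <- qc$n_genes < cfg$min_genes
  high_mito <- qc$mito_fraction > cfg$max_mito
  keep <- !low_genes & !high_mito
  if (!any(keep)) warn("no cells pass the QC filters")
  removed <- tibble(
    barcode = qc$barcode[!keep],
    low_genes = low_genes[!keep],
    high_mito = high_mito[!keep]
  )
  report <- tibble(
    rule = c(sprintf("n_genes < %d", cfg$min_genes),
             sprintf("mito_fraction > %g", cfg$max_mito),
             "retained"),
    n_cells = c(sum(low_genes), sum(high_mito), sum(keep))
  )
  structure(list(counts = counts[, keep, drop = FALSE],
                 report = report, removed = removed),
            class = "qc_filter")
}

#' @export
print.qc_filter <- function(x, ...) {
  cat(sprintf("<qc_filter> retained %d cells\n",
              x$report$n_cells[x$report$rule == "retained"]))
  print(x$report)
  invisible(x)
}

#' Log-normalize a count matrix
#'
#' Per-cell depth normalization followed by a log transform:
#' `ln(1 + count / library_size * scale_factor)`. Zeros map to zeros, so
#' the sparsity pattern is preserved; the result is invariant to scaling
#' all counts of a cell.
#'
#' @param counts Genes x cells count matrix; no zero-library cells (run
#'   [filter_cells()] first).
#' @param scale_factor Depth scale factor (default 1e4).
#' @return Sparse `dgCMatrix` of normalized expression.
#' @export
lognormalize <- function(counts, scale_factor = 1e4) {
  assert_count_matrix(counts)
  m <- as_dgc(counts)
  lib <- Matrix::colSums(m)
  if (any(lib == 0)) {
    abort(sprintf("zero library size for barcode(s): %s",
                  paste(colnames(m)[lib == 0], collapse = ", ")))
  }
  if (length(m@x)) {
    col_of <- rep(seq_len(ncol(m)), diff(m@p))
    m@x <- log1p(m@x / lib[col_of] * scale_factor)
  }
  m
}
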