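#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test returning the exact two-sided p-value (full
#' enumeration of the null rank-sum distribution) whenever the smaller
#' sample has at most 25 observations and there are no ties, and the
#' normal approximation with tie correction and continuity correction
#' otherwise.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return A list with `statistic` (Mann-Whitney U for `x`) and `p`.
#' @export
#' @examples
#' wilcoxon_test(c(1, 2, 3), c(4, 5, 6))$p  # exact: 2/20 = 0.1
wilcoxon_test <- function(x, y, alternative = "two.sided") {
  if (!length(x) || !length(y)) abort("both samples must be non-empty")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    # fully tied data carry no ordering information
    return(list(statistic = length(x) * length(y) / 2, p = 1))
  }
  ties <- anyDuplicated(pooled) > 0
  exact <- !ties && min(length(x), length(y)) <= 25
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment:
#' `padj_(i) = min_{j >= i} min(1, p_(j) * m / j)` on the sorted p-values,
#' mapped back to input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1] with no NA")
  }
  p.adjust(p, method = "BH")
}

#' Log fold change between cell groups
#'
#' Natural-log fold change in the expm1-mean convention used throughout
#' this package: `ln(mean(expm1(v1)) + 1) - ln(mean(expm1(v2)) + 1)` where
#' `v` are log-normalized values, so the published 0.25 (DEG) and 1.0
#' (marker) cutoffs apply on the intended scale.
#'
#' @param norm Normalized genes x cells matrix.
#' @param cells1,cells2 Barcodes (or column indices) of the two groups.
#' @param genes Genes to evaluate (default all).
#' @return Named numeric vector of log fold changes (group1 - group2).
#' @export
log_fold_change <- function(norm, cells1, cells2, genes = rownames(norm)) {
  if (!length(cells1) || !length(cells2)) abort("both groups must be non-empty")
  m1 <- Matrix::rowMeans(expm1_sparse(norm[genes, cells1, drop = FALSE]))
  m2 <- Matrix::rowMeans(expm1_sparse(norm[genes, cells2, drop = FALSE]))
  log(m1 + 1) - log(m2 + 1)
}

expm1_sparse <- function(m) {
  if (is(m, "sparseMatrix")) {
    m <- as_dgc(m)
    m@x <- expm1(m@x)
    m
  } else {
    expm1(m)
  }
}

de_core <- function(norm, cells1, cells2, cfg, positive_only = FALSE) {
  sub1 <- norm[, cells1, drop = FALSE]
  sub2 <- norm[, cells2, drop = FALSE]
  pct1 <- Matrix::rowSums(sub1 > 0) / length(cells1)
  pct2 <- Matrix::rowSums(sub2 > 0) / length(cells2)
  test_genes <- rownames(norm)[pmax(pct1, pct2) >= cfg$min_pct]
  lfc <- log_fold_change(norm, cells1, cells2, genes = test_genes)
  d1 <- as.matrix(sub1[test_genes, , drop = FALSE])
  d2 <- as.matrix(sub2[test_genes, , drop = FALSE])
  p <- vapply(seq_along(test_genes), function(i) {
    wilcoxon_test(d1[i, ], d2[i, ])$p
  }, numeric(1))
  padj <- if (cfg$adjust == "BH") bh_adjust(p) else p.adjust(p, "bonferroni")
  lfc_cut <- if (positive_only) cfg$marker_lfc else cfg$deg_lfc
  sig <- if (positive_only) {
    lfc > lfc_cut & padj < cfg$alpha
  } else {
    abs(lfc) > lfc_cut & padj < cfg$alpha
  }
  tibble(
    gene = test_genes,
    logFC = as.numeric(lfc),
    pct1 = as.numeric(pct1[test_genes]),
    pct2 = as.numeric(pct2[test_genes]),
    p = p, padj = padj, significant = sig
  )
}

#' Aging differential expression within a cell type
#'
#' Wilcoxon rank-sum test per gene, aged (group 1) versus young (group 2),
#' restricted to one cell type. Genes are pre-filtered to a detection
#' fraction of at least `cfg$min_pct` in at least one group; adjustment is
#' applied over the tested genes of the cell type. A gene is significant
#' when `|logFC| > cfg$deg_lfc` and `padj < cfg$alpha` (defaults 0.25 and
#' 0.05).
#'
#' @param norm Normalized genes x cells matrix.
#' @param cells Cell metadata with `barcode`, `age_group`, `cell_type`.
#' @param cell_type Cell type to test.
#' @param cfg An [analysis_config()].
#' @return A tibble of class `"de_table"`: `gene`, `logFC`, `pct1`, `pct2`,
#'   `p`, `padj`, `significant` (logFC is aged minus young).
#' @export
find_degs <- function(norm, cells, cell_type, cfg = analysis_config()) {
  cells <- check_cells_aligned(norm, cells)
  sel <- cells$cell_type == cell_type
  aged <- cells$barcode[sel & cells$age_group == "aged"]
  young <- cells$barcode[sel & cells$age_group == "young"]
  if (!length(aged) || !length(young)) {
    abort(sprintf("cell type '%s' is missing from one age group", cell_type))
  }
  out <- de_core(norm, aged, young, cfg)
  structure(out, class = c("de_table", class(out)),
            contrast = "aged-vs-young", cell_type = cell_type)
}

#' One-vs-rest marker genes per cell type
#'
#' For every cell type, tests each gene against all remaining cells and
#' keeps positive markers: `logFC > cfg$marker_lfc` (default 1) and
#' `padj < cfg$alpha`. Results are ranked by decreasing logFC within type,
#' supporting top-N marker selection.
#'
#' @inheritParams find_degs
#' @return A tibble of class `"marker_table"` with a `cell_type` column and
#'   the [find_degs()] columns, ranked by logFC within type.
#' @export
find_markers <- function(norm, cells, cfg = analysis_config()) {
  cells <- check_cells_aligned(norm, cells)
  types <- unique(cells$cell_type)
  if (length(types) < 2) abort("at least two cell types are required")
  out <- map(types, function(ty) {
    in_ty <- cells$barcode[cells$cell_type == ty]
    rest <- cells$barcode[cells$cell_type != ty]
    de_core(norm, in_ty, rest, cfg, positive_only = TRUE) |>
      mutate(cell_type = ty, .before = 1) |>
      arrange(dplyr::desc(.data$logFC))
  }) |> list_rbind()
  structure(out, class = c("marker_table", class(out)))
}
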