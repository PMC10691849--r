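#' Marker-based cell-type assignment
#'
#' Scores every cell for each marker panel with the bin-matched module
#' score and labels the cell with the highest-scoring type. Cells are
#' labelled `"ambiguous"` on an exact tie for the maximum or when no score
#' is positive; ambiguous cells should be excluded from per-type
#' statistics downstream.
#'
#' @param norm Normalized genes x cells matrix.
#' @param markers Named list: cell type -> character vector of marker
#'   genes. At least two panels; panels with no genes in the matrix are an
#'   error.
#' @param cfg An [analysis_config()]; supplies `nbin`, `nctrl` and the
#'   seed for control-gene sampling (the only stochastic step).
#' @return A tibble: `barcode`, `cell_type`, plus one `score_<type>`
#'   column per panel.
#' @export
assign_cell_types <- function(norm, markers, cfg = analysis_config()) {
  if (!is.list(markers) || length(markers) < 2 || is.null(names(markers))) {
    abort("`markers` must be a named list of at least two marker panels")
  }
  scores <- vapply(names(markers), function(ty) {
    present <- intersect(markers[[ty]], rownames(norm))
    if (!length(present)) {
      abort(sprintf("marker panel '%s' has no genes in the matrix", ty))
    }
    # the control-draw seed depends on the panel's gene content, so two
    # types with identical panels get identical scores and tie exactly
    module_score(norm, present, nbin = cfg$nbin, nctrl = cfg$nctrl,
                 seed = substream_seed(cfg$seed, "annotate",
                                       paste(sort(present), collapse = ",")))
  }, numeric(ncol(norm)))
  best <- max.col(scores, ties.method = "first")
  top <- scores[cbind(seq_len(nrow(scores)), best)]
  n_at_max <- rowSums(scores == top)
  label <- unname(ifelse(top <= 0 | n_at_max > 1, "ambiguous",
                         colnames(scores)[best]))
  out <- tibble(barcode = colnames(norm), cell_type = label)
  score_cols <- as_tibble(as.data.frame(scores))
  names(score_cols) <- paste0("score_", names(markers))
  dplyr::bind_cols(out, score_cols)
}

#' Cell-type proportions by age group
#'
#' Fraction of each group's cells belonging to each cell type, with raw
#' counts alongside. Fractions sum to 1 within each group.
#'
#' @param cells Cell metadata tibble with `cell_type` and `age_group`.
#' @param drop_ambiguous Drop cells labelled `"ambiguous"` before
#'   computing fractions (default TRUE).
#' @return A tibble: `cell_type`, `age_group`, `n`, `fraction`.
#' @export
#' @examples
#' cells <- tibble::tibble(
#'   cell_type = c("A", "A", "B", "B", "A", "A", "A", "B"),
#'   age_group = rep(c("young", "aged"), each = 4)
#' )
#' celltype_proportions(cells)
celltype_proportions <- function(cells, drop_ambiguous = TRUE) {
  if (!all(c("cell_type", "age_group") %in% names(cells))) {
    abort("`cells` must have columns cell_type and age_group")
  }
  if (drop_ambiguous) cells <- filter(cells, .data$cell_type != "ambiguous")
  groups <- unique(cells$age_group)
  if (!length(groups) || any(table(cells$age_group) == 0)) {
    abort("every age group must contain at least one annotated cell")
  }
  cells |>
    count(.data$age_group, .data$cell_type, name = "n") |>
    group_by(.data$age_group) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup() |>
    tidyr::complete(.data$age_group, .data$cell_type,
                    fill = list(n = 0L, fraction = 0)) |>
    relocate("cell_type", "age_group")
}
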