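#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a transcriptional-noise report
#'
#' One row per analysed cell type with both log2 aged/young ratios.
#'
#' @param x A `"noise_report"` from [transcriptional_noise()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.noise_report <- function(x, ...) x$summary

#' @rdname tidy.noise_report
#' @export
glance.noise_report <- function(x, ...) {
  tibble(
    n_types = nrow(x$summary),
    n_excluded = nrow(x$excluded),
    top_type = x$summary$cell_type[which.max(x$summary$log2_ratio_cells)],
    max_log2_ratio_cells = max(x$summary$log2_ratio_cells)
  )
}

#' Tidy a QC filter result
#'
#' @param x A `"qc_filter"` from [filter_cells()].
#' @param ... Unused.
#' @return The per-rule report tibble.
#' @export
tidy.qc_filter <- function(x, ...) x$report

#' @rdname tidy.qc_filter
#' @export
glance.qc_filter <- function(x, ...) {
  tibble(n_retained = x$report$n_cells[x$report$rule == "retained"],
         n_removed = nrow(x$removed))
}

#' Tidy a differential-expression table
#'
#' @param x A `"de_table"` from [find_degs()].
#' @param ... Unused.
#' @return A plain tibble of per-gene results.
#' @export
tidy.de_table <- function(x, ...) as_tibble(unclass_tbl(x))

#' @rdname tidy.de_table
#' @export
glance.de_table <- function(x, ...) {
  tibble(
    n_tested = nrow(x),
    n_up = sum(x$significant & x$logFC > 0),
    n_down = sum(x$significant & x$logFC < 0)
  )
}

#' Tidy a ligand-receptor comparison
#'
#' @param x An `"lr_comparison"` from [compare_groups()].
#' @param ... Unused.
#' @return The classified interaction tibble.
#' @export
tidy.lr_comparison <- function(x, ...) x$classified

#' @rdname tidy.lr_comparison
#' @export
glance.lr_comparison <- function(x, ...) {
  cls <- x$classified$class
  tibble(
    n_young_only = sum(cls == "young_only"),
    n_aged_only = sum(cls == "aged_only"),
    n_shared = sum(cls == "shared")
  )
}

unclass_tbl <- function(x) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}
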