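#' Analysis configuration
#'
#' Collects every tunable threshold of the downstream analyses in one
#' validated object. Defaults are the published cutoffs of the workflow this
#' package implements: nuclei with fewer than 200 detected genes or a
#' mitochondrial UMI fraction above 5% are discarded; markers require
#' log fold change > 1, aging DEGs |logFC| > 0.25, both at BH-adjusted
#' p < 0.05; the noise statistic requires at least 10 young and 10 aged
#' cells per cell type; ligand--receptor pairs must be detected in > 10% of
#' cells of some cell type and are called at permutation p < 0.01.
#'
#' @param min_genes Minimum number of detected genes per nucleus (kept if
#'   `n_genes >= min_genes`).
#' @param max_mito Maximum mitochondrial UMI fraction (kept if
#'   `mito_fraction <= max_mito`).
#' @param scale_factor Library-size scale factor for log-normalization.
#' @param marker_lfc Natural-log fold-change cutoff for one-vs-rest markers
#'   (positive side only).
#' @param deg_lfc Absolute natural-log fold-change cutoff for aged-vs-young
#'   DEGs.
#' @param alpha Adjusted p-value cutoff for markers and DEGs.
#' @param min_cells_noise Minimum cells per age group for a cell type to
#'   enter the transcriptional-noise computation.
#' @param lr_min_frac Detection-fraction gate for ligand--receptor testing.
#' @param lr_alpha Permutation p-value cutoff for a valid interaction.
#' @param n_perm Number of label permutations for the interaction test.
#' @param nbin Number of equal-frequency expression bins for module scoring.
#' @param nctrl Control genes drawn per gene-set gene for module scoring.
#' @param min_pct Detection-fraction pre-filter for differential expression.
#' @param adjust Multiple-testing method, `"BH"` or `"bonferroni"`.
#' @param seed Integer seed governing all stochastic steps.
#'
#' @return A validated list of class `"tx_config"`.
#' @export
#' @examples
#' cfg <- analysis_config(seed = 7)
#' cfg$min_genes
analysis_config <- function(min_genes = 200, max_mito = 0.05,
                            scale_factor = 1e4, marker_lfc = 1.0,
                            deg_lfc = 0.25, alpha = 0.05,
                            min_cells_noise = 10, lr_min_frac = 0.10,
                            lr_alpha = 0.01, n_perm = 1000,
                            nbin = 24, nctrl = 100,
                            min_pct = 0.1, adjust = c("BH", "bonferroni"),
                            seed = 1L) {
  adjust <- match.arg(adjust)
  cfg <- list(
    min_genes = min_genes, max_mito = max_mito, scale_factor = scale_factor,
    marker_lfc = marker_lfc, deg_lfc = deg_lfc, alpha = alpha,
    min_cells_noise = min_cells_noise, lr_min_frac = lr_min_frac,
    lr_alpha = lr_alpha, n_perm = n_perm, nbin = nbin, nctrl = nctrl,
    min_pct = min_pct, adjust = adjust, seed = as.integer(seed)
  )
  chk <- function(ok, field, msg) {
    if (!ok) abort(sprintf("invalid `%s`: %s", field, msg))
  }
  chk(min_genes >= 0, "min_genes", "must be >= 0")
  chk(max_mito >= 0 && max_mito <= 1, "max_mito", "must be in [0, 1]")
  chk(scale_factor > 0, "scale_factor", "must be positive")
  chk(deg_lfc >= 0, "deg_lfc", "must be >= 0")
  chk(alpha > 0 && alpha <= 1, "alpha", "must be in (0, 1]")
  chk(min_cells_noise >= 1, "min_cells_noise", "must be >= 1")
  chk(lr_min_frac >= 0 && lr_min_frac < 1, "lr_min_frac", "must be in [0, 1)")
  chk(lr_alpha > 0 && lr_alpha <= 1, "lr_alpha", "must be in (0, 1]")
  chk(n_perm >= 1, "n_perm", "must be >= 1")
  chk(nbin >= 2, "nbin", "must be >= 2")
  chk(nctrl >= 1, "nctrl", "must be >= 1")
  chk(min_pct >= 0 && min_pct <= 1, "min_pct", "must be in [0, 1]")
  structure(cfg, class = "tx_config")
}

#' @export
print.tx_config <- function(x, ...) {
  cat("<tx_config>\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
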