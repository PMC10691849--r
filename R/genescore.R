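#' Bin-matched control-gene module score
#'
#' Scores every cell for a gene set against expression-matched controls:
#' (1) average each gene's normalized expression over all cells; (2) cut
#' genes into `nbin` equal-frequency bins of that average; (3) for each set
#' gene, draw `nctrl` control genes uniformly from the non-set genes of
#' its bin (with replacement only when that pool is smaller than
#' `nctrl`); (4) score each
#' cell as mean expression over the set genes minus mean expression over
#' the pooled control multiset. Under no enrichment the score is centered
#' near 0; adding a constant to the set genes of some cells shifts their
#' scores by exactly that constant.
#'
#' @param norm Normalized genes x cells matrix (see [lognormalize()]).
#' @param genes Character vector of gene-set members; members absent from
#'   the matrix are dropped with a warning.
#' @param nbin Number of equal-frequency bins (default 24).
#' @param nctrl Controls per set gene (default 100).
#' @param seed Integer seed for the control draw.
#' @return Named numeric vector, one score per cell.
#' @export
module_score <- function(norm, genes, nbin = 24, nctrl = 100, seed = 1L) {
  if (nbin < 2) abort("`nbin` must be >= 2")
  if (nctrl < 1) abort("`nctrl` must be >= 1")
  present <- intersect(genes, rownames(norm))
  if (!length(present)) abort("no gene-set members are present in the matrix")
  if (length(present) < length(unique(genes))) {
    warn(sprintf("%d gene-set member(s) absent from the matrix were dropped",
                 length(unique(genes)) - length(present)))
  }
  avg <- Matrix::rowMeans(norm)
  nbin_eff <- min(nbin, nrow(norm))
  # equal-frequency bins by rank of the per-gene average; ties broken by
  # original order so the binning is deterministic
  rk <- rank(avg, ties.method = "first")
  bin <- ceiling(rk * nbin_eff / nrow(norm))
  names(bin) <- rownames(norm)
  ctrl <- with_seed(seed, {
    unlist(lapply(present, function(g) {
      # set genes are excluded from the control pool so that a shift in
      # the set genes moves the score by exactly that shift
      pool <- setdiff(rownames(norm)[bin == bin[[g]]], present)
      if (!length(pool)) pool <- rownames(norm)[bin == bin[[g]]]
      sample(pool, nctrl, replace = length(pool) < nctrl)
    }), use.names = FALSE)
  })
  set_mean <- Matrix::colMeans(norm[present, , drop = FALSE])
  # control multiset: duplicated draws contribute with multiplicity
  tab <- table(ctrl)
  w <- as.numeric(tab)
  ctrl_mean <- as.numeric(w %*% norm[names(tab), , drop = FALSE]) / sum(w)
  setNames(as.numeric(set_mean - ctrl_mean), colnames(norm))
}

#' Compare module scores between groups
#'
#' Summarises a score vector by group and tests the difference with a
#' Wilcoxon rank-sum test (two-sided by default; one-sided alternatives
#' available for directional hypotheses).
#'
#' @param scores Named numeric vector from [module_score()].
#' @param cells Cell metadata tibble with `barcode` and the grouping
#'   column.
#' @param group Name of the grouping column (default `"age_group"`).
#' @param alternative Test sidedness: `"two.sided"`, `"less"`, `"greater"`
#'   (group1 vs group2 in the order of factor/sorted levels).
#' @return A tibble with one row per group (`n`, `mean`, `median`) and
#'   columns `p` and `statistic` repeated across rows (attribute-free,
#'   pipe-friendly).
#' @export
score_groups <- function(scores, cells, group = "age_group",
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!group %in% names(cells)) abort(sprintf("column `%s` not in `cells`", group))
  cells <- cells[match(names(scores), cells$barcode), , drop = FALSE]
  if (anyNA(cells$barcode)) abort("`scores` contains barcodes absent from `cells`")
  g <- cells[[group]]
  lev <- if (is.factor(g)) levels(g) else sort(unique(g))
  if (any(table(factor(g, lev)) == 0) || length(lev) < 2) {
    abort("every group must contain at least one cell")
  }
  smry <- tibble(group = g, score = as.numeric(scores)) |>
    group_by(.data$group) |>
    summarise(n = n(), mean = mean(.data$score),
              median = median(.data$score), .groups = "drop")
  if (length(lev) == 2) {
    wt <- wilcoxon_test(scores[g == lev[1]], scores[g == lev[2]],
                        alternative = alternative)
    smry$p <- wt$p
    smry$statistic <- wt$statistic
  }
  names(smry)[1] <- group
  smry
}

#' Cell-cycle phase assignment
#'
#' Scores each cell for S-phase and G2/M gene programs with
#' [module_score()] and assigns the phase by score: S when the S score
#' exceeds both the G2/M score and 0; G2M when the G2/M score is at least
#' the S score and positive; G1 otherwise (neither program enriched).
#'
#' @param norm Normalized genes x cells matrix.
#' @param s_genes,g2m_genes Character vectors of S-phase and G2/M genes.
#' @param nbin,nctrl,seed Passed to [module_score()].
#' @return A tibble: `barcode`, `s_score`, `g2m_score`, `phase`.
#' @export
cycle_phase <- function(norm, s_genes, g2m_genes, nbin = 24, nctrl = 100,
                        seed = 1L) {
  s <- module_score(norm, s_genes, nbin, nctrl, seed = substream_seed(seed, "S"))
  g2m <- module_score(norm, g2m_genes, nbin, nctrl,
                      seed = substream_seed(seed, "G2M"))
  phase <- unname(ifelse(s > g2m & s > 0, "S",
                         ifelse(g2m >= s & g2m > 0, "G2M", "G1")))
  tibble(barcode = colnames(norm), s_score = as.numeric(s),
         g2m_score = as.numeric(g2m), phase = phase)
}
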