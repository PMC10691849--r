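#' Down-sample every cell to an equal library size
#'
#' Draws, for each cell, `target` UMIs without replacement from the cell's
#' UMI multiset (a multivariate hypergeometric draw), so every column of
#' the result sums exactly to `target` and no entry exceeds its original
#' count. Each cell uses its own RNG substream derived from `seed` and the
#' barcode, so results do not depend on column order.
#'
#' @param counts Genes x cells integer count matrix; every library size
#'   must be at least `target`.
#' @param target Target library size (>= 1).
#' @param seed Integer seed.
#' @return Sparse `dgCMatrix` of down-sampled counts.
#' @export
downsample_umis <- function(counts, target, seed = 1L) {
  assert_count_matrix(counts)
  if (target < 1) abort("`target` must be >= 1")
  m <- as_dgc(counts)
  lib <- Matrix::colSums(m)
  short <- lib < target
  if (any(short)) {
    abort(sprintf("target %d exceeds the library size of barcode(s): %s",
                  as.integer(target),
                  paste(colnames(m)[short], collapse = ", ")))
  }
  cols <- map(seq_len(ncol(m)), function(j) {
    if (m@p[j] == m@p[j + 1]) return(list(i = integer(), x = numeric()))
    idx <- m@i[(m@p[j] + 1):m@p[j + 1]] + 1L
    cnt <- m@x[(m@p[j] + 1):m@p[j + 1]]
    if (lib[j] == target) return(list(i = idx, x = cnt))
    kept <- with_seed(substream_seed(seed, "cell", colnames(m)[j]), {
      # exact multivariate hypergeometric: permute the UMI multiset and
      # keep the first `target` molecules
      pool <- rep.int(idx, as.integer(cnt))
      tabulate(pool[sample.int(length(pool), as.integer(target))],
               nbins = nrow(m))
    })
    nz <- which(kept > 0)
    list(i = nz, x = kept[nz])
  })
  lens <- map_int(cols, function(cc) length(cc$i))
  sparseMatrix(
    i = unlist(map(cols, "i"), use.names = FALSE),
    j = rep(seq_len(ncol(m)), lens),
    x = unlist(map(cols, "x"), use.names = FALSE),
    dims = dim(m), dimnames = dimnames(m)
  )
}

#' Balance young and aged cell numbers for one cell type
#'
#' Keeps all cells of the smaller age group and a seeded uniform
#' subsample, without replacement, of the larger group, so both groups
#' contribute equally many cells.
#'
#' @param cells Cell metadata with `barcode`, `age_group`, `cell_type`.
#' @param cell_type Cell type to balance.
#' @param seed Integer seed.
#' @return Character vector of retained barcodes.
#' @export
equalize_groups <- function(cells, cell_type, seed = 1L) {
  sel <- cells[cells$cell_type == cell_type, , drop = FALSE]
  young <- sel$barcode[sel$age_group == "young"]
  aged <- sel$barcode[sel$age_group == "aged"]
  if (!length(young) || !length(aged)) {
    abort(sprintf("cell type '%s' is absent from one age group", cell_type))
  }
  k <- min(length(young), length(aged))
  with_seed(substream_seed(seed, "equalize", cell_type), {
    c(if (length(young) > k) sample(young, k) else young,
      if (length(aged) > k) sample(aged, k) else aged)
  })
}

#' Per-cell distance to the group mean
#'
#' For each group, the mean expression vector over that group's cells;
#' each cell's transcriptional noise is its Euclidean distance to its own
#' group's mean.
#'
#' @param values Genes x cells matrix slice (counts or transformed).
#' @param labels Group label per cell (length `ncol(values)`).
#' @return A tibble: `barcode`, `group`, `distance`.
#' @export
#' @examples
#' v <- cbind(y1 = c(0, 0), y2 = c(2, 2), a1 = c(0, 0), a2 = c(4, 4))
#' group_distances(v, c("young", "young", "aged", "aged"))
group_distances <- function(values, labels) {
  if (length(labels) != ncol(values)) {
    abort("`labels` must have one entry per column of `values`")
  }
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("cell%d", seq_len(ncol(values)))
  }
  out <- map(unique(labels), function(g) {
    sub <- values[, labels == g, drop = FALSE]
    ctr <- rowMeans(sub)
    tibble(barcode = colnames(sub), group = g,
           distance = unname(sqrt(Matrix::colSums((sub - ctr)^2))))
  })
  list_rbind(out)
}

#' Transcriptional noise per cell type
#'
#' Quantifies aging-related transcriptional noise for every cell type with
#' at least `cfg$min_cells_noise` young and aged cells: (1) restrict to
#' the type's cells; (2) down-sample every cell's UMIs to the minimum
#' library size within that subset, so all cells have equal depth;
#' (3) down-sample cell numbers so both age groups are equally
#' represented; (4) compute each cell's Euclidean distance to its age
#' group's cell-type mean; (5) form aged/young log2 ratios of the mean
#' distance, at the cell level and at the sample level (mean of per-sample
#' mean distances within each group, then the ratio).
#'
#' @param counts Genes x cells integer count matrix (post-QC).
#' @param cells Cell metadata with `barcode`, `sample_id`, `age_group`,
#'   `cell_type`.
#' @param cfg An [analysis_config()]; `min_cells_noise` (default 10) sets
#'   the eligibility rule and `seed` drives the down-sampling.
#' @param transform `"raw"` (default) computes distances on the
#'   down-sampled counts; `"log1p"` applies `ln(1 + x)` first.
#' @param target `"per-type"` (default) down-samples to the minimum
#'   library size within each cell type's subset; `"global"` uses the
#'   minimum over all cells of eligible types.
#' @return A list of class `"noise_report"`:
#'   \describe{
#'     \item{summary}{tibble per cell type: `n_used_per_group`,
#'       `target_libsize`, `mean_dist_young`, `mean_dist_aged`,
#'       `log2_ratio_cells`, `log2_ratio_samples`, `flagged`}
#'     \item{cell_distances}{tibble: `cell_type`, `barcode`, `sample_id`,
#'       `age_group`, `distance`}
#'     \item{sample_distances}{tibble: `cell_type`, `sample_id`,
#'       `age_group`, `n_cells`, `mean_distance`}
#'     \item{excluded}{tibble: `cell_type`, `reason`}
#'   }
#' @export
transcriptional_noise <- function(counts, cells, cfg = analysis_config(),
                                  transform = c("raw", "log1p"),
                                  target = c("per-type", "global")) {
  transform <- match.arg(transform)
  target <- match.arg(target)
  assert_count_matrix(counts)
  cells <- check_cells_aligned(counts, cells)
  if (!all(c("sample_id", "age_group", "cell_type") %in% names(cells))) {
    abort("`cells` needs columns sample_id, age_group, cell_type")
  }
  tab <- cells |>
    filter(.data$cell_type != "ambiguous") |>
    count(.data$cell_type, .data$age_group) |>
    tidyr::pivot_wider(names_from = "age_group", values_from = "n",
                       values_fill = 0L)
  for (g in c("young", "aged")) if (!g %in% names(tab)) tab[[g]] <- 0L
  eligible <- tab$cell_type[tab$young >= cfg$min_cells_noise &
                              tab$aged >= cfg$min_cells_noise]
  excluded <- tab |>
    filter(!.data$cell_type %in% eligible) |>
    mutate(reason = sprintf("fewer than %d cells in a group (young=%d, aged=%d)",
                            cfg$min_cells_noise, .data$young, .data$aged)) |>
    select("cell_type", "reason")
  if (!length(eligible)) {
    abort(sprintf("no cell type has at least %d young and %d aged cells",
                  cfg$min_cells_noise, cfg$min_cells_noise))
  }
  lib <- Matrix::colSums(counts)
  global_target <- min(lib[cells$cell_type %in% eligible])
  res <- map(eligible, function(ty) {
    sel <- cells$barcode[cells$cell_type == ty]
    sub <- counts[, sel, drop = FALSE]
    tgt <- if (target == "global") global_target else min(lib[sel])
    ds <- downsample_umis(sub, tgt, seed = substream_seed(cfg$seed, "noise", ty))
    use <- equalize_groups(cells, ty, seed = cfg$seed)
    meta <- cells[match(use, cells$barcode), , drop = FALSE]
    vals <- ds[, use, drop = FALSE]
    if (transform == "log1p") vals <- log1p(vals)
    dist <- group_distances(vals, meta$age_group) |>
      left_join(select(meta, "barcode", "sample_id"), by = "barcode") |>
      mutate(cell_type = ty, .before = 1) |>
      rename(age_group = "group")
    per_sample <- dist |>
      group_by(.data$sample_id, .data$age_group) |>
      summarise(n_cells = n(), mean_distance = mean(.data$distance),
                .groups = "drop") |>
      mutate(cell_type = ty, .before = 1)
    mean_by_group <- dist |>
      group_by(.data$age_group) |>
      summarise(m = mean(.data$distance), .groups = "drop")
    my <- mean_by_group$m[mean_by_group$age_group == "young"]
    ma <- mean_by_group$m[mean_by_group$age_group == "aged"]
    samp_means <- per_sample |>
      group_by(.data$age_group) |>
      summarise(m = mean(.data$mean_distance), .groups = "drop")
    sy <- samp_means$m[samp_means$age_group == "young"]
    sa <- samp_means$m[samp_means$age_group == "aged"]
    flagged <- (my == 0) != (ma == 0) || (sy == 0) != (sa == 0)
    if (flagged) {
      warn(sprintf("cell type '%s': one group has zero mean distance; log2 ratio is infinite",
                   ty))
    }
    list(
      summary = tibble(
        cell_type = ty,
        n_used_per_group = length(use) %/% 2L,
        target_libsize = as.integer(tgt),
        mean_dist_young = my, mean_dist_aged = ma,
        log2_ratio_cells = log2(ma / my),
        log2_ratio_samples = log2(sa / sy),
        flagged = flagged
      ),
      cell_distances = dist,
      sample_distances = per_sample
    )
  })
  structure(list(
    summary = list_rbind(map(res, "summary")),
    cell_distances = list_rbind(map(res, "cell_distances")),
    sample_distances = list_rbind(map(res, "sample_distances")),
    excluded = excluded
  ), class = "noise_report")
}

#' @export
print.noise_report <- function(x, ...) {
  cat(sprintf("<noise_report> %d cell type(s), %d excluded\n",
              nrow(x$summary), nrow(x$excluded)))
  print(x$summary)
  invisible(x)
}
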