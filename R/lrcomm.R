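#' Ligand-receptor pair table
#'
#' Builds/validates a pair table. Multi-subunit complexes are written as
#' semicolon-joined gene lists; a complex counts as expressed via its
#' least-detected subunit and contributes its minimum subunit mean to the
#' interaction score.
#'
#' @param pair_id Unique pair identifiers.
#' @param ligand,receptor Semicolon-joined subunit gene ids.
#' @return A tibble of class `"lr_pairs"`.
#' @export
#' @examples
#' lr_pairs("NRG1_ERBB3", "NRG1", "ERBB3")
lr_pairs <- function(pair_id, ligand, receptor) {
  if (anyDuplicated(pair_id)) abort("`pair_id` must be unique")
  if (any(!nzchar(ligand)) || any(!nzchar(receptor))) {
    abort("subunit lists must be non-empty")
  }
  structure(tibble(pair_id = pair_id, ligand = ligand, receptor = receptor),
            class = c("lr_pairs", class(tibble())))
}

split_subunits <- function(s) strsplit(s, ";", fixed = TRUE)[[1]]

#' Detection fraction per cell type
#'
#' Fraction of each cell type's cells in which a gene is detected
#' (count > 0). For a multi-subunit complex the fraction is the minimum
#' over subunits.
#'
#' @param counts Genes x cells count matrix.
#' @param cells Cell metadata with `barcode`, `cell_type`.
#' @param gene Gene id or semicolon-joined complex.
#' @return Named numeric vector: fraction per cell type.
#' @export
expressed_fraction <- function(counts, cells, gene) {
  cells <- check_cells_aligned(counts, cells)
  subunits <- split_subunits(gene)
  missing <- setdiff(subunits, rownames(counts))
  if (length(missing)) {
    abort(sprintf("unknown gene(s): %s", paste(missing, collapse = ", ")))
  }
  types <- unique(cells$cell_type)
  det <- counts[subunits, , drop = FALSE] > 0
  vapply(setNames(types, types), function(ty) {
    sub <- det[, cells$cell_type == ty, drop = FALSE]
    min(Matrix::rowMeans(sub))
  }, numeric(1))
}

# cluster means of the named genes for given type labels (matrix genes x types)
cluster_means <- function(norm, genes, labels) {
  dense <- as.matrix(norm[genes, , drop = FALSE])
  cluster_means_dense(dense, labels)
}

# rowsum-based kernel reused across permutations: dense is genes x cells
cluster_means_dense <- function(dense, labels) {
  sums <- rowsum(t(dense), labels)        # types x genes
  sizes <- as.vector(table(labels)[rownames(sums)])
  out <- t(sums / sizes)
  rownames(out) <- rownames(dense)
  out
}

# score for one pair given a cluster-mean matrix: ligand side uses the
# subunit with the minimum sender mean, receptor side likewise
pair_score <- function(cm, ligand, receptor, sender, receiver) {
  l <- min(cm[split_subunits(ligand), sender])
  r <- min(cm[split_subunits(receptor), receiver])
  (l + r) / 2
}

#' Filter ligand-receptor pairs on detection
#'
#' A pair enters testing when both its ligand and its receptor are
#' detected in more than `cfg$lr_min_frac` of the cells of at least one
#' cell type in at least one age group (either side may qualify through
#' any type).
#'
#' @param counts Genes x cells count matrix.
#' @param cells Cell metadata with `barcode`, `cell_type`, `age_group`.
#' @param pairs An [lr_pairs()] table.
#' @param cfg An [analysis_config()].
#' @return The subset of `pairs` passing the gate.
#' @export
filter_lr_pairs <- function(counts, cells, pairs, cfg = analysis_config()) {
  cells <- check_cells_aligned(counts, cells)
  passes <- function(gene) {
    any(vapply(unique(cells$age_group), function(g) {
      sub <- cells$barcode[cells$age_group == g]
      fr <- expressed_fraction(counts[, sub, drop = FALSE],
                               cells[cells$age_group == g, , drop = FALSE],
                               gene)
      any(fr > cfg$lr_min_frac)
    }, logical(1)))
  }
  keep <- vapply(seq_len(nrow(pairs)), function(i) {
    passes(pairs$ligand[i]) && passes(pairs$receptor[i])
  }, logical(1))
  pairs[keep, , drop = FALSE]
}

#' Permutation test for ligand-receptor interactions in one age group
#'
#' For every pair and ordered (sender, receiver) cell-type combination,
#' the interaction score is the average of the ligand's mean normalized
#' expression over sender cells and the receptor's mean over receiver
#' cells (complexes use their minimum-mean subunit). The null is built by
#' shuffling cell-type labels within the group `n_perm` times;
#' `p = (1 + #\{perm score >= observed\}) / (n_perm + 1)`, so p is never
#' exactly 0. An interaction is significant at `p < cfg$lr_alpha`
#' (default 0.01).
#'
#' @param norm Normalized genes x cells matrix restricted to one age
#'   group's cells.
#' @param cells Matching metadata with `barcode`, `cell_type`.
#' @param pairs An [lr_pairs()] table (pre-filter with
#'   [filter_lr_pairs()]).
#' @param group Label stored in the result (e.g. `"young"`).
#' @param cfg An [analysis_config()]; uses `n_perm`, `lr_alpha`, `seed`.
#' @param senders,receivers Optional restriction of the type combinations
#'   tested (defaults: all types).
#' @return A tibble of class `"lr_result"`: `pair_id`, `sender`,
#'   `receiver`, `group`, `score`, `p`, `significant`.
#' @export
permutation_test <- function(norm, cells, pairs, group,
                             cfg = analysis_config(),
                             senders = NULL, receivers = NULL) {
  if (cfg$n_perm < 1) abort("`n_perm` must be >= 1")
  cells <- check_cells_aligned(norm, cells)
  labels <- cells$cell_type
  types <- sort(unique(labels))
  senders <- senders %||% types
  receivers <- receivers %||% types
  genes <- unique(unlist(lapply(c(pairs$ligand, pairs$receptor),
                                split_subunits)))
  missing <- setdiff(genes, rownames(norm))
  if (length(missing)) {
    abort(sprintf("unknown gene(s): %s", paste(missing, collapse = ", ")))
  }
  combos <- tidyr::expand_grid(
    pair = seq_len(nrow(pairs)),
    sender = senders, receiver = receivers
  )
  dense <- as.matrix(norm[genes, , drop = FALSE])
  score_all <- function(cm) {
    vapply(seq_len(nrow(combos)), function(k) {
      pair_score(cm, pairs$ligand[combos$pair[k]],
                 pairs$receptor[combos$pair[k]],
                 combos$sender[k], combos$receiver[k])
    }, numeric(1))
  }
  obs <- score_all(cluster_means_dense(dense, labels))
  exceed <- integer(nrow(combos))
  with_seed(substream_seed(cfg$seed, "lrperm", group), {
    for (b in seq_len(cfg$n_perm)) {
      perm <- score_all(cluster_means_dense(dense, sample(labels)))
      exceed <- exceed + (perm >= obs)
    }
  })
  p <- (1 + exceed) / (cfg$n_perm + 1)
  out <- tibble(
    pair_id = pairs$pair_id[combos$pair],
    sender = combos$sender, receiver = combos$receiver,
    group = group, score = obs, p = p,
    significant = p < cfg$lr_alpha
  )
  structure(out, class = c("lr_result", class(out)))
}

#' Classify interactions across age groups
#'
#' Joins the young and aged permutation results over the same pair
#' universe and classifies each (pair, sender, receiver): `young_only`
#' (significant in young, not aged — lost with age), `aged_only` (gained
#' with age), `shared`, or `neither`. Also tabulates the aged-minus-young
#' difference in significant-pair counts per (sender, receiver).
#'
#' @param young,aged [permutation_test()] results for the two groups,
#'   over identical (pair, sender, receiver) universes.
#' @return A list of class `"lr_comparison"`: `classified` (tibble with
#'   `class` column) and `count_diff` (tibble: `sender`, `receiver`,
#'   `n_young`, `n_aged`, `diff`).
#' @export
compare_groups <- function(young, aged) {
  key <- c("pair_id", "sender", "receiver")
  ku <- young[key]; ka <- aged[key]
  if (nrow(ku) != nrow(ka) ||
      !identical(dplyr::arrange(ku, dplyr::across(dplyr::everything())),
                 dplyr::arrange(ka, dplyr::across(dplyr::everything())))) {
    abort("young and aged results cover different pair universes")
  }
  merged <- left_join(
    young |> select(dplyr::all_of(key), score_young = "score",
                    p_young = "p", sig_young = "significant"),
    aged |> select(dplyr::all_of(key), score_aged = "score",
                   p_aged = "p", sig_aged = "significant"),
    by = key
  ) |>
    mutate(class = dplyr::case_when(
      .data$sig_young & !.data$sig_aged ~ "young_only",
      !.data$sig_young & .data$sig_aged ~ "aged_only",
      .data$sig_young & .data$sig_aged ~ "shared",
      TRUE ~ "neither"
    ))
  count_diff <- merged |>
    group_by(.data$sender, .data$receiver) |>
    summarise(n_young = sum(.data$sig_young), n_aged = sum(.data$sig_aged),
              diff = sum(.data$sig_aged) - sum(.data$sig_young),
              .groups = "drop")
  structure(list(classified = merged, count_diff = count_diff),
            class = "lr_comparison")
}

#' @export
print.lr_comparison <- function(x, ...) {
  cls <- table(x$classified$class)
  cat("<lr_comparison>", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
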