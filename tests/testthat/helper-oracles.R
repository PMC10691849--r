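# Independent oracles and small shared configs for the test suite.

# Exhaustive two-sided Wilcoxon rank-sum p-value: enumerate every
# assignment of the pooled values to the two samples and compare the
# rank-sum of x under each.
oracle_wilcox_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n <- length(x)
  obs <- sum(r[seq_len(n)])
  sets <- utils::combn(length(pooled), n)
  ws <- apply(sets, 2, function(idx) sum(r[idx]))
  p_le <- mean(ws <= obs)
  p_ge <- mean(ws >= obs)
  min(1, 2 * min(p_le, p_ge))
}

# Step-up BH closed form, coded directly from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(pmin(ranked, 1))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Brute-force module score: dense loops over cells; shares only the seeded
# control draw (re-derived from the documented sampling scheme).
oracle_module_score <- function(norm, genes, nbin, nctrl, seed) {
  dense <- as.matrix(norm)
  avg <- apply(dense, 1, mean)
  rk <- rank(avg, ties.method = "first")
  nbin_eff <- min(nbin, nrow(dense))
  bin <- ceiling(rk * nbin_eff / nrow(dense))
  names(bin) <- rownames(dense)
  set.seed(seed)
  ctrl <- character()
  for (g in genes) {
    pool <- setdiff(rownames(dense)[bin == bin[[g]]], genes)
    if (!length(pool)) pool <- rownames(dense)[bin == bin[[g]]]
    ctrl <- c(ctrl, sample(pool, nctrl, replace = length(pool) < nctrl))
  }
  out <- numeric(ncol(dense))
  for (j in seq_len(ncol(dense))) {
    out[j] <- mean(dense[genes, j]) - mean(dense[ctrl, j])
  }
  names(out) <- colnames(dense)
  out
}

# Exhaustive ligand-receptor permutation p on a tiny instance: every
# distinct reassignment of the type labels.
oracle_lr_perm_p <- function(norm, labels, ligand, receptor,
                             sender, receiver, obs) {
  perms <- unique(combinat_perms(labels))
  cm_score <- function(lab) {
    l <- mean(norm[ligand, lab == sender])
    r <- mean(norm[receptor, lab == receiver])
    (l + r) / 2
  }
  scores <- vapply(perms, cm_score, numeric(1))
  mean(scores >= obs)
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    rest <- combinat_perms(v[-i])
    out <- c(out, lapply(rest, function(r) c(v[i], r)))
  }
  out
}

# Small three-type simulation shared by recovery tests.
small_sim_config <- function(seed, n_genes = 300, n_cells = 60, ...) {
  sim_config(
    n_genes = n_genes, n_cells_per_sample = n_cells,
    cell_types = tibble::tibble(
      name = c("A", "B", "C"),
      prop_young = c(0.4, 0.3, 0.3),
      prop_aged = c(0.3, 0.3, 0.4)
    ),
    seed = seed, ...
  )
}

# Annotated per-cell table using the simulation's ground truth.
truth_cells <- function(sim, counts = sim$counts) {
  cells <- sim$cells[sim$cells$barcode %in% colnames(counts), ]
  cells$cell_type <- cells$true_type
  cells
}
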