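test_that("module score matches an independent brute-force scorer", {
  sim <- simulate_counts(small_sim_config(41, n_genes = 50, n_cells = 3))
  norm <- lognormalize(sim$counts[, 1:20])
  genes <- rownames(norm)[c(12, 20, 33, 47)]
  for (seed in c(1L, 9L, 101L)) {
    mine <- module_score(norm, genes, nbin = 5, nctrl = 10, seed = seed)
    brute <- oracle_module_score(norm, genes, nbin = 5, nctrl = 10, seed = seed)
    expect_equal(mine, brute, tolerance = 1e-12)
  }
})

test_that("module score is zero on constant input and linear in set shifts", {
  m <- matrix(2, 30, 10,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("c%02d", 1:10)))
  genes <- c("g03", "g07", "g11")
  s <- module_score(m, genes, nbin = 3, nctrl = 10, seed = 1)
  expect_equal(unname(s), rep(0, 10), tolerance = 1e-12)

  # +delta on the set genes in some cells raises exactly those scores by delta
  delta <- 0.37
  m2 <- m
  m2[genes, 1:4] <- m2[genes, 1:4] + delta
  s2 <- module_score(m2, genes, nbin = 3, nctrl = 10, seed = 1)
  expect_equal(unname(s2[1:4] - s[1:4]), rep(delta, 4), tolerance = 1e-10)

  # permutation of cells permutes scores (control draw depends only on genes)
  perm <- c(4, 1, 3, 2, 9, 10, 5, 6, 8, 7)
  s3 <- module_score(m2[, perm], genes, nbin = 3, nctrl = 10, seed = 1)
  expect_equal(unname(s3), unname(s2[perm]), tolerance = 1e-12)

  expect_error(module_score(m, c("zz1", "zz2"), 3, 10, 1), "no gene-set")
  expect_warning(module_score(m, c("g03", "zz1"), 3, 10, 1), "dropped")
})

test_that("random matched-bin gene sets score near zero on average", {
  sim <- simulate_counts(small_sim_config(43, n_genes = 300, n_cells = 25))
  norm <- lognormalize(sim$counts)
  set.seed(7)
  means <- vapply(1:100, function(i) {
    genes <- sample(rownames(norm), 10)
    mean(module_score(norm, genes, seed = i))
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.01)
})

test_that("group score comparison detects planted shifts and calibrates under the null", {
  sim <- simulate_counts(small_sim_config(47, n_genes = 200, n_cells = 40))
  norm <- lognormalize(sim$counts)
  cells <- truth_cells(sim)
  genes <- rownames(norm)[101:115]

  # identical groups: p = 1
  s_const <- stats::setNames(rep(1.5, ncol(norm)), colnames(norm))
  sg <- score_groups(s_const, cells)
  expect_equal(unique(sg$p), 1)

  # planted down-shift in aged cells of the set genes
  hits <- vapply(1:10, function(seed) {
    sim_i <- simulate_counts(small_sim_config(
      seed, n_genes = 200, n_cells = 40,
      planted_degs = tibble::tibble(cell_type = rep(c("A", "B", "C"),
                                                    each = 15),
                                    gene = rep(genes, 3), delta = -0.5)))
    norm_i <- lognormalize(sim_i$counts)
    cells_i <- truth_cells(sim_i)
    s <- module_score(norm_i, genes, seed = seed)
    sg_i <- score_groups(s, cells_i)
    sg_i$mean[sg_i$age_group == "aged"] < sg_i$mean[sg_i$age_group == "young"]
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("cell-cycle phases follow the score-argmax rule and recover a planted program", {
  m <- matrix(1, 40, 6,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("c%d", 1:6)))
  s_genes <- c("g01", "g02", "g03")
  g2m_genes <- c("g04", "g05", "g06")
  m[s_genes, 1:2] <- 4       # S program on
  m[g2m_genes, 3:4] <- 4     # G2M program on
  ph <- cycle_phase(m, s_genes, g2m_genes, nbin = 2, nctrl = 10, seed = 1)
  expect_equal(ph$phase[1:2], c("S", "S"))
  expect_equal(ph$phase[3:4], c("G2M", "G2M"))
  expect_equal(ph$phase[5:6], c("G1", "G1"))  # both scores <= 0

  # planted S-like program in a cell subset raises its S fraction
  hits <- vapply(1:10, function(seed) {
    sim <- simulate_counts(small_sim_config(
      seed + 100, n_genes = 200, n_cells = 30,
      planted_degs = tibble::tibble(cell_type = "A",
                                    gene = sprintf("G%05d", 61:75),
                                    delta = 1)))
    norm <- lognormalize(sim$counts)
    cells <- truth_cells(sim)
    ph_i <- cycle_phase(norm, sprintf("G%05d", 61:75),
                        sprintf("G%05d", 121:135), seed = seed)
    aged_A <- cells$barcode[cells$true_type == "A" & cells$age_group == "aged"]
    bg <- setdiff(ph_i$barcode, aged_A)
    mean(ph_i$phase[ph_i$barcode %in% aged_A] == "S") >
      mean(ph_i$phase[ph_i$barcode %in% bg] == "S")
  }, logical(1))
  expect_gte(sum(hits), 9)
})
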