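test_that("UMI down-sampling conserves the target exactly and is hypergeometric", {
  # identity at full depth
  m <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 1), x = c(5, 3),
                            dims = c(3, 1),
                            dimnames = list(c("g1", "g2", "g3"), "c1"))
  expect_identical(as.matrix(downsample_umis(m, 8)), as.matrix(m))

  # exceeding a library size names the barcode
  expect_error(downsample_umis(m, 9), "c1")

  # conservation on simulated data
  sim <- simulate_counts(small_sim_config(2, n_genes = 100, n_cells = 15))
  tgt <- min(Matrix::colSums(sim$counts))
  ds <- downsample_umis(sim$counts, tgt, seed = 4)
  expect_true(all(Matrix::colSums(ds) == tgt))
  expect_true(all(as.matrix(ds) <= as.matrix(sim$counts)))

  # column order independence: same cell, same seed, different position
  ds_sub <- downsample_umis(sim$counts[, 5:10], tgt, seed = 4)
  expect_identical(as.matrix(ds_sub[, 1]), as.matrix(ds[, 5]))

  # [4,4] cell at target 4: expectation [2,2] within 3 SE over many draws
  cell <- Matrix::sparseMatrix(i = 1:2, j = c(1, 1), x = c(4, 4),
                               dims = c(2, 1),
                               dimnames = list(c("a", "b"), "x"))
  draws <- vapply(1:2000, function(s) {
    downsample_umis(cell, 4, seed = s)["a", 1]
  }, numeric(1))
  # var of hypergeometric(N=8, K=4, n=4): 4*0.5*0.5*(4/7) = 4/7
  se <- sqrt((4 / 7) / 2000)
  expect_lt(abs(mean(draws) - 2), 3 * se)
})

test_that("group balancing keeps the smaller group whole and is seeded", {
  cells <- tibble::tibble(
    barcode = sprintf("c%02d", 1:42),
    age_group = c(rep("young", 30), rep("aged", 12)),
    cell_type = "T"
  )
  sel <- equalize_groups(cells, "T", seed = 3)
  expect_length(sel, 24)
  aged_bc <- cells$barcode[cells$age_group == "aged"]
  expect_true(all(aged_bc %in% sel))
  expect_identical(sel, equalize_groups(cells, "T", seed = 3))
  # already balanced: everything returned
  bal <- cells[c(1:12, 31:42), ]
  expect_setequal(equalize_groups(bal, "T", 1), bal$barcode)
  expect_error(equalize_groups(cells[cells$age_group == "young", ], "T", 1),
               "absent")
})

test_that("group distances match the hand-computed fixture", {
  fx <- make_fixture("two-type-noise")
  t1 <- fx$cells$true_type == "T1"
  d <- group_distances(as.matrix(fx$counts[, t1]), fx$cells$age_group[t1])
  young <- d$distance[d$group == "young"]
  aged <- d$distance[d$group == "aged"]
  expect_equal(young, rep(sqrt(2), 2), tolerance = 1e-12)
  expect_equal(aged, rep(2 * sqrt(2), 2), tolerance = 1e-12)
  expect_equal(log2(mean(aged) / mean(young)), 1, tolerance = 1e-12)

  # all-identical group has zero distances
  same <- matrix(3, 2, 3)
  expect_true(all(group_distances(same, rep("g", 3))$distance == 0))

  # duplicating every cell leaves the per-cell distance multiset unchanged
  v <- as.matrix(fx$counts[, t1])
  d2 <- group_distances(cbind(v, v), rep(fx$cells$age_group[t1], 2))
  expect_equal(sort(d2$distance), sort(rep(d$distance, 2)), tolerance = 1e-12)
})

test_that("noise report excludes under-sized types and flags degenerate ratios", {
  sim <- simulate_counts(small_sim_config(13, n_genes = 150, n_cells = 40))
  cells <- truth_cells(sim)
  # shrink type C's aged arm below the threshold
  drop <- cells$barcode[cells$cell_type == "C" & cells$age_group == "aged"]
  keep_aged_C <- head(drop, 9)
  cells2 <- cells[!(cells$barcode %in% setdiff(drop, keep_aged_C)), ]
  counts2 <- sim$counts[, cells2$barcode]
  nr <- transcriptional_noise(counts2, cells2, analysis_config(seed = 2))
  expect_true("C" %in% nr$excluded$cell_type)
  expect_false("C" %in% nr$summary$cell_type)
  expect_match(nr$excluded$reason[nr$excluded$cell_type == "C"], "fewer than 10")
  # balanced group sizes within each analysed type
  expect_true(all(nr$summary$n_used_per_group >= 10))
  expect_true(all(nr$cell_distances$distance >= 0))
  # no eligible type at an absurd threshold errors
  expect_error(
    transcriptional_noise(counts2, cells2,
                          analysis_config(min_cells_noise = 10000)),
    "no cell type")
})

test_that("log2 noise ratio responds monotonically to planted dispersion inflation", {
  ratios <- vapply(c(1, 1.5, 2, 3), function(phi) {
    nf <- if (phi > 1) c(B = phi) else numeric()
    sim <- simulate_counts(small_sim_config(31, n_genes = 200, n_cells = 50,
                                            noise_inflation = nf))
    cells <- truth_cells(sim)
    nr <- transcriptional_noise(sim$counts, cells, analysis_config(seed = 1))
    nr$summary$log2_ratio_cells[nr$summary$cell_type == "B"]
  }, numeric(1))
  expect_identical(order(ratios), 1:4)  # Spearman rho = 1 on the means
  expect_lt(abs(ratios[1]), 0.15)      # phi = 1 sits near 0
  expect_gt(ratios[4], ratios[1] + 0.3)
})
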