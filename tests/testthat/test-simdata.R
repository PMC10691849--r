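test_that("simulation is deterministic and counts are conserved", {
  cfg <- small_sim_config(seed = 7, n_genes = 120, n_cells = 25)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(as.matrix(s1$counts), as.matrix(s2$counts))
  expect_identical(s1$cells, s2$cells)
  expect_true(all(s1$counts@x >= 0))
  expect_true(all(s1$counts@x == floor(s1$counts@x)))
  # library sizes are the column sums by construction
  expect_equal(unname(Matrix::colSums(s1$counts)),
               unname(colSums(as.matrix(s1$counts))))
  # mito genes lead the gene list
  expect_true(all(startsWith(rownames(s1$counts)[1:10], "MT-")))
})

test_that("adding a sample does not perturb existing samples", {
  cfg8 <- small_sim_config(seed = 11, n_genes = 100, n_cells = 20)
  extra <- dplyr::bind_rows(cfg8$samples,
                            tibble::tibble(sample_id = "A9",
                                           age_group = "aged"))
  cfg9 <- small_sim_config(seed = 11, n_genes = 100, n_cells = 20,
                           samples = extra)
  s8 <- simulate_counts(cfg8)
  s9 <- simulate_counts(cfg9)
  shared <- s8$cells$barcode
  expect_identical(as.matrix(s8$counts[, shared]),
                   as.matrix(s9$counts[, shared]))
})

test_that("null configuration gives exchangeable young and aged cells", {
  # one type, no planted effects: per-gene group comparison should be
  # non-significant for the overwhelming majority of genes
  frac_sig <- sapply(1:4, function(seed) {
    cfg <- sim_config(
      n_genes = 150, n_cells_per_sample = 30,
      cell_types = tibble::tibble(name = "T", prop_young = 1, prop_aged = 1),
      seed = seed
    )
    sim <- simulate_counts(cfg)
    young <- as.matrix(sim$counts[, sim$cells$age_group == "young"])
    aged <- as.matrix(sim$counts[, sim$cells$age_group == "aged"])
    p <- vapply(seq_len(nrow(young)), function(i) {
      wilcoxon_test(young[i, ], aged[i, ])$p
    }, numeric(1))
    mean(p < 0.05)
  })
  expect_gte(mean(frac_sig <= 0.06), 1)  # >=94% of genes null in each seed
})

test_that("age-shifted proportions and planted fold changes are recovered", {
  cfg <- sim_config(
    n_genes = 200, n_cells_per_sample = 500,
    cell_types = tibble::tibble(name = c("A", "B"),
                                prop_young = c(0.5, 0.5),
                                prop_aged = c(0.5, 0.5)),
    planted_degs = tibble::tibble(cell_type = "A", gene = "G00050",
                                  delta = 0.8),
    seed = 5
  )
  sim <- simulate_counts(cfg)
  aged_A <- sim$cells$age_group == "aged" & sim$cells$true_type == "A"
  n_aged <- sum(sim$cells$age_group == "aged")
  # observed aged fraction of type A within 3 binomial SE of 0.5
  se <- sqrt(0.25 / n_aged)
  expect_lt(abs(mean(sim$cells$true_type[sim$cells$age_group == "aged"] == "A") - 0.5),
            3 * se)
  # planted DEG: aged mean ~ exp(delta) x young mean in type A
  young_A <- sim$cells$age_group == "young" & sim$cells$true_type == "A"
  ratio <- mean(sim$counts["G00050", aged_A]) / mean(sim$counts["G00050", young_A])
  expect_gt(ratio, exp(0.8) * 0.75)
  expect_lt(ratio, exp(0.8) * 1.25)
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_config(cell_types = tibble::tibble(
    name = c("A", "B"), prop_young = c(0.6, 0.6), prop_aged = c(0.5, 0.5))),
    "prop_young")
  expect_error(small_sim_config(1, noise_inflation = c(A = 0.5)),
               "noise_inflation")
  expect_error(small_sim_config(1, planted_degs = tibble::tibble(
    cell_type = "A", gene = "NOPE", delta = 1)), "named genes")
  expect_error(small_sim_config(1, n_cells = 0), "n_cells_per_sample")
})

test_that("fixtures match their documented shapes and unknown names error", {
  fx <- make_fixture("tiny-qc")
  qc <- compute_qc(fx$counts)
  expect_identical(sum(qc$n_genes < 200), 2L)
  expect_identical(sum(qc$mito_fraction > 0.05), 1L)
  tn <- make_fixture("two-type-noise")
  expect_identical(dim(tn$counts), c(2L, 8L))
  expect_error(make_fixture("no-such"), "available")
})
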