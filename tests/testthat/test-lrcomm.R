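test_that("detection fractions follow the count>0 and complex-min rules", {
  m <- Matrix::sparseMatrix(
    i = c(1, 1, 1, 2, 3), j = c(1, 2, 3, 1, 1), x = c(1, 2, 3, 5, 1),
    dims = c(3, 20),
    dimnames = list(c("L", "R", "S2"), sprintf("c%02d", 1:20))
  )
  cells <- tibble::tibble(barcode = colnames(m), cell_type = "T")
  fr <- expressed_fraction(m, cells, "L")
  expect_equal(unname(fr["T"]), 3 / 20)
  # complex: minimum over subunits
  fr2 <- expressed_fraction(m, cells, "R;S2")
  expect_equal(unname(fr2["T"]), 1 / 20)
  # all-zero gene is 0 everywhere; unknown gene errors by name
  m2 <- rbind(m, Z = 0)
  expect_equal(unname(expressed_fraction(as(m2, "CsparseMatrix"), cells, "Z")["T"]), 0)
  expect_error(expressed_fraction(m, cells, "NOPE"), "NOPE")
})

test_that("interaction scores are cluster-mean averages with the complex-min rule", {
  m <- matrix(0, 3, 4, dimnames = list(c("L", "R", "R2"), paste0("c", 1:4)))
  m["L", 1:2] <- 2      # sender cluster mean 2
  m["R", 3:4] <- 4      # receiver cluster mean 4
  m["R2", 3:4] <- 0.2
  cells <- tibble::tibble(barcode = paste0("c", 1:4),
                          cell_type = rep(c("A", "B"), each = 2))
  cm <- txnoise:::cluster_means(m, c("L", "R", "R2"), cells$cell_type)
  expect_equal(txnoise:::pair_score(cm, "L", "R", "A", "B"), 3)
  # absent receptor contributes its zero mean
  expect_equal(txnoise:::pair_score(cm, "L", "R", "A", "A"), 1)
  # complex side uses the minimum subunit mean
  expect_equal(txnoise:::pair_score(cm, "L", "R;R2", "A", "B"), (2 + 0.2) / 2)
})

test_that("Monte-Carlo permutation p matches the exhaustive oracle on 8 cells", {
  set.seed(3)
  m <- matrix(stats::runif(2 * 8), 2, 8,
              dimnames = list(c("L", "R"), paste0("c", 1:8)))
  m["L", 1:4] <- m["L", 1:4] + 1.5
  m["R", 5:8] <- m["R", 5:8] + 1.5
  labels <- rep(c("A", "B"), each = 4)
  cells <- tibble::tibble(barcode = colnames(m), cell_type = labels)
  pairs <- lr_pairs("L_R", "L", "R")
  cfg <- analysis_config(n_perm = 4000, seed = 11)
  res <- permutation_test(m, cells, pairs, "young", cfg,
                          senders = "A", receivers = "B")
  p_exact <- oracle_lr_perm_p(m, labels, "L", "R", "A", "B", res$score)
  se <- sqrt(p_exact * (1 - p_exact) / cfg$n_perm)
  expect_lt(abs(res$p - p_exact), 3 * se + 1 / cfg$n_perm)
  # zero observed score gives p = 1 under the add-one convention
  m0 <- m; m0["L", ] <- 0; m0["R", ] <- 0
  res0 <- permutation_test(m0, cells, pairs, "young", cfg,
                           senders = "A", receivers = "B")
  expect_equal(res0$p, 1)
})

test_that("pair gating, classification, and planted group-specific activity work", {
  lrt <- tibble::tibble(ligand = "G00021", receptor = "G00022",
                        sender = "A", receiver = "B", active_in = "young")
  hits <- vapply(1:10, function(seed) {
    sim <- simulate_counts(small_sim_config(seed + 300, n_genes = 150,
                                            n_cells = 50, lr_truth = lrt))
    norm <- lognormalize(sim$counts)
    cells <- truth_cells(sim)
    pairs <- lr_pairs("P1", "G00021", "G00022")
    kept <- filter_lr_pairs(sim$counts, cells, pairs)
    if (nrow(kept) == 0) return(FALSE)
    cfg <- analysis_config(n_perm = 400, seed = seed)
    res <- purrr::map(c("young", "aged"), function(g) {
      sel <- cells$age_group == g
      permutation_test(norm[, cells$barcode[sel], drop = FALSE],
                       cells[sel, ], kept, g, cfg,
                       senders = c("A", "B"), receivers = c("A", "B"))
    })
    comp <- compare_groups(res[[1]], res[[2]])
    cls <- comp$classified
    cls$class[cls$sender == "A" & cls$receiver == "B"] == "young_only"
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("comparison classifies shared pairs and rejects mismatched universes", {
  base <- tibble::tibble(pair_id = "P", sender = "A", receiver = "B",
                         group = "young", score = 1, p = 0.001,
                         significant = TRUE)
  aged <- dplyr::mutate(base, group = "aged")
  comp <- compare_groups(base, aged)
  expect_equal(comp$classified$class, "shared")
  expect_equal(comp$count_diff$diff, 0)
  # empty significant sets: all counts zero
  comp0 <- compare_groups(dplyr::mutate(base, significant = FALSE),
                          dplyr::mutate(aged, significant = FALSE))
  expect_true(all(comp0$count_diff$n_young == 0) &&
                all(comp0$count_diff$n_aged == 0))
  expect_error(compare_groups(base, dplyr::mutate(aged, sender = "C")),
               "universe")
})

test_that("label-shuffled nulls give super-uniform permutation p-values", {
  sim <- simulate_counts(small_sim_config(55, n_genes = 120, n_cells = 30))
  norm <- lognormalize(sim$counts)
  cells <- truth_cells(sim)
  young <- cells[cells$age_group == "young", ]
  normy <- norm[, young$barcode]
  set.seed(99)
  genes <- rownames(norm)[31:70]
  ps <- vapply(1:300, function(i) {
    gl <- sample(genes, 2)
    pairs <- lr_pairs("P", gl[1], gl[2])
    shuffled <- dplyr::mutate(young, cell_type = sample(.data$cell_type))
    res <- permutation_test(normy, shuffled, pairs, "young",
                            analysis_config(n_perm = 200, seed = i),
                            senders = "A", receivers = "B")
    res$p
  }, numeric(1))
  expect_lte(mean(ps < 0.01), 0.02)
})
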