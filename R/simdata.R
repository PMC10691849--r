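#' Simulation configuration for synthetic snRNA-seq data
#'
#' Describes a synthetic single-nucleus experiment: cell types with
#' age-group-specific proportions, a two-group (young/aged) multi-sample
#' design, negative-binomial UMI counts with per-cell lognormal library-size
#' heterogeneity, and planted effects -- differential genes, dispersion
#' inflation ("transcriptional noise") in chosen aged cell types, marker
#' genes, and condition-specific ligand--receptor activity. The default
#' design mirrors a two-group primate testis study: four young and four aged
#' samples and a catalogue of germ and somatic cell types.
#'
#' Counts for gene g in cell i are NB(mu, size) with
#' `mu = profile[g, type] * libfactor_i` and `size = nb_dispersion`
#' (variance `mu + mu^2/size`). For aged cells of a noise-inflated type the
#' size is divided by `phi >= 1`, increasing cell-to-cell dispersion at a
#' fixed mean; planted DEGs multiply the mean by `exp(delta)` in aged cells
#' of the stated type.
#'
#' @param n_genes Number of genes; the first `mito_gene_count` are named
#'   with the `MT-` prefix.
#' @param cell_types Data frame with columns `name`, `prop_young`,
#'   `prop_aged`; proportions must sum to 1 within each group.
#' @param n_cells_per_sample Cells simulated per sample.
#' @param samples Data frame with columns `sample_id`, `age_group`
#'   (`"young"`/`"aged"`).
#' @param nb_dispersion Baseline NB size parameter (larger = less noisy).
#' @param noise_inflation Named numeric, cell type -> phi >= 1; the NB size
#'   is divided by phi in aged cells of that type.
#' @param planted_degs Data frame `cell_type`, `gene`, `delta` (natural-log
#'   fold change applied in aged cells of that type).
#' @param marker_genes Named list, cell type -> character vector of genes
#'   upregulated in that type.
#' @param marker_strength Natural-log upregulation applied to marker genes.
#' @param lr_truth Data frame `ligand`, `receptor`, `sender`, `receiver`,
#'   `active_in` (one of `"young"`, `"aged"`, `"young;aged"`).
#' @param lr_strength Natural-log upregulation of ligand in sender cells and
#'   receptor in receiver cells when the pair is active.
#' @param mito_gene_count Number of leading mitochondrial genes.
#' @param libsize_meanlog,libsize_sdlog Lognormal parameters of the per-cell
#'   library-size factor.
#' @param seed Integer master seed; split into named substreams per sample
#'   so adding a sample does not perturb the others.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 200, n_cells_per_sample = 50, seed = 1)
#' sim <- simulate_counts(cfg)
#' dim(sim$counts)
sim_config <- function(n_genes = 1000,
                       cell_types = NULL,
                       n_cells_per_sample = 500,
                       samples = NULL,
                       nb_dispersion = 2,
                       noise_inflation = numeric(),
                       planted_degs = NULL,
                       marker_genes = NULL,
                       marker_strength = 1.5,
                       lr_truth = NULL,
                       lr_strength = 2,
                       mito_gene_count = 10,
                       libsize_meanlog = log(2500),
                       libsize_sdlog = 0.35,
                       seed = 1L) {
  if (is.null(cell_types)) {
    nm <- c("SSC", "Diff.SPG", "EarlySPC", "LateSPC", "EarlyRS", "LateRS",
            "Elongating", "Elongated", "Sertoli", "ImmLeydig", "Leydig",
            "PMC", "Pericyte", "VSMC", "EC")
    cell_types <- tibble(
      name = nm,
      prop_young = rep(1 / length(nm), length(nm)),
      prop_aged = rep(1 / length(nm), length(nm))
    )
  }
  cell_types <- as_tibble(cell_types)
  if (is.null(samples)) {
    samples <- tibble(
      sample_id = c(paste0("Y", 1:4), paste0("A", 1:4)),
      age_group = rep(c("young", "aged"), each = 4)
    )
  }
  samples <- as_tibble(samples)
  gene_ids <- make_gene_ids(n_genes, mito_gene_count)
  if (is.null(marker_genes)) {
    # disjoint 8-gene panels drawn from the non-mito tail, deterministic;
    # panels of this size give stable module-score annotation
    k <- 8
    avail <- gene_ids[(mito_gene_count + 1):n_genes]
    need <- k * nrow(cell_types)
    if (need > length(avail)) abort("invalid `marker_genes`: not enough genes for default panels")
    picks <- avail[seq_len(need)]
    marker_genes <- split(picks, rep(cell_types$name, each = k))[cell_types$name]
  }
  planted_degs <- if (is.null(planted_degs)) {
    tibble(cell_type = character(), gene = character(), delta = numeric())
  } else as_tibble(planted_degs)
  lr_truth <- if (is.null(lr_truth)) {
    tibble(ligand = character(), receptor = character(),
           sender = character(), receiver = character(),
           active_in = character())
  } else as_tibble(lr_truth)

  cfg <- structure(list(
    n_genes = as.integer(n_genes), cell_types = cell_types,
    n_cells_per_sample = as.integer(n_cells_per_sample), samples = samples,
    nb_dispersion = nb_dispersion, noise_inflation = noise_inflation,
    planted_degs = planted_degs, marker_genes = marker_genes,
    marker_strength = marker_strength, lr_truth = lr_truth,
    lr_strength = lr_strength, mito_gene_count = as.integer(mito_gene_count),
    libsize_meanlog = libsize_meanlog, libsize_sdlog = libsize_sdlog,
    gene_ids = gene_ids, seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
}

make_gene_ids <- function(n_genes, mito_gene_count) {
  if (mito_gene_count > n_genes) abort("invalid `mito_gene_count`: exceeds `n_genes`")
  c(sprintf("MT-%d", seq_len(mito_gene_count)),
    sprintf("G%05d", seq_len(n_genes - mito_gene_count)))
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) abort(sprintf("invalid `%s`: %s", field, msg))
  }
  ct <- cfg$cell_types
  chk(all(c("name", "prop_young", "prop_aged") %in% names(ct)),
      "cell_types", "needs columns name, prop_young, prop_aged")
  chk(!anyDuplicated(ct$name), "cell_types", "duplicated type names")
  chk(abs(sum(ct$prop_young) - 1) < 1e-9, "cell_types",
      "prop_young must sum to 1")
  chk(abs(sum(ct$prop_aged) - 1) < 1e-9, "cell_types",
      "prop_aged must sum to 1")
  chk(all(ct$prop_young >= 0) && all(ct$prop_aged >= 0), "cell_types",
      "proportions must be nonnegative")
  chk(cfg$n_cells_per_sample >= 1, "n_cells_per_sample", "must be >= 1")
  chk(cfg$nb_dispersion > 0, "nb_dispersion", "must be positive")
  chk(all(c("sample_id", "age_group") %in% names(cfg$samples)),
      "samples", "needs columns sample_id, age_group")
  chk(all(cfg$samples$age_group %in% c("young", "aged")),
      "samples", "age_group must be 'young' or 'aged'")
  chk(!anyDuplicated(cfg$samples$sample_id), "samples",
      "duplicated sample ids")
  if (length(cfg$noise_inflation)) {
    chk(!is.null(names(cfg$noise_inflation)) &&
          all(names(cfg$noise_inflation) %in% ct$name),
        "noise_inflation", "names must be cell types")
    chk(all(cfg$noise_inflation >= 1), "noise_inflation", "phi must be >= 1")
  }
  all_named <- c(unlist(cfg$marker_genes, use.names = FALSE),
                 cfg$planted_degs$gene, cfg$lr_truth$ligand,
                 cfg$lr_truth$receptor)
  chk(all(all_named %in% cfg$gene_ids), "planted genes",
      "all named genes must exist among the simulated gene ids")
  chk(all(cfg$planted_degs$cell_type %in% ct$name), "planted_degs",
      "cell_type must be a simulated type")
  if (nrow(cfg$planted_degs)) {
    dup <- cfg$planted_degs |> count(.data$cell_type, .data$gene) |>
      filter(.data$n > 1)
    chk(nrow(dup) == 0, "planted_degs", "genes must be unique per cell type")
  }
  chk(all(cfg$lr_truth$sender %in% ct$name) &&
        all(cfg$lr_truth$receiver %in% ct$name),
      "lr_truth", "sender/receiver must be simulated types")
  if (nrow(cfg$lr_truth)) {
    groups <- strsplit(cfg$lr_truth$active_in, ";", fixed = TRUE)
    chk(all(unlist(groups) %in% c("young", "aged")), "lr_truth",
        "active_in must be 'young', 'aged' or 'young;aged'")
  }
  cfg
}

# Mean-profile matrix (genes x types x groups, collapsed to a list of
# matrices by group): shared lognormal baseline, type-specific jitter,
# marker upregulation, then planted DEG and LR multipliers per group.
sim_profiles <- function(cfg) {
  types <- cfg$cell_types$name
  base <- with_seed(substream_seed(cfg$seed, "profiles"), {
    b <- rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1)
    jit <- vapply(types, function(ty) {
      j <- rep(1, cfg$n_genes)
      idx <- sample.int(cfg$n_genes, size = max(1L, cfg$n_genes %/% 10))
      j[idx] <- rlnorm(length(idx), 0, 0.5)
      j
    }, numeric(cfg$n_genes))
    b * jit
  })
  dimnames(base) <- list(cfg$gene_ids, types)
  for (ty in names(cfg$marker_genes)) {
    g <- intersect(cfg$marker_genes[[ty]], cfg$gene_ids)
    base[g, ty] <- base[g, ty] * exp(cfg$marker_strength)
  }
  out <- list(young = base, aged = base)
  if (nrow(cfg$planted_degs)) {
    for (i in seq_len(nrow(cfg$planted_degs))) {
      d <- cfg$planted_degs[i, ]
      out$aged[d$gene, d$cell_type] <- out$aged[d$gene, d$cell_type] * exp(d$delta)
    }
  }
  if (nrow(cfg$lr_truth)) {
    for (i in seq_len(nrow(cfg$lr_truth))) {
      p <- cfg$lr_truth[i, ]
      for (grp in strsplit(p$active_in, ";", fixed = TRUE)[[1]]) {
        out[[grp]][p$ligand, p$sender] <- out[[grp]][p$ligand, p$sender] * exp(cfg$lr_strength)
        out[[grp]][p$receptor, p$receiver] <- out[[grp]][p$receptor, p$receiver] * exp(cfg$lr_strength)
      }
    }
  }
  # normalise each (type, group) profile to sum 1: relative expression,
  # so the lognormal library factor sets the expected depth
  lapply(out, function(m) sweep(m, 2, Matrix::colSums(m), "/"))
}

#' Simulate a synthetic snRNA-seq dataset
#'
#' Draws seeded negative-binomial UMI counts under a [sim_config()] design
#' and returns the count matrix, per-cell metadata and ground-truth tables
#' for parameter-recovery testing. Identical config and seed give
#' bit-identical output; each sample has its own named RNG substream.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"sim_data"`:
#'   \describe{
#'     \item{counts}{sparse `dgCMatrix`, genes x cells, integer UMIs}
#'     \item{cells}{tibble: `barcode`, `sample_id`, `age_group`, `true_type`}
#'     \item{truth}{list of tibbles: `cell_truth`, `deg_truth`,
#'       `noise_truth`, `lr_truth`}
#'   }
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  validate_sim_config(config)
  profiles <- sim_profiles(config)
  types <- config$cell_types$name
  infl <- setNames(rep(1, length(types)), types)
  if (length(config$noise_inflation)) {
    infl[names(config$noise_inflation)] <- config$noise_inflation
  }
  per_sample <- map(seq_len(nrow(config$samples)), function(si) {
    sm <- config$samples[si, ]
    n <- config$n_cells_per_sample
    with_seed(substream_seed(config$seed, "sample", sm$sample_id), {
      props <- if (sm$age_group == "young") config$cell_types$prop_young
               else config$cell_types$prop_aged
      type_i <- sample(types, n, replace = TRUE, prob = props)
      libf <- rlnorm(n, config$libsize_meanlog, config$libsize_sdlog)
      prof <- profiles[[sm$age_group]]
      size_by_type <- config$nb_dispersion /
        (if (sm$age_group == "aged") infl else setNames(rep(1, length(types)), types))
      cnt <- vapply(seq_len(n), function(i) {
        mu <- prof[, type_i[i]] * libf[i]
        rnbinom(config$n_genes, mu = mu, size = size_by_type[[type_i[i]]])
      }, numeric(config$n_genes))
      list(
        counts = cnt,
        cells = tibble(
          barcode = sprintf("%s_C%05d", sm$sample_id, seq_len(n)),
          sample_id = sm$sample_id, age_group = sm$age_group,
          true_type = type_i
        )
      )
    })
  })
  counts <- do.call(cbind, map(per_sample, "counts"))
  cells <- list_rbind(map(per_sample, "cells"))
  dimnames(counts) <- list(config$gene_ids, cells$barcode)
  counts <- as_dgc(counts)
  truth <- list(
    cell_truth = cells,
    deg_truth = config$planted_degs,
    noise_truth = tibble(cell_type = types, phi = unname(infl[types])),
    lr_truth = config$lr_truth
  )
  structure(list(counts = counts, cells = cells, truth = truth,
                 config = config),
            class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf("<sim_data> %d genes x %d cells, %d samples, %d cell types\n",
              nrow(x$counts), ncol(x$counts), nrow(x$config$samples),
              nrow(x$config$cell_types)))
  invisible(x)
}

#' Built-in miniature fixtures
#'
#' Small hand-specified datasets whose expected outputs are documented
#' constants, used for worked examples and exact tests.
#'
#' \describe{
#'   \item{`"tiny-qc"`}{250 genes x 6 cells; cells `low1`, `low2` detect
#'     fewer than 200 genes, `mito1` has mitochondrial fraction 0.06, and
#'     `ok1`--`ok3` pass the default QC filters.}
#'   \item{`"two-type-noise"`}{2 genes x 8 cells, two cell types each with
#'     two young cells at (0,0) and (2,2) and two aged cells at (0,0) and
#'     (4,4): group distances are sqrt(2) (young) and 2*sqrt(2) (aged), so
#'     the aged/young log2 distance ratio is exactly 1.}
#'   \item{`"lr-toy"`}{20 genes x 40 cells, two types; gene `LIG` is high
#'     in sender type A, gene `REC` high in receiver type B.}
#' }
#'
#' @param name Fixture name.
#' @return A list with `counts` (sparse matrix) and `cells` (tibble).
#' @export
#' @examples
#' fx <- make_fixture("tiny-qc")
#' ncol(fx$counts)
make_fixture <- function(name) {
  fixtures <- c("tiny-qc", "two-type-noise", "lr-toy")
  if (!is.character(name) || length(name) != 1 || !(name %in% fixtures)) {
    abort(sprintf("unknown fixture %s; available: %s",
                  deparse(substitute(name)), paste(fixtures, collapse = ", ")))
  }
  switch(name,
    "tiny-qc" = fixture_tiny_qc(),
    "two-type-noise" = fixture_two_type_noise(),
    "lr-toy" = fixture_lr_toy()
  )
}

fixture_tiny_qc <- function() {
  n_genes <- 250
  genes <- make_gene_ids(n_genes, 5)
  m <- matrix(0L, n_genes, 6,
              dimnames = list(genes, c("low1", "low2", "mito1",
                                       "ok1", "ok2", "ok3")))
  nonmito <- 6:n_genes
  # low1/low2: only 50 genes detected (< 200)
  m[nonmito[1:50], "low1"] <- 2L
  m[nonmito[1:50], "low2"] <- 3L
  # mito1: 200 non-mito genes at 1 + mito depth giving fraction 0.06
  m[nonmito[1:200], "mito1"] <- 2L           # 400 non-mito UMIs
  m["MT-1", "mito1"] <- 26L                  # hits 200 genes... plus MT-1
  # 26 / 426 ~ 0.061 > 0.05
  for (cc in c("ok1", "ok2", "ok3")) {
    m[nonmito[1:220], cc] <- 1L
    m["MT-1", cc] <- 5L                      # 5 / 225 ~ 0.022 <= 0.05
  }
  list(counts = as_dgc(m),
       cells = tibble(barcode = colnames(m),
                      sample_id = "S1",
                      age_group = rep(c("young", "aged"), 3),
                      true_type = "T"))
}

fixture_two_type_noise <- function() {
  vals <- cbind(c(0, 0), c(2, 2), c(0, 0), c(4, 4))
  m <- cbind(vals, vals)
  dimnames(m) <- list(c("G1", "G2"),
                      c("t1y1", "t1y2", "t1a1", "t1a2",
                        "t2y1", "t2y2", "t2a1", "t2a2"))
  list(counts = as_dgc(m),
       cells = tibble(
         barcode = colnames(m),
         sample_id = rep(c("Y1", "Y1", "A1", "A1"), 2),
         age_group = rep(c("young", "young", "aged", "aged"), 2),
         true_type = rep(c("T1", "T2"), each = 4)))
}

fixture_lr_toy <- function() {
  genes <- c("LIG", "REC", sprintf("BG%02d", 1:18))
  # fixture is a documented constant; internal fixed seed
  m <- with_seed(42L, matrix(stats::rpois(20 * 40, 1), 20, 40,
                             dimnames = list(genes, sprintf("c%02d", 1:40))))
  types <- rep(c("A", "B"), each = 20)
  m["LIG", types == "A"] <- 20L
  m["REC", types == "B"] <- 20L
  storage.mode(m) <- "integer"
  list(counts = as_dgc(m),
       cells = tibble(barcode = colnames(m),
                      sample_id = rep(c("Y1", "A1"), 20),
                      age_group = rep(c("young", "aged"), 20),
                      true_type = types))
}

#' Write a simulated dataset to a 10x-style directory
#'
#' Writes `matrix.mtx`, `features.tsv`, `barcodes.tsv`, `metadata.tsv` and,
#' when ground truth is present, `truth_*.tsv` tables.
#'
#' @param sim A `"sim_data"` object (or any list with `counts` and `cells`).
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_sim_data <- function(sim, dir) {
  write_tenx(sim$counts, dir)
  readr::write_tsv(sim$cells, file.path(dir, "metadata.tsv"))
  if (!is.null(sim$truth)) {
    for (nm in setdiff(names(sim$truth), "cell_truth")) {
      readr::write_tsv(sim$truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")))
    }
  }
  invisible(dir)
}
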