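test_that("config validation rejects unstable or impossible settings", {
  expect_error(sim_config(codon_length = 9), "codon_length")
  expect_error(sim_config(omega_background = 0), "omega")
  expect_error(sim_config(omega_per_family = rep(-1, 40)), "omega")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(n_datasets = 1), "n_datasets")
  expect_error(simulate_codon_pair(300, 0, 0.1, 1), "omega")
  expect_error(simulate_codon_pair(5, 1, 0.1, 1), "codons")
})

test_that("zero divergence yields identical family members and pairs", {
  p <- simulate_codon_pair(50, 1, 0, seed = 3)
  expect_identical(p$cds_a, p$cds_b)

  cfg <- sim_config(n_datasets = 3, n_families = 5, branch_scale = 0,
                    duplication_rate = 0, seed = 9)
  sim <- simulate_repertoires(cfg)
  by_fam <- split(sim$records$cds, sim$truth$sequences$family)
  for (fam in by_fam) expect_length(unique(fam), 1L)
})

test_that("a fixed seed reproduces the whole simulation byte for byte", {
  cfg <- sim_config(n_datasets = 4, n_families = 8, seed = 17)
  a <- simulate_repertoires(cfg)
  b <- simulate_repertoires(cfg)
  expect_identical(a, b)
  expect_identical(simulate_expression(a$truth, cfg),
                   simulate_expression(b$truth, cfg))
})

test_that("secretion labels are family-level and effectors secreted", {
  cfg <- sim_config(n_datasets = 8, n_families = 30, effector_fraction = 0.2,
                    seed = 5)
  sim <- simulate_repertoires(cfg)
  ann <- sim$annotations
  fam <- sim$truth$sequences$family[match(ann$id, sim$truth$sequences$id)]
  for (col in c("has_signal_peptide", "has_tm_domain", "has_nls")) {
    per_fam <- tapply(ann[[col]], fam, function(x) length(unique(x)))
    expect_true(all(per_fam == 1L))
  }
  eff <- sim$truth$sequences$effector[match(ann$id, sim$truth$sequences$id)]
  expect_true(all(ann$has_signal_peptide[eff]))
  expect_false(any(ann$has_tm_domain[eff]))
})

test_that("pioneer families are unannotated and confined to one dataset", {
  cfg <- sim_config(n_datasets = 8, n_families = 40, effector_fraction = 0.3,
                    pioneer_fraction = 0.5, seed = 21)
  sim <- simulate_repertoires(cfg)
  fam <- sim$truth$families
  expect_gt(sum(fam$pioneer), 0)
  pio_seqs <- sim$truth$sequences[sim$truth$sequences$pioneer, ]
  for (f in unique(pio_seqs$family)) {
    expect_length(unique(pio_seqs$dataset[pio_seqs$family == f]), 1L)
  }
  ann <- sim$annotations
  pio <- ann$id %in% pio_seqs$id
  expect_true(all(is.na(ann$best_db_hit_evalue[pio])))
  expect_false(any(ann$has_pfamA[pio]))
})

test_that("every sequence belongs to exactly one family", {
  sim <- simulate_repertoires(sim_config(n_datasets = 5, n_families = 12,
                                         duplication_rate = 0.5, seed = 2))
  expect_false(anyDuplicated(sim$truth$sequences$id) > 0)
  expect_setequal(sim$records$id, sim$truth$sequences$id)
})

test_that("similarity edges are symmetric, floored, and thresholded", {
  rec <- data.frame(id = c("a", "b", "c"),
                    protein = c("MKVLTAGHIE", "MKVLTAGHIE", "QQWWSSPPRR"),
                    stringsAsFactors = FALSE)
  e <- emit_similarity_edges(rec)
  ab <- e[e$query == "a" & e$subject == "b", ]
  expect_equal(ab$identity, 100)
  expect_equal(ab$evalue, 1e-180)  # bitscore 100 -> proxy floored
  ba <- e[e$query == "b" & e$subject == "a", ]
  expect_equal(ab$identity, ba$identity)
  # c shares 0/10 positions with a and b: below the 20 % cutoff, no edge
  expect_false(any(e$query == "c" | e$subject == "c"))
})

test_that("expression simulation is head-biased only for effectors", {
  cfg <- sim_config(n_datasets = 2, n_families = 20, effector_fraction = 0.3,
                    fold_change = 8, seed = 31)
  sim <- simulate_repertoires(cfg)
  counts <- simulate_expression(sim$truth, cfg)
  expect_named(counts, sim$truth$datasets$dataset[
    sim$truth$datasets$dataset %in% sim$truth$sequences$dataset])
  cm <- counts[[1]]
  head_cols <- cm$design$library[cm$design$tissue == "head"]
  body_cols <- cm$design$library[cm$design$tissue == "body"]
  tr <- sim$truth$sequences[match(rownames(cm$counts),
                                  sim$truth$sequences$id), ]
  ratio <- rowMeans(cm$counts[, head_cols]) /
    pmax(rowMeans(cm$counts[, body_cols]), 1)
  expect_gt(median(ratio[tr$effector]), 4)
  expect_lt(median(ratio[!tr$effector]), 2)
})

test_that("a zero-mean transcript keeps its all-zero row", {
  cfg <- sim_config(n_datasets = 2, n_families = 4, effector_fraction = 0,
                    seed = 8)
  sim <- simulate_repertoires(cfg)
  ids <- sim$truth$sequences$id
  means <- stats::setNames(rep(50, length(ids)), ids)
  ds1 <- sim$truth$sequences$dataset[1]
  zero_id <- sim$truth$sequences$id[sim$truth$sequences$dataset == ds1][1]
  means[zero_id] <- 0
  counts <- simulate_expression(sim$truth, cfg, base_means = means)
  expect_true(zero_id %in% rownames(counts[[ds1]]$counts))
  expect_true(all(counts[[ds1]]$counts[zero_id, ] == 0))
})
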