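test_that("noiseless mixture with no planted effects reproduces M %*% t(Omega) exactly", {
  cfg <- methylome_sim_config(n_subjects = 6, n_cpgs = 400, noise_sd = 0,
                              n_responsive_cpgs = 0, batch_shift = 0,
                              seed = 11)
  sim <- simulate_methylome(cfg)
  expect_equal(max(abs(sim$Y - sim$truth$true_M %*% t(sim$truth$true_Omega))),
               0)
  expect_true(all(sim$Y >= 0 & sim$Y <= 1))
})

test_that("planted responsive CpGs carry the configured shift, recomputed from the emitted matrix", {
  cfg <- methylome_sim_config(n_subjects = 10, n_cpgs = 1000, noise_sd = 0,
                              n_responsive_cpgs = 50, delta_beta = 0.10,
                              seed = 21)
  sim <- simulate_methylome(cfg)
  expect_length(sim$truth$responsive_cpg_ids, 50)
  expect_true(all(sim$truth$responsive_cpg_ids %in% rownames(sim$Y)))

  hyper <- names(sim$truth$responsive_direction)[
    sim$truth$responsive_direction == "hyper"]
  resp <- sim$sheet$subject_id %in% sim$truth$responder_subjects
  bl_cols <- sim$sheet$sample_id[resp & sim$sheet$timepoint == "BL"]
  m3_cols <- sim$sheet$sample_id[resp & sim$sheet$timepoint == "M3"]
  observed <- mean(sim$Y[hyper, m3_cols]) - mean(sim$Y[hyper, bl_cols])
  # clip-aware oracle from the stored truth
  clean <- sim$truth$true_M %*% t(sim$truth$true_Omega)
  expected <- mean(pmin(clean[hyper, m3_cols] + 0.10, 1)) -
    mean(clean[hyper, bl_cols])
  expect_equal(observed, expected, tolerance = 1e-12)
  expect_gt(observed, 0.07)   # near the planted 0.10 up to clipping
})

test_that("simulators are deterministic in the seed and vary across seeds", {
  cfg <- methylome_sim_config(n_subjects = 4, n_cpgs = 100, seed = 5)
  expect_identical(simulate_methylome(cfg), simulate_methylome(cfg))
  cfg2 <- cfg; cfg2$seed <- 6L
  expect_false(identical(simulate_methylome(cfg)$Y,
                         simulate_methylome(cfg2)$Y))

  expect_identical(simulate_genesets(seed = 3), simulate_genesets(seed = 3))
  expect_identical(simulate_genotypes(n_samples = 50, n_snps = 10, seed = 4),
                   simulate_genotypes(n_samples = 50, n_snps = 10, seed = 4))
  expect_false(identical(simulate_genotypes(n_samples = 50, n_snps = 10,
                                            seed = 4)$genotypes,
                         simulate_genotypes(n_samples = 50, n_snps = 10,
                                            seed = 5)$genotypes))
})

test_that("simulator invariants hold across configurations", {
  for (s in 1:5) {
    cfg <- methylome_sim_config(n_subjects = 3 + s, n_cpgs = 200,
                                n_celltypes_true = 1 + (s %% 3),
                                noise_sd = 0.02 * s,
                                n_responsive_cpgs = 10 * s,
                                batch_labels = c("b1", "b2"),
                                batch_shift = c(b1 = 0, b2 = 0.02),
                                seed = s)
    sim <- simulate_methylome(cfg)
    expect_true(all(sim$Y >= 0 & sim$Y <= 1))
    expect_lt(max(abs(rowSums(sim$truth$true_Omega) - 1)), 1e-9)
    expect_true(all(sim$truth$true_M >= 0 & sim$truth$true_M <= 1))
    expect_true(all(sim$truth$responsive_cpg_ids %in% rownames(sim$Y)))
    expect_true(all(sim$sheet$sample_id %in% colnames(sim$Y)))
    # paired structure: every subject at every timepoint
    expect_true(all(table(sim$sheet$subject_id, sim$sheet$timepoint) == 1))
  }
})

test_that("simulator rejects invalid configurations", {
  expect_error(methylome_sim_config(n_celltypes_true = 0), "cell type")
  expect_error(methylome_sim_config(timepoints = "BL"), "2 timepoint")
  expect_error(methylome_sim_config(n_responsive_cpgs = 10, delta_beta = 1.2),
               "delta_beta")
  expect_error(methylome_sim_config(noise_sd = -1), "noise_sd")
})

test_that("gene-set simulator plants disjoint clusters at zero background overlap", {
  gs <- simulate_genesets(n_clusters = 2, sets_per_cluster = 5,
                          genes_per_set = 20, within_cluster_pool = 40,
                          universe_size = 200,
                          background_overlap_rate = 0, seed = 7)
  labs <- gs$truth
  for (a in names(labs)) for (b in names(labs)) {
    if (labs[a] != labs[b])
      expect_length(intersect(gs$collection[[a]], gs$collection[[b]]), 0)
  }
})

test_that("within-cluster Jaccard exceeds between-cluster Jaccard (brute force over all pairs)", {
  gs <- simulate_genesets(n_clusters = 3, sets_per_cluster = 10,
                          genes_per_set = 30, within_cluster_pool = 60,
                          universe_size = 1000,
                          background_overlap_rate = 0.02, seed = 9)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  nm <- names(gs$truth)
  within <- between <- numeric(0)
  for (i in seq_along(nm)) for (j in seq_len(i - 1)) {
    v <- jac(gs$collection[[nm[i]]], gs$collection[[nm[j]]])
    if (gs$truth[nm[i]] == gs$truth[nm[j]]) within <- c(within, v)
    else between <- c(between, v)
  }
  expect_gt(mean(within), mean(between))
  expect_gt(mean(within), 0.2)
})

test_that("degenerate gene-set configurations behave", {
  gs <- simulate_genesets(n_clusters = 1, sets_per_cluster = 1,
                          genes_per_set = 10, within_cluster_pool = 10,
                          universe_size = 20, seed = 2)
  expect_length(gs$collection, 1)
  expect_error(simulate_genesets(background_overlap_rate = 1), "overlap_rate")
  expect_error(simulate_genesets(genes_per_set = 50,
                                 within_cluster_pool = 40), "pool")
})

test_that("genotype simulator respects HWE structure, MAF range and planted effects", {
  sim <- simulate_genotypes(n_samples = 2000, n_snps = 20,
                            maf_range = c(0.1, 0.4), causal_snp_idx = 3,
                            or_binary = 1.6, seed = 13)
  g <- sim$genotypes
  expect_true(all(g %in% c(0, 1, 2)))
  af <- colMeans(g) / 2
  # empirical frequencies near their drawn values, which sit in the range
  expect_true(all(abs(af - sim$truth$allele_freq) < 0.05))
  expect_true(all(sim$truth$allele_freq >= 0.1 &
                    sim$truth$allele_freq <= 0.4))
  # cases carry more alt alleles at the causal SNP (contingency counting)
  dos <- g[, sim$truth$causal_snp]
  y <- sim$phenotypes$response
  f_case <- sum(dos[y == 1]) / (2 * sum(y == 1))
  f_ctrl <- sum(dos[y == 0]) / (2 * sum(y == 0))
  expect_gt(f_case, f_ctrl)

  null <- simulate_genotypes(n_samples = 100, n_snps = 5, or_binary = 1,
                             beta_quant = 0, seed = 1)
  expect_true(all(null$genotypes %in% c(0, 1, 2)))
  expect_error(simulate_genotypes(causal_snp_idx = 99, n_snps = 5),
               "out of range")
})
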