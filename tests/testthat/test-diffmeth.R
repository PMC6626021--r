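test_that("probe filter applies detection-P and SNP rules with per-rule counts", {
  d <- null_beta_design(n_subjects = 4, n_cpgs = 10, seed = 2)
  idf <- filter_probes(d$Y)
  expect_equal(idf$report$n_removed, 0)
  expect_equal(idf$Y, d$Y)

  det <- matrix(0.001, nrow(d$Y), ncol(d$Y), dimnames = dimnames(d$Y))
  det["cpg00005", 3] <- 0.02          # fails in one sample -> dropped
  spec <- probe_filter_spec(snp_probe_list = c("cpg00001", "cpg00002"))
  out <- filter_probes(d$Y, spec, detection_p = det)
  expect_equal(nrow(out$Y), 7)
  expect_equal(out$report$removed_detection, 1)
  expect_equal(out$report$removed_snp_probe, 2)
  expect_setdiff <- setdiff(rownames(d$Y),
                            c("cpg00001", "cpg00002", "cpg00005"))
  expect_equal(rownames(out$Y), expect_setdiff)

  # sex-chromosome probes are retained by default
  chrom <- setNames(rep(c("chrX", "chr1"), each = 5), rownames(d$Y))
  keep_xy <- filter_probes(d$Y, probe_filter_spec(chromosome = chrom))
  expect_equal(nrow(keep_xy$Y), 10)
  drop_xy <- filter_probes(d$Y, probe_filter_spec(chromosome = chrom,
                                                  drop_sex_chromosomes = TRUE))
  expect_equal(drop_xy$report$removed_sex_chromosome, 5)

  expect_warning(filter_probes(d$Y,
                               probe_filter_spec(snp_probe_list = "nope")),
                 "not present")
})

test_that("covariate-free paired model reproduces the classical paired t-test to 1e-10", {
  d <- null_beta_design(n_subjects = 6, n_cpgs = 40, sd = 0.05, seed = 77)
  dm <- fit_paired_lm(d$Y, d$sheet, design_spec(contrast = c("BL", "M3")))
  subj <- unique(d$sheet$subject_id)
  for (i in seq_len(nrow(d$Y))) {
    bl <- d$Y[i, paste0(subj, "_BL")]
    m3 <- d$Y[i, paste0(subj, "_M3")]
    tt <- t.test(m3, bl, paired = TRUE)
    expect_equal(dm$p_raw[i], tt$p.value, tolerance = 1e-10)
    expect_equal(dm$t_stat[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(dm$delta_beta[i], mean(m3 - bl), tolerance = 1e-12)
  }
})

test_that("constant betas give zero effects and ns labels everywhere", {
  d <- null_beta_design(n_subjects = 5, n_cpgs = 12, sd = 0, seed = 1)
  d$Y[] <- rep(runif(nrow(d$Y)), ncol(d$Y))   # CpG-specific constants
  dm <- fit_paired_lm(d$Y, d$sheet)
  expect_true(all(dm$delta_beta == 0))
  expect_true(all(dm$label == "ns"))
})

test_that("covariates are accepted, collinearity is named, small designs are rejected", {
  cfg <- methylome_sim_config(n_subjects = 8, n_cpgs = 60, noise_sd = 0.04,
                              n_responsive_cpgs = 0, seed = 12)
  sim <- simulate_methylome(cfg)
  sim$sheet$sex <- rep(rep(c("F", "M"), length.out = 8), 3)
  fit <- fit_reffree(sim$Y, T = 2, seed = 1, max_iter = 50)
  dm <- fit_paired_lm(sim$Y, sim$sheet,
                      design_spec(covariates = c("age", "sex", "ct1")),
                      covariate_data = omega_as_covariates(fit))
  expect_equal(nrow(dm), nrow(sim$Y))
  expect_true(all(dm$p_adj >= dm$p_raw))

  # a covariate identical to the timepoint indicator is collinear
  cd <- omega_as_covariates(fit)
  cd$dup <- as.numeric(sim$sheet[match(rownames(cd), sim$sheet$sample_id),
                                 "timepoint"] == "M3")
  expect_error(fit_paired_lm(sim$Y, sim$sheet,
                             design_spec(covariates = "dup"),
                             covariate_data = cd),
               "collinear")

  d2 <- null_beta_design(n_subjects = 2, n_cpgs = 5)
  expect_error(fit_paired_lm(d2$Y, d2$sheet), ">= 3 subjects")
})

test_that("per-batch mean-centering exactly removes an additive batch offset", {
  d <- null_beta_design(n_subjects = 8, n_cpgs = 120, sd = 0.03, seed = 44)
  # batches cut across subjects and timepoints
  d$sheet$batch <- rep(c("b1", "b2"), length.out = nrow(d$sheet))
  Yoff <- d$Y
  b2 <- d$sheet$sample_id[d$sheet$batch == "b2"]
  Yoff[, b2] <- Yoff[, b2] + 0.15
  ref <- fit_paired_lm(d$Y, d$sheet, design_spec(batch_center = TRUE))
  off <- fit_paired_lm(Yoff, d$sheet, design_spec(batch_center = TRUE))
  expect_equal(off$t_stat, ref$t_stat, tolerance = 1e-10)
  expect_equal(off$delta_beta, ref$delta_beta, tolerance = 1e-12)
})

test_that("null exceedance at p < 0.001 stays inside the exact binomial interval", {
  d <- null_beta_design(n_subjects = 12, n_cpgs = 5000, sd = 0.03, seed = 99)
  dm <- fit_paired_lm(d$Y, d$sheet)
  exceed <- sum(dm$p_raw < 0.001)
  ci <- qbinom(c(0.005, 0.995), nrow(d$Y), 0.001)
  expect_gte(exceed, ci[1])
  expect_lte(exceed, ci[2])
})

test_that("planted effects are ranked ahead of null CpGs (AUROC over 5 seeds)", {
  aucs <- vapply(1:5, function(s) {
    cfg <- methylome_sim_config(n_subjects = 24, timepoints = c("BL", "M3"),
                                n_cpgs = 1500, n_celltypes_true = 1,
                                noise_sd = 0.03, n_responsive_cpgs = 60,
                                delta_beta = 0.10, seed = 200 + s)
    sim <- simulate_methylome(cfg)
    resp_sheet <- sim$sheet[sim$sheet$group == "responder", ]
    dm <- fit_paired_lm(sim$Y[, resp_sheet$sample_id], resp_sheet)
    truth <- dm$cpg_id %in% sim$truth$responsive_cpg_ids
    auroc(-dm$p_raw, truth)
  }, numeric(1))
  expect_true(all(aucs >= 0.95))
})

test_that("BH adjustment matches the hand-computed step-up and is rank-monotone", {
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(adjust_bh(c(0.1, NA)), "NA")
  expect_error(adjust_bh(c(0.1, 1.4)), "\\[0,1\\]")
  for (s in 1:10) {
    set.seed(s)
    p <- runif(50)
    adj <- adjust_bh(p)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("volcano classification applies both gates, idempotently and monotonely", {
  expect_equal(eval(formals(volcano_classify)$min_delta), 0.05)
  expect_equal(eval(formals(volcano_classify)$p_threshold), 0.001)

  res <- data.frame(cpg_id = "cg1", delta_beta = 0.049, t_stat = 50,
                    df = 5, p_raw = 1e-9, p_adj = 1e-8)
  expect_equal(volcano_classify(res)$label, "ns")   # effect-size gate

  set.seed(3)
  res <- data.frame(cpg_id = sprintf("cg%04d", 1:500),
                    delta_beta = runif(500, -0.2, 0.2), t_stat = 0, df = 10,
                    p_raw = runif(500)^3, p_adj = NA)
  lab <- volcano_classify(res)
  brute <- ifelse(res$p_raw < 0.001 & res$delta_beta >= 0.05, "hyper",
           ifelse(res$p_raw < 0.001 & res$delta_beta <= -0.05, "hypo", "ns"))
  expect_equal(lab$label, brute)
  expect_equal(volcano_classify(lab), lab)          # idempotent
  stricter <- volcano_classify(res, min_delta = 0.10)
  expect_true(all(stricter$label == "ns" | stricter$label == lab$label))
  expect_lte(sum(stricter$label != "ns"), sum(lab$label != "ns"))
})

test_that("top-k selection is fully ordered and permutation-invariant", {
  set.seed(5)
  res <- data.frame(cpg_id = sprintf("cg%03d", 1:20),
                    delta_beta = round(runif(20, -0.2, 0.2), 2),
                    t_stat = 0, df = 10,
                    p_raw = sample(rep(c(0.001, 0.01, 0.5), length.out = 20)),
                    p_adj = NA)
  all_sorted <- select_top_cpgs(res, nrow(res))
  ord <- order(res$p_raw, -abs(res$delta_beta), res$cpg_id)
  expect_equal(all_sorted, res$cpg_id[ord])
  perm <- res[sample(nrow(res)), ]
  expect_equal(select_top_cpgs(perm, 7), all_sorted[1:7])
  expect_error(select_top_cpgs(res, 0), "positive")
  expect_error(select_top_cpgs(res, 21), "exceeds")
})

test_that("the paired model agrees with limma's ordinary (unmoderated) statistics", {
  d <- null_beta_design(n_subjects = 7, n_cpgs = 25, sd = 0.04, seed = 64)
  dm <- fit_paired_lm(d$Y, d$sheet)
  design <- model.matrix(~ factor(timepoint, levels = c("BL", "M3")) +
                           factor(subject_id), data = d$sheet)
  lf <- limma::lmFit(d$Y[, d$sheet$sample_id], design)
  t_ord <- lf$coefficients[, 2] / (lf$stdev.unscaled[, 2] * lf$sigma)
  expect_equal(dm$t_stat, unname(t_ord), tolerance = 1e-10)
  expect_equal(dm$p_raw, unname(2 * pt(-abs(t_ord), lf$df.residual)),
               tolerance = 1e-10)
})
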