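test_that("HWE exact test agrees with full enumeration and handles monomorphic input", {
  expect_equal(hwe_exact_test(0, 2, 0), hwe_oracle(0, 2, 0))
  expect_equal(hwe_exact_test(1, 0, 1), hwe_oracle(1, 0, 1))
  p <- hwe_exact_test(10, 0, 0)
  expect_equal(as.numeric(p), 1)
  expect_true(attr(p, "monomorphic"))
  expect_error(hwe_exact_test(0, 0, 0), ">= 1")
})

test_that("HWE exact test matches the enumeration oracle for all totals up to 20", {
  for (n in 1:20) {
    for (n_AA in 0:n) for (n_Aa in 0:(n - n_AA)) {
      n_aa <- n - n_AA - n_Aa
      expect_equal(as.numeric(hwe_exact_test(n_AA, n_Aa, n_aa)),
                   hwe_oracle(n_AA, n_Aa, n_aa), tolerance = 1e-12,
                   label = sprintf("counts (%d,%d,%d)", n_AA, n_Aa, n_aa))
    }
  }
})

test_that("marker QC removes exactly the failing SNPs with recorded reasons", {
  expect_equal(eval(formals(qc_spec)$maf_min), 0.02)
  expect_equal(eval(formals(qc_spec)$call_rate_min), 0.98)
  expect_equal(eval(formals(qc_spec)$hwe_p_min), 1e-4)

  set.seed(7)
  n <- 400
  g <- cbind(
    good1 = rbinom(n, 2, 0.3),
    rare  = rbinom(n, 2, 0.01),     # MAF below 0.02
    gappy = rbinom(n, 2, 0.3),
    good2 = rbinom(n, 2, 0.4),
    hwe_bad = rep(1, n))            # all heterozygous: extreme HWE failure
  g[sample(n, 60), "gappy"] <- NA   # call rate 0.85
  rownames(g) <- sprintf("i%03d", seq_len(n))
  storage.mode(g) <- "double"
  controls <- rownames(g)[1:200]
  out <- qc_filter(g, qc_spec(), control_ids = controls)
  expect_equal(colnames(out$g), c("good1", "good2"))
  rep <- out$report
  expect_match(rep$reason[rep$snp_id == "rare"], "low_maf")
  expect_match(rep$reason[rep$snp_id == "gappy"], "low_call_rate")
  expect_match(rep$reason[rep$snp_id == "hwe_bad"], "hwe_failure")
  expect_equal(unname(attr(rep, "rule_counts")["removed"]), 3)

  # idempotence: filtering an all-passing table is the identity
  again <- qc_filter(out$g, qc_spec(), control_ids = controls)
  expect_equal(again$g, out$g)
  expect_error(qc_filter(g, qc_spec(), control_ids = character(0)),
               "control")
})

test_that("genotype PCA separates simulated subpopulations and finds nothing in a null", {
  expect_equal(eval(formals(genotype_pca)$n_components), 11L)

  sim <- simulate_genotypes(n_samples = 300, n_snps = 120,
                            n_subpops = 2, freq_divergence = 0.15,
                            seed = 31)
  pcs <- genotype_pca(sim$genotypes, n_components = 5)
  r <- abs(cor(pcs[, 1], sim$truth$subpop))
  expect_gte(r, 0.9)

  null <- simulate_genotypes(n_samples = 300, n_snps = 120, seed = 32)
  pcs0 <- genotype_pca(null$genotypes, n_components = 5)
  set.seed(1)
  lab <- rbinom(300, 1, 0.5)
  obs <- max(abs(cor(pcs0, lab)))
  perm_q <- quantile(replicate(200, {
    max(abs(cor(pcs0, sample(lab))))
  }), 0.99)
  expect_lte(obs, perm_q)
  expect_error(genotype_pca(null$genotypes, n_components = 400), "exceeds")
})

test_that("covariate-free logistic fit matches the grouped-data likelihood oracle", {
  sim <- simulate_genotypes(n_samples = 800, n_snps = 1, or_binary = 1.5,
                            seed = 41)
  res <- logistic_assoc(sim$genotypes, sim$phenotypes$response)
  # oracle: identical likelihood maximized on the 3-row grouped table
  tab <- table(factor(sim$genotypes[, 1], levels = 0:2),
               sim$phenotypes$response)
  grouped <- glm(cbind(tab[, "1"], tab[, "0"]) ~ c(0, 1, 2),
                 family = binomial())
  expect_equal(res$beta, unname(coef(grouped)[2]), tolerance = 1e-6)
  expect_equal(res$or, exp(unname(coef(grouped)[2])), tolerance = 1e-6)
  expect_error(logistic_assoc(sim$genotypes, rep(1, 800)), "constant")
})

test_that("covariate-free quantitative fit equals the simple-regression closed form", {
  sim <- simulate_genotypes(n_samples = 200, n_snps = 2, beta_quant = 0.3,
                            causal_snp_idx = 1, seed = 55)
  res <- quant_assoc(sim$genotypes, sim$phenotypes$ros)
  x <- sim$genotypes[, 1]; y <- sim$phenotypes$ros
  b <- cov(x, y) / var(x)
  a <- mean(y) - b * mean(x)
  s2 <- sum((y - a - b * x)^2) / (length(y) - 2)
  se <- sqrt(s2 / sum((x - mean(x))^2))
  expect_equal(res$beta[1], b, tolerance = 1e-10)
  expect_equal(res$se[1], se, tolerance = 1e-10)
  expect_equal(res$p[1], 2 * pt(-abs(b / se), length(y) - 2),
               tolerance = 1e-10)
})

test_that("Wald p-values are invariant to affine recoding of covariates", {
  sim <- simulate_genotypes(n_samples = 300, n_snps = 3, or_binary = 1.4,
                            seed = 61)
  covar <- data.frame(age = rnorm(300, 40, 10))
  res1 <- logistic_assoc(sim$genotypes, sim$phenotypes$response, covar)
  res2 <- logistic_assoc(sim$genotypes, sim$phenotypes$response,
                         data.frame(age = (covar$age - 40) / 10))
  expect_equal(res1$p, res2$p, tolerance = 1e-6)
  expect_equal(res1$beta, res2$beta, tolerance = 1e-6)

  q1 <- quant_assoc(sim$genotypes, sim$phenotypes$ros, covar)
  q2 <- quant_assoc(sim$genotypes, sim$phenotypes$ros,
                    data.frame(age = covar$age * 3 + 100))
  expect_equal(q1$p, q2$p, tolerance = 1e-8)
})

test_that("complete separation is flagged per SNP, not fatal", {
  g <- matrix(c(rep(0, 20), rep(2, 20)), ncol = 1,
              dimnames = list(sprintf("i%02d", 1:40), "snp1"))
  y <- c(rep(0, 20), rep(1, 20))
  res <- logistic_assoc(g, y)
  expect_equal(res$flag, "separation")
  expect_true(is.na(res$p))

  # missing dosages are excluded casewise
  g2 <- cbind(g, snp2 = rbinom(40, 2, 0.4))
  g2[1:4, "snp2"] <- NA
  res2 <- logistic_assoc(g2, y)
  expect_equal(res2$n_used[res2$snp_id == "snp2"], 36L)
})
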