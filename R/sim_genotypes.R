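#' Simulate genotypes and phenotypes with an optional planted effect
#'
#' Per-SNP allele frequencies are drawn uniformly from `maf_range` and
#' genotypes sampled under Hardy-Weinberg equilibrium (dosage ~
#' Binomial(2, p)). A binary treatment-response phenotype follows a logistic
#' model with log(`or_binary`) per alt-dosage unit at the causal SNP
#' (intercept centred so prevalence is near 0.5); a quantitative phenotype
#' (e.g. an ROS-production readout) follows a linear model with slope
#' `beta_quant` plus unit-variance Gaussian noise. Setting `n_subpops = 2`
#' splits samples into two subpopulations whose allele frequencies diverge
#' by `freq_divergence` on average, to exercise PCA stratification
#' correction.
#'
#' @param n_samples,n_snps table dimensions.
#' @param maf_range allele-frequency interval, subset of (0, 0.5\].
#' @param causal_snp_idx column index of the causal SNP.
#' @param or_binary per-dosage odds ratio for the binary phenotype (1 =
#'   null).
#' @param beta_quant per-dosage slope for the quantitative phenotype (0 =
#'   null).
#' @param n_subpops 1 or 2.
#' @param freq_divergence sd of the per-SNP allele-frequency perturbation
#'   between subpopulations (only with `n_subpops = 2`).
#' @param missing_rate per-call missingness probability.
#' @param seed integer RNG seed.
#' @return list with `genotypes` (sample-by-SNP dosage matrix), `phenotypes`
#'   (data.frame: sample_id, response, ros) and `truth` (causal SNP id,
#'   effects, subpopulation labels).
#' @export
simulate_genotypes <- function(n_samples = 500, n_snps = 50,
                               maf_range = c(0.05, 0.5),
                               causal_snp_idx = 1L,
                               or_binary = 1.0, beta_quant = 0,
                               n_subpops = 1L, freq_divergence = 0.1,
                               missing_rate = 0,
                               seed = 1L) {
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop_fmt("maf_range must be a subset of (0, 0.5]")
  if (or_binary <= 0) stop_fmt("or_binary must be positive")
  if (causal_snp_idx < 1 || causal_snp_idx > n_snps)
    stop_fmt("causal_snp_idx out of range 1..%d", n_snps)
  with_seed(seed, {
    sid <- sprintf("ind%04d", seq_len(n_samples))
    snp <- sprintf("snp%04d", seq_len(n_snps))
    p <- stats::runif(n_snps, maf_range[1], maf_range[2])
    pop <- rep(1L, n_samples)
    freq <- matrix(p, n_samples, n_snps, byrow = TRUE)
    if (n_subpops == 2) {
      pop <- rep(1:2, length.out = n_samples)
      shift <- stats::rnorm(n_snps, 0, freq_divergence)
      p2 <- pmin(pmax(p + shift, 0.01), 0.99)
      freq[pop == 2, ] <- matrix(p2, sum(pop == 2), n_snps, byrow = TRUE)
    }
    g <- matrix(stats::rbinom(n_samples * n_snps, 2, freq),
                n_samples, n_snps, dimnames = list(sid, snp))
    if (missing_rate > 0)
      g[stats::runif(length(g)) < missing_rate] <- NA
    dos <- g[, causal_snp_idx]
    dos_c <- ifelse(is.na(dos), mean(dos, na.rm = TRUE), dos)
    eta <- log(or_binary) * (dos_c - mean(dos_c))
    y_bin <- stats::rbinom(n_samples, 1, stats::plogis(eta))
    y_quant <- beta_quant * dos_c + stats::rnorm(n_samples)
    pheno <- data.frame(sample_id = sid, response = y_bin, ros = y_quant,
                        stringsAsFactors = FALSE)
    storage.mode(g) <- "double"
    list(genotypes = g, phenotypes = pheno,
         truth = list(causal_snp = snp[causal_snp_idx],
                      or_binary = or_binary, beta_quant = beta_quant,
                      allele_freq = stats::setNames(p, snp),
                      subpop = stats::setNames(pop, sid)))
  })
}
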