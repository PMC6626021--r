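# Genotype QC, Hardy-Weinberg exact testing, PCA stratification correction
# and per-SNP logistic / linear association.

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional on the observed allele counts, the number of heterozygotes
#' under HWE follows the Levene-Haldane distribution
#' P(het = h) proportional to 2^h / (n_AA! n_Aa! n_aa!). The two-sided
#' P-value sums the probabilities of all heterozygote counts (with the same
#' allele totals) that are no more probable than the observed one.
#' A monomorphic SNP (one allele absent) carries no information and returns
#' P = 1 with a `monomorphic` attribute.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (nonnegative, total >= 1).
#' @return P-value in \[0,1\].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop_fmt("total genotype count must be >= 1")
  n_A <- 2 * n_AA + n_Aa
  n_a <- 2 * n_aa + n_Aa
  if (n_A == 0 || n_a == 0)
    return(structure(1, monomorphic = TRUE))
  n_rare <- min(n_A, n_a)
  # possible het counts share the parity of the rare-allele total
  h <- seq(n_rare %% 2, n_rare, by = 2)
  logw <- h * log(2) - lfactorial((n_rare - h) / 2) - lfactorial(h) -
    lfactorial((2 * n - n_rare - h) / 2)
  prob <- exp(logw - max(logw))
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_Aa, h)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-10)]))
}

#' Marker quality-control specification
#'
#' Standard GWAS marker QC triad: minor allele frequency, genotyping
#' success (call) rate, and Hardy-Weinberg equilibrium assessed among
#' controls. Defaults: MAF > 0.02, call rate > 0.98, HWE exact P >= 1e-4.
#'
#' @param maf_min,call_rate_min,hwe_p_min thresholds, each in (0,1).
#' @param hwe_in_controls_only compute HWE only in control samples
#'   (default TRUE).
#' @return a `qc_spec` list.
#' @export
qc_spec <- function(maf_min = 0.02, call_rate_min = 0.98,
                    hwe_p_min = 1e-4, hwe_in_controls_only = TRUE) {
  for (v in c(maf_min, call_rate_min, hwe_p_min))
    if (v <= 0 || v >= 1) stop_fmt("QC thresholds must lie in (0,1)")
  structure(list(maf_min = maf_min, call_rate_min = call_rate_min,
                 hwe_p_min = hwe_p_min,
                 hwe_in_controls_only = hwe_in_controls_only),
            class = "qc_spec")
}

#' Filter SNPs on MAF, call rate and Hardy-Weinberg equilibrium
#'
#' @param g sample-by-SNP dosage matrix.
#' @param spec a [qc_spec()].
#' @param control_ids sample ids forming the control stratum for the HWE
#'   test; required when `hwe_in_controls_only` is set.
#' @return list: `g` (SNPs passing every rule) and `report` (per-SNP
#'   data.frame with maf, call_rate, hwe_p, per-rule pass flags, a combined
#'   reason string, and a `relatedness_pruned` placeholder column for
#'   upstream-pruned inputs).
#' @export
qc_filter <- function(g, spec = qc_spec(), control_ids = NULL) {
  stopifnot(inherits(spec, "qc_spec"))
  validate_genotypes(g)
  if (spec$hwe_in_controls_only) {
    if (is.null(control_ids) || length(control_ids) == 0)
      stop_fmt("hwe_in_controls_only requires a non-empty control set")
    bad <- setdiff(control_ids, rownames(g))
    if (length(bad))
      stop_fmt("control id(s) not in genotype table: %s",
               paste(utils::head(bad, 5), collapse = ", "))
    g_hwe <- g[control_ids, , drop = FALSE]
  } else g_hwe <- g

  af <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  call_rate <- colMeans(!is.na(g))
  hwe_p <- vapply(seq_len(ncol(g)), function(j) {
    d <- g_hwe[, j]
    hwe_exact_test(sum(d == 0, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
                   sum(d == 2, na.rm = TRUE))
  }, numeric(1))

  pass_maf <- maf > spec$maf_min
  pass_cr <- call_rate > spec$call_rate_min
  pass_hwe <- hwe_p >= spec$hwe_p_min
  pass <- pass_maf & pass_cr & pass_hwe
  reason <- vapply(seq_len(ncol(g)), function(j) {
    r <- c(if (!pass_maf[j]) "low_maf", if (!pass_cr[j]) "low_call_rate",
           if (!pass_hwe[j]) "hwe_failure")
    if (length(r)) paste(r, collapse = ";") else ""
  }, "")
  report <- data.frame(snp_id = colnames(g), maf = maf,
                       call_rate = call_rate, hwe_p = hwe_p,
                       pass_maf = pass_maf, pass_call_rate = pass_cr,
                       pass_hwe = pass_hwe, pass = pass, reason = reason,
                       relatedness_pruned = NA,
                       row.names = NULL, stringsAsFactors = FALSE)
  attr(report, "rule_counts") <- c(low_maf = sum(!pass_maf),
                                   low_call_rate = sum(!pass_cr),
                                   hwe_failure = sum(!pass_hwe),
                                   removed = sum(!pass))
  list(g = g[, pass, drop = FALSE], report = report)
}

#' Genotype principal components for stratification correction
#'
#' Missing dosages are mean-imputed per SNP, dosages standardized the
#' GWAS way (center `2p`, scale `sqrt(2p(1-p))` with `p` the alt-allele
#' frequency), and the leading left singular vectors (scaled by their
#' singular values) returned as per-sample scores. Monomorphic SNPs are
#' dropped. Sign convention: each component's largest-magnitude SNP loading
#' is made positive, so scores are reproducible.
#'
#' @param g sample-by-SNP dosage matrix (post-QC).
#' @param n_components number of components (default 11, the convention of
#'   the stratification correction this mirrors).
#' @return sample-by-component score matrix (columns `PC1`, `PC2`, ...).
#' @export
genotype_pca <- function(g, n_components = 11L) {
  validate_genotypes(g)
  if (n_components > min(dim(g)))
    stop_fmt("n_components = %d exceeds min(n_samples, n_snps) = %d",
             n_components, min(dim(g)))
  af <- colMeans(g, na.rm = TRUE) / 2
  keep <- af > 0 & af < 1
  g <- g[, keep, drop = FALSE]
  af <- af[keep]
  if (ncol(g) < n_components)
    stop_fmt("fewer polymorphic SNPs (%d) than requested components", ncol(g))
  X <- sweep(g, 2, 2 * af)
  X[is.na(X)] <- 0                       # mean imputation after centering
  X <- sweep(X, 2, sqrt(2 * af * (1 - af)), "/")
  sv <- svd(X, nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(k) {
    v <- sv$v[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components) %*%
    diag(flip, n_components)
  dimnames(scores) <- list(rownames(g), paste0("PC", seq_len(n_components)))
  scores
}

assoc_one <- function(dos, y, covars, family) {
  ok <- stats::complete.cases(dos, y, covars)
  d <- data.frame(y = y[ok], dos = dos[ok])
  if (!is.null(covars)) d <- cbind(d, covars[ok, , drop = FALSE])
  n_used <- sum(ok)
  if (stats::var(d$dos) == 0)
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                n_used = n_used, flag = "monomorphic"))
  fit <- tryCatch(
    stats::glm(y ~ ., data = d, family = family),
    warning = function(w) {
      f <- suppressWarnings(stats::glm(y ~ ., data = d, family = family))
      attr(f, "warned") <- TRUE
      f
    })
  co <- summary(fit)$coefficients
  if (!"dos" %in% rownames(co))
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                n_used = n_used, flag = "not_estimable"))
  b <- co["dos", 1]; se <- co["dos", 2]
  flag <- ""
  separated <- family$family == "binomial" &&
    (abs(b) > 15 || se > 100 || !fit$converged)
  if (separated)
    return(list(beta = b, se = se, p = NA_real_, n_used = n_used,
                flag = "separation"))
  if (isTRUE(attr(fit, "warned"))) flag <- "fit_warning"
  list(beta = b, se = se, p = co["dos", 4], n_used = n_used, flag = flag)
}

assoc_table <- function(g, y, covars, family, odds_ratio) {
  validate_genotypes(g)
  if (!is.null(covars)) {
    covars <- as.data.frame(covars)
    if (nrow(covars) != nrow(g))
      stop_fmt("covariate rows (%d) do not match samples (%d)",
               nrow(covars), nrow(g))
    if (anyNA(covars)) stop_fmt("covariates must be complete")
  }
  rows <- lapply(seq_len(ncol(g)), function(j)
    assoc_one(g[, j], y, covars, family))
  out <- data.frame(snp_id = colnames(g),
                    beta = vapply(rows, `[[`, 0, "beta"),
                    se = vapply(rows, `[[`, 0, "se"),
                    p = vapply(rows, `[[`, 0, "p"),
                    n_used = vapply(rows, `[[`, 0L, "n_used"),
                    flag = vapply(rows, `[[`, "", "flag"),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (odds_ratio) out$or <- exp(out$beta)
  out[, c("snp_id", "beta", "se", if (odds_ratio) "or", "p",
          "n_used", "flag")]
}

#' Per-SNP logistic association with a binary phenotype
#'
#' For each SNP, fits an additive-dosage logistic regression of the binary
#' phenotype on dosage plus covariates (typically the leading genotype
#' principal components) and reports the Wald test on the dosage
#' coefficient with its odds ratio. Samples with a missing call at a SNP
#' are excluded casewise for that SNP only. Quasi-separation and
#' non-convergence are flagged per SNP (`p = NA`), never fatal.
#'
#' @param g sample-by-SNP dosage matrix.
#' @param y binary 0/1 phenotype vector aligned with the rows of `g`.
#' @param covars optional complete covariate data.frame/matrix (same row
#'   order).
#' @return data.frame: snp_id, beta (log-odds per dosage unit), se, or, p,
#'   n_used, flag.
#' @export
logistic_assoc <- function(g, y, covars = NULL) {
  if (!all(y %in% c(0, 1))) stop_fmt("y must be binary 0/1")
  if (length(unique(y)) < 2) stop_fmt("phenotype is constant")
  assoc_table(g, y, covars, stats::binomial(), odds_ratio = TRUE)
}

#' Per-SNP linear association with a quantitative phenotype
#'
#' Ordinary least squares of the quantitative trait on additive dosage plus
#' covariates, with a Wald t-test on the dosage slope.
#'
#' @inheritParams logistic_assoc
#' @param y numeric phenotype vector.
#' @return data.frame: snp_id, beta (slope per dosage unit), se, p, n_used,
#'   flag.
#' @export
quant_assoc <- function(g, y, covars = NULL) {
  if (!is.numeric(y) || any(!is.finite(y))) stop_fmt("y must be finite numeric")
  if (stats::var(y) == 0) stop_fmt("phenotype is constant")
  assoc_table(g, y, covars, stats::gaussian(), odds_ratio = FALSE)
}
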