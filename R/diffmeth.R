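#' Probe filter specification
#'
#' Mirrors standard EPIC-array preprocessing: probes failing the detection
#' P-value threshold in any sample are dropped, probes overlapping known
#' SNPs are dropped, and sex-chromosome probes are *kept* by default — in a
#' paired before/after design each subject is their own control, so X/Y
#' probes need not be removed.
#'
#' @param detection_p_threshold detection P threshold, in (0,1); default
#'   0.01.
#' @param snp_probe_list character vector of CpG ids overlapping known SNPs.
#' @param drop_sex_chromosomes drop chrX/chrY probes (default FALSE).
#' @param chromosome named character vector mapping CpG id to chromosome
#'   (needed only if `drop_sex_chromosomes` is TRUE).
#' @return a `probe_filter_spec` list.
#' @export
probe_filter_spec <- function(detection_p_threshold = 0.01,
                              snp_probe_list = character(0),
                              drop_sex_chromosomes = FALSE,
                              chromosome = NULL) {
  if (detection_p_threshold <= 0 || detection_p_threshold >= 1)
    stop_fmt("detection_p_threshold must lie in (0,1)")
  structure(list(detection_p_threshold = detection_p_threshold,
                 snp_probe_list = unique(as.character(snp_probe_list)),
                 drop_sex_chromosomes = drop_sex_chromosomes,
                 chromosome = chromosome),
            class = "probe_filter_spec")
}

#' Filter probes from a beta matrix
#'
#' @param Y beta matrix.
#' @param spec a [probe_filter_spec()].
#' @param detection_p optional CpG-by-sample matrix of detection P-values
#'   (same shape as `Y`); a probe is removed if its detection P is at or
#'   above the threshold in *any* sample (strictest reading, the default of
#'   standard array loaders).
#' @return list: `Y` (filtered matrix) and `report` (per-rule removal
#'   counts and removed ids).
#' @export
filter_probes <- function(Y, spec = probe_filter_spec(),
                          detection_p = NULL) {
  stopifnot(inherits(spec, "probe_filter_spec"))
  cpgs <- rownames(Y)
  removed_det <- character(0)
  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(Y)))
      stop_fmt("detection_p must have the same shape as Y")
    removed_det <- cpgs[apply(detection_p >= spec$detection_p_threshold,
                              1, any)]
  }
  unknown <- setdiff(spec$snp_probe_list, cpgs)
  if (length(unknown))
    warn_fmt("%d SNP-probe id(s) not present in the matrix (e.g. '%s')",
             length(unknown), unknown[1])
  removed_snp <- intersect(spec$snp_probe_list, cpgs)
  removed_sex <- character(0)
  if (isTRUE(spec$drop_sex_chromosomes)) {
    if (is.null(spec$chromosome))
      stop_fmt("drop_sex_chromosomes requires a chromosome annotation")
    sex <- names(spec$chromosome)[spec$chromosome %in%
                                    c("chrX", "chrY", "X", "Y")]
    removed_sex <- intersect(sex, cpgs)
  }
  drop <- unique(c(removed_det, removed_snp, removed_sex))
  keep <- setdiff(cpgs, drop)
  list(Y = Y[keep, , drop = FALSE],
       report = list(n_input = length(cpgs),
                     removed_detection = length(removed_det),
                     removed_snp_probe = length(removed_snp),
                     removed_sex_chromosome = length(removed_sex),
                     n_removed = length(drop), n_kept = length(keep),
                     removed_ids = list(detection = removed_det,
                                        snp_probe = removed_snp,
                                        sex_chromosome = removed_sex)))
}

#' Design specification for the paired differential-methylation model
#'
#' @param contrast ordered pair of timepoint labels, earlier then later
#'   (effects are reported as later minus earlier).
#' @param covariates character vector naming covariates: columns of the
#'   sample sheet (`age`, `sex`) and/or columns of `covariate_data` (e.g.
#'   cell-mixture proportions from [omega_as_covariates()]).
#' @param paired block on subject (subject fixed effects); default TRUE.
#' @param batch_center per-batch mean-centering of each CpG before
#'   modelling, which exactly removes an additive per-batch offset.
#' @return a `design_spec` list.
#' @export
design_spec <- function(contrast = c("BL", "M3"), covariates = character(0),
                        paired = TRUE, batch_center = FALSE) {
  if (length(contrast) != 2 || contrast[1] == contrast[2])
    stop_fmt("contrast must be two distinct timepoint labels")
  structure(list(contrast = contrast, covariates = covariates,
                 paired = paired, batch_center = batch_center),
            class = "design_spec")
}

#' Paired per-CpG linear model for differential methylation
#'
#' For every CpG, fits ordinary least squares of beta on a timepoint
#' indicator plus any covariates plus subject fixed effects (the pairing),
#' and tests the timepoint coefficient with a two-sided t-test. With no
#' covariates this reproduces the classical paired t-test exactly. The
#' reported effect size `delta_beta` is the raw paired mean difference
#' (later minus earlier) on the beta scale, so the volcano's 5% gate refers
#' to visible methylation change, not a partially adjusted coefficient.
#' P-values are Benjamini-Hochberg adjusted across all tested CpGs.
#'
#' @param Y complete beta matrix (no NAs).
#' @param sheet sample sheet covering the samples of `Y`.
#' @param design a [design_spec()].
#' @param covariate_data optional data.frame of extra numeric covariates
#'   with rownames = sample ids (e.g. mixture proportions).
#' @param min_delta,p_threshold volcano thresholds forwarded to
#'   [volcano_classify()].
#' @return a `dm_result` data.frame: cpg_id, delta_beta, t_stat, df, p_raw,
#'   p_adj, label.
#' @export
fit_paired_lm <- function(Y, sheet, design = design_spec(),
                          covariate_data = NULL,
                          min_delta = 0.05, p_threshold = 0.001) {
  stopifnot(inherits(design, "design_spec"))
  sheet <- validate_sample_sheet(sheet,
                                 timepoint_levels = levels(factor(sheet$timepoint)))
  check_sheet_matches_matrix(Y, sheet)
  if (anyNA(Y)) stop_fmt("Y contains missing betas; impute first")
  lev <- design$contrast
  keep <- sheet$timepoint %in% lev
  sheet <- sheet[keep, , drop = FALSE]
  if (design$paired) {
    tab <- table(sheet$subject_id, factor(sheet$timepoint, levels = lev))
    paired_subj <- rownames(tab)[tab[, 1] == 1 & tab[, 2] == 1]
    if (length(paired_subj) < 3)
      stop_fmt("need >= 3 subjects paired at %s and %s (found %d)",
               lev[1], lev[2], length(paired_subj))
    sheet <- sheet[sheet$subject_id %in% paired_subj, , drop = FALSE]
  }
  sheet <- sheet[order(match(sheet$timepoint, lev), sheet$subject_id), ]
  Ys <- Y[, sheet$sample_id, drop = FALSE]

  if (isTRUE(design$batch_center) && length(unique(sheet$batch)) > 1) {
    grand <- rowMeans(Ys)
    for (b in unique(sheet$batch)) {
      cols <- sheet$batch == b
      Ys[, cols] <- Ys[, cols] - rowMeans(Ys[, cols, drop = FALSE]) + grand
    }
  }

  df_x <- data.frame(timepoint = factor(as.character(sheet$timepoint),
                                        levels = lev),
                     row.names = sheet$sample_id)
  used_covs <- character(0)
  dropped <- character(0)
  for (cv in design$covariates) {
    if (cv %in% names(sheet)) {
      v <- sheet[[cv]]
    } else if (!is.null(covariate_data) && cv %in% colnames(covariate_data)) {
      v <- covariate_data[sheet$sample_id, cv]
    } else stop_fmt("covariate '%s' found neither in the sheet nor in covariate_data", cv)
    if (anyNA(v)) stop_fmt("covariate '%s' has missing values", cv)
    if (is.character(v)) v <- factor(v)
    # subject fixed effects absorb any covariate that is constant within
    # subject (age, sex, ...): it is exactly collinear and already
    # adjusted for by the pairing
    if (design$paired &&
        all(tapply(as.character(v), sheet$subject_id,
                   function(x) length(unique(x))) == 1)) {
      dropped <- c(dropped, cv)
      next
    }
    if (length(unique(v)) < 2)
      stop_fmt("covariate '%s' is constant over the modelled samples", cv)
    df_x[[cv]] <- v
    used_covs <- c(used_covs, cv)
  }
  if (length(dropped))
    message(sprintf(
      "covariate(s) %s constant within subject; absorbed by the pairing",
      paste(sQuote(dropped), collapse = ", ")))
  form <- stats::as.formula(paste(
    c("~ timepoint", used_covs,
      if (design$paired) "subject" else NULL), collapse = " + "))
  if (design$paired) df_x$subject <- factor(sheet$subject_id)
  X <- stats::model.matrix(form, df_x)

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_fmt("collinear design columns: %s", paste(aliased, collapse = ", "))
  }
  n <- nrow(X); rdf <- n - qrX$rank
  if (rdf < 1) stop_fmt("no residual degrees of freedom")
  Yt <- t(Ys)                                   # samples x CpGs
  coefs <- qr.coef(qrX, Yt)
  fitted <- X %*% coefs
  res <- Yt - fitted
  sigma2 <- colSums(res^2) / rdf
  inv <- chol2inv(qr.R(qrX))
  XtXinv <- matrix(0, ncol(X), ncol(X))
  XtXinv[qrX$pivot, qrX$pivot] <- inv
  tp_col <- which(colnames(X) == paste0("timepoint", lev[2]))
  se <- sqrt(sigma2 * XtXinv[tp_col, tp_col])
  tstat <- coefs[tp_col, ] / se
  p_raw <- 2 * stats::pt(-abs(tstat), rdf)

  later <- sheet$timepoint == lev[2]
  if (design$paired) {
    ord1 <- sheet$sample_id[!later][order(sheet$subject_id[!later])]
    ord2 <- sheet$sample_id[later][order(sheet$subject_id[later])]
    delta <- rowMeans(Ys[, ord2, drop = FALSE] - Ys[, ord1, drop = FALSE])
  } else {
    delta <- rowMeans(Ys[, sheet$sample_id[later], drop = FALSE]) -
      rowMeans(Ys[, sheet$sample_id[!later], drop = FALSE])
  }

  res_df <- data.frame(cpg_id = rownames(Ys), delta_beta = unname(delta),
                       t_stat = unname(tstat), df = rdf,
                       p_raw = unname(p_raw),
                       p_adj = adjust_bh(unname(p_raw)),
                       stringsAsFactors = FALSE)
  class(res_df) <- c("dm_result", "data.frame")
  volcano_classify(res_df, min_delta = min_delta, p_threshold = p_threshold)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement (delegates to
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p_raw vector of raw P-values in \[0,1\]; NaN/NA rejected.
#' @return adjusted P-values, same order.
#' @export
adjust_bh <- function(p_raw) {
  if (anyNA(p_raw)) stop_fmt("NA/NaN p-values are not allowed")
  if (any(p_raw < 0 | p_raw > 1)) stop_fmt("p-values must lie in [0,1]")
  stats::p.adjust(p_raw, method = "BH")
}

#' Volcano classification of differentially methylated CpGs
#'
#' A CpG is `hyper` if its paired mean difference is at least `+min_delta`
#' and its raw P is below `p_threshold`; `hypo` symmetrically; otherwise
#' `ns`. Defaults are the conventional 5% minimum methylation change and
#' P < 0.001.
#'
#' @param res a `dm_result`.
#' @param min_delta minimum absolute methylation change (beta scale).
#' @param p_threshold raw P-value cutoff.
#' @return `res` with its `label` column (re)computed.
#' @export
volcano_classify <- function(res, min_delta = 0.05, p_threshold = 0.001) {
  res$label <- ifelse(res$p_raw < p_threshold & res$delta_beta >= min_delta,
                      "hyper",
               ifelse(res$p_raw < p_threshold & res$delta_beta <= -min_delta,
                      "hypo", "ns"))
  res
}

#' Top-k most significant CpGs
#'
#' CpGs ordered by raw P ascending, ties broken by absolute effect size
#' descending then id lexicographically, so the result is deterministic
#' under input row permutation.
#'
#' @param res a `dm_result`.
#' @param k how many CpGs, `1 <= k <= nrow(res)`.
#' @return character vector of CpG ids.
#' @export
select_top_cpgs <- function(res, k) {
  if (k <= 0) stop_fmt("k must be positive")
  if (k > nrow(res)) stop_fmt("k exceeds the number of tested CpGs")
  ord <- order(res$p_raw, -abs(res$delta_beta), res$cpg_id)
  res$cpg_id[ord][seq_len(k)]
}
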