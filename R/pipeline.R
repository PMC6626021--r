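#' Pipeline configuration
#'
#' Either point the stages at real input files (`beta_path`, `sheet_path`,
#' `gmt_path`, `genotype_path`, `reference_path`) or leave them NULL to
#' have the pipeline simulate its inputs with the bundled generators. One
#' global `seed` drives everything: each stage derives its own seed from it
#' deterministically, so identical configurations yield byte-identical
#' outputs.
#'
#' @param output_dir directory for all result tables and the run report.
#' @param seed global integer seed.
#' @param stages character subset of
#'   `c("deconvolution", "diffmeth", "geneset", "association")`.
#' @param beta_path,sheet_path,gmt_path,genotype_path,reference_path
#'   optional input files; NULL means simulate.
#' @param sim_methylome a [methylome_sim_config()] used when no beta input
#'   is given (its seed is overridden by the derived stage seed).
#' @param sim_geneset_args,sim_genotype_args argument lists for
#'   [simulate_genesets()] / [simulate_genotypes()] when inputs are
#'   simulated.
#' @param T_deconv fixed number of cell types; NULL selects it by
#'   bootstrap.
#' @param T_range,n_boot selection-curve settings.
#' @param contrast,covariates,min_delta,p_threshold,batch_center
#'   differential-methylation settings; `"omega"` in `covariates` expands
#'   to the fitted mixture columns.
#' @param cluster_method,k_range gene-set clustering settings.
#' @param n_components number of genotype PCs used as association
#'   covariates.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir,
                            seed = 1L,
                            stages = c("deconvolution", "diffmeth",
                                       "geneset", "association"),
                            beta_path = NULL, sheet_path = NULL,
                            gmt_path = NULL, genotype_path = NULL,
                            reference_path = NULL,
                            sim_methylome = methylome_sim_config(),
                            sim_geneset_args = list(),
                            sim_genotype_args = list(),
                            T_deconv = NULL, T_range = 1:6, n_boot = 50L,
                            contrast = c("BL", "M3"),
                            covariates = c("age", "sex", "omega"),
                            min_delta = 0.05, p_threshold = 0.001,
                            batch_center = FALSE,
                            cluster_method = "gmm", k_range = 2:6,
                            n_components = 11L) {
  stages <- match.arg(stages, several.ok = TRUE)
  if ("diffmeth" %in% stages && "omega" %in% covariates &&
      !"deconvolution" %in% stages)
    stop_fmt(paste("diffmeth requests mixture covariates but the",
                   "deconvolution stage is disabled"))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the enabled stages in dependency order — deconvolution feeds
#' the paired differential-methylation model its cell-mixture covariates;
#' gene-set clustering and SNP association run on their own inputs — and
#' writes every stage's tables plus a JSON run report (seeds, parameter
#' echo, per-stage summaries, and planted-truth recovery metrics whenever
#' the inputs were simulated) under `output_dir`.
#'
#' @param config a [pipeline_config()].
#' @return the run report, invisibly (also written as `run_report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cf <- config
  dir.create(cf$output_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package_version = as.character(utils::packageVersion("methresponse")),
                 seed = cf$seed, stages = cf$stages,
                 parameters = list(contrast = cf$contrast,
                                   covariates = cf$covariates,
                                   min_delta = cf$min_delta,
                                   p_threshold = cf$p_threshold,
                                   cluster_method = cf$cluster_method,
                                   n_components = cf$n_components))
  truth <- list()
  need_meth <- any(c("deconvolution", "diffmeth") %in% cf$stages)

  Y <- sheet <- NULL
  if (need_meth) {
    if (!is.null(cf$beta_path)) {
      Y <- read_beta_matrix(cf$beta_path)
      sheet <- read_sample_sheet(cf$sheet_path)
    } else {
      sim_cf <- cf$sim_methylome
      sim_cf$seed <- derive_seed(cf$seed, 1L)
      sim <- simulate_methylome(sim_cf)
      Y <- sim$Y; sheet <- sim$sheet; truth$methylome <- sim$truth
      write_beta_matrix(Y, file.path(cf$output_dir, "simulated_betas.tsv"))
      write_sample_sheet(sheet, file.path(cf$output_dir, "simulated_sheet.csv"))
    }
    check_sheet_matches_matrix(Y, sheet)
    Y <- impute_betas(Y)
  }

  fit <- NULL
  if ("deconvolution" %in% cf$stages) {
    dseed <- derive_seed(cf$seed, 2L)
    T_use <- cf$T_deconv
    if (is.null(T_use)) {
      curve <- select_num_celltypes(Y, T_range = cf$T_range,
                                    n_boot = cf$n_boot, seed = dseed)
      T_use <- curve$chosen_T
      utils::write.table(
        data.frame(T = curve$T_values,
                   epsilon = format_num(curve$epsilon),
                   epsilon_se = format_num(curve$epsilon_se)),
        file.path(cf$output_dir, "selection_curve.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      report$deconvolution <- list(chosen_T = curve$chosen_T)
    } else report$deconvolution <- list(chosen_T = T_use, fixed = TRUE)
    fit <- fit_reffree(Y, T_use, seed = dseed)
    utils::write.table(
      data.frame(sample_id = rownames(fit$Omega),
                 apply(fit$Omega, 2, format_num)),
      file.path(cf$output_dir, "omega.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    report$deconvolution$final_rss <-
      utils::tail(fit$objective_trajectory, 1)
    if (!is.null(truth$methylome)) {
      rec <- match_mixture_columns(fit$Omega, truth$methylome$true_Omega)
      report$deconvolution$omega_recovery_r <- rec$mean_r
    }
  }

  if ("diffmeth" %in% cf$stages) {
    covs <- setdiff(cf$covariates, "omega")
    # a covariate constant across subjects (e.g. an all-female cohort)
    # carries no information and would break the fit
    const <- covs[vapply(covs, function(cv)
      cv %in% names(sheet) && length(unique(sheet[[cv]])) < 2, logical(1))]
    covs <- setdiff(covs, const)
    cov_data <- NULL
    if ("omega" %in% cf$covariates && !is.null(fit)) {
      cov_data <- omega_as_covariates(fit)
      covs <- c(covs, colnames(cov_data))
    }
    dm <- fit_paired_lm(Y, sheet,
                        design_spec(contrast = cf$contrast,
                                    covariates = covs,
                                    batch_center = cf$batch_center),
                        covariate_data = cov_data,
                        min_delta = cf$min_delta,
                        p_threshold = cf$p_threshold)
    write_dm_result(dm, file.path(cf$output_dir, "diffmeth.tsv"))
    report$diffmeth <- list(n_tested = nrow(dm),
                            n_hyper = sum(dm$label == "hyper"),
                            n_hypo = sum(dm$label == "hypo"),
                            n_ns = sum(dm$label == "ns"))
  }

  if ("geneset" %in% cf$stages) {
    gseed <- derive_seed(cf$seed, 3L)
    if (!is.null(cf$gmt_path)) {
      collection <- read_gmt(cf$gmt_path)
    } else {
      args <- utils::modifyList(list(seed = gseed), cf$sim_geneset_args)
      gs <- do.call(simulate_genesets, args)
      collection <- gs$collection; truth$genesets <- gs$truth
      write_gmt(collection, file.path(cf$output_dir, "simulated_sets.gmt"))
    }
    reference <- if (!is.null(cf$reference_path))
      read_gene_list(cf$reference_path)
    else with_seed(derive_seed(cf$seed, 4L), {
      pool <- unique(unlist(collection, use.names = FALSE))
      sample(pool, max(1L, round(0.2 * length(pool))))
    })
    rr <- compute_rr_matrix(collection)
    cl <- cluster_gene_sets(rr, method = cf$cluster_method,
                            k_range = cf$k_range, seed = gseed)
    scores <- ros_score(cl, collection, reference)
    utils::write.table(
      data.frame(set_name = names(cl$labels), cluster = cl$labels),
      file.path(cf$output_dir, "cluster_labels.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    scores_out <- scores
    scores_out$fraction <- format_num(scores_out$fraction)
    utils::write.table(scores_out,
                       file.path(cf$output_dir, "ros_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$geneset <- list(k = cl$k, method = cl$method,
                           ros_fraction = scores$fraction)
    if (!is.null(truth$genesets))
      report$geneset$ari <-
        mclust::adjustedRandIndex(cl$labels[names(truth$genesets)],
                                  truth$genesets)
  }

  if ("association" %in% cf$stages) {
    aseed <- derive_seed(cf$seed, 5L)
    if (!is.null(cf$genotype_path)) {
      stop_fmt("association on file inputs needs a phenotype table; call qc_filter/genotype_pca/logistic_assoc directly")
    } else {
      args <- utils::modifyList(list(seed = aseed), cf$sim_genotype_args)
      sim <- do.call(simulate_genotypes, args)
      g <- sim$genotypes; pheno <- sim$phenotypes
      truth$genotypes <- sim$truth
      write_genotypes(g, file.path(cf$output_dir, "simulated_dosages.tsv"))
    }
    controls <- pheno$sample_id[pheno$response == 0]
    qc <- qc_filter(g, qc_spec(), control_ids = controls)
    n_pc <- min(cf$n_components, min(dim(qc$g)) - 1L)
    pcs <- genotype_pca(qc$g, n_components = n_pc)
    log_res <- logistic_assoc(qc$g, pheno$response, covars = pcs)
    quant_res <- quant_assoc(qc$g, pheno$ros, covars = pcs)
    write_assoc_result(log_res,
                       file.path(cf$output_dir, "assoc_logistic.tsv"))
    write_assoc_result(quant_res,
                       file.path(cf$output_dir, "assoc_quantitative.tsv"))
    report$association <- list(
      n_snps_input = ncol(g), n_snps_pass = ncol(qc$g), n_pcs = n_pc,
      rule_counts = as.list(attr(qc$report, "rule_counts")))
    if (!is.null(truth$genotypes)) {
      cs <- truth$genotypes$causal_snp
      if (cs %in% log_res$snp_id) {
        report$association$causal_or_hat <-
          log_res$or[log_res$snp_id == cs]
        report$association$causal_beta_hat <-
          quant_res$beta[quant_res$snp_id == cs]
      }
    }
  }

  jsonlite::write_json(report, file.path(cf$output_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Match fitted mixture columns to the truth
#'
#' The factorization is identified only up to a permutation of the latent
#' cell types, so fitted mixture columns are greedily matched to truth
#' columns by Pearson correlation before comparison.
#'
#' @param Omega_hat,Omega_true sample-by-T mixture matrices.
#' @return list: `perm` (truth column matched to each fitted column),
#'   `per_column_r`, `mean_r`.
#' @export
match_mixture_columns <- function(Omega_hat, Omega_true) {
  Tn <- ncol(Omega_true)
  r <- abs(stats::cor(Omega_hat, Omega_true))
  r[!is.finite(r)] <- -1
  perm <- integer(Tn)
  taken_row <- taken_col <- rep(FALSE, Tn)
  rr <- r
  for (i in seq_len(Tn)) {      # greedy best-pair assignment
    best <- which(rr == max(rr), arr.ind = TRUE)[1, ]
    perm[best[1]] <- best[2]
    rr[best[1], ] <- -Inf
    rr[, best[2]] <- -Inf
  }
  per_r <- vapply(seq_len(Tn), function(i)
    suppressWarnings(stats::cor(Omega_hat[, i], Omega_true[, perm[i]])),
    numeric(1))
  list(perm = perm, per_column_r = per_r, mean_r = mean(per_r))
}

#' Write a differential-methylation result table
#' @param dm a `dm_result`.
#' @param path output TSV path.
#' @export
write_dm_result <- function(dm, path) {
  out <- data.frame(cpg_id = dm$cpg_id,
                    delta_beta = format_num(dm$delta_beta),
                    t_stat = format_num(dm$t_stat), df = dm$df,
                    p_raw = format_num(dm$p_raw, 9),
                    p_adj = format_num(dm$p_adj, 9), label = dm$label)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an association result table
#' @param res a [logistic_assoc()] / [quant_assoc()] result.
#' @param path output TSV path.
#' @export
write_assoc_result <- function(res, path) {
  out <- res
  for (cl in intersect(c("beta", "se", "or"), names(out)))
    out[[cl]] <- format_num(out[[cl]])
  if ("p" %in% names(out)) out$p <- format_num(out$p, 9)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
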