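#!/usr/bin/env Rscript

# Stage 1: generate the study-shaped synthetic inputs every later stage
# consumes — a longitudinal beta matrix with latent cell mixtures and
# planted treatment-responsive CpGs, a gene-set collection with planted
# cluster structure, and a genotype/phenotype table with a planted
# response-associated SNP.

suppressPackageStartupMessages(library(methresponse))
dir.create("results/inputs", recursive = TRUE, showWarnings = FALSE)
seed <- 20260926L

cfg <- methylome_sim_config(n_subjects = 12, timepoints = c("BL", "M3", "M6"),
                            n_cpgs = 5000, n_celltypes_true = 3,
                            n_responsive_cpgs = 100, delta_beta = 0.10,
                            noise_sd = 0.03, seed = seed)
meth <- simulate_methylome(cfg)
write_beta_matrix(meth$Y, "results/inputs/betas.tsv")
write_sample_sheet(meth$sheet, "results/inputs/sample_sheet.csv")
saveRDS_path <- "results/inputs/methylome_truth.json"
jsonlite::write_json(list(responsive_cpg_ids = meth$truth$responsive_cpg_ids,
                          responder_subjects = meth$truth$responder_subjects),
                     saveRDS_path, auto_unbox = TRUE)

gs <- simulate_genesets(n_clusters = 3, sets_per_cluster = 10,
                        genes_per_set = 30, within_cluster_pool = 60,
                        universe_size = 1000,
                        background_overlap_rate = 0.02, seed = seed + 1L)
write_gmt(gs$collection, "results/inputs/gene_sets.gmt")
writeLines(unique(unlist(gs$collection[names(gs$truth)[gs$truth == 1]])),
           "results/inputs/ros_reference.txt")

gt <- simulate_genotypes(n_samples = 2000, n_snps = 50,
                         causal_snp_idx = 7, or_binary = 1.57,
                         beta_quant = -0.28, seed = seed + 2L)
write_genotypes(gt$genotypes, "results/inputs/dosages.tsv")
write.csv(gt$phenotypes, "results/inputs/phenotypes.csv", row.names = FALSE)

cat("Simulated:", nrow(meth$Y), "CpGs x", ncol(meth$Y), "samples;",
    length(gs$collection), "gene sets;", nrow(gt$genotypes), "subjects x",
    ncol(gt$genotypes), "SNPs\n")
cat("Planted:", length(meth$truth$responsive_cpg_ids),
    "responsive CpGs (delta_beta = 0.10), 3 gene-set clusters,",
    "causal SNP", gt$truth$causal_snp, "(OR = 1.57, beta = -0.28)\n")
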