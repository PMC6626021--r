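#!/usr/bin/env Rscript

# Stage 5: SNP association with treatment response (logistic) and the
# quantitative ROS readout (linear), after marker QC (MAF > 0.02, call
# rate > 0.98, HWE exact P >= 1e-4 in controls) and with 11 genotype
# principal components as stratification covariates.

suppressPackageStartupMessages(library(methresponse))
dir.create("results/association", showWarnings = FALSE, recursive = TRUE)

g <- read_genotypes("results/inputs/dosages.tsv")
pheno <- read.csv("results/inputs/phenotypes.csv")
stopifnot(identical(pheno$sample_id, rownames(g)))

qc <- qc_filter(g, qc_spec(), control_ids =
                  pheno$sample_id[pheno$response == 0])
write.table(qc$report, "results/association/qc_report.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("QC:", ncol(qc$g), "of", ncol(g), "SNPs pass;",
    "removed per rule:", paste(names(attr(qc$report, "rule_counts")),
                               attr(qc$report, "rule_counts"),
                               collapse = ", "), "\n")

pcs <- genotype_pca(qc$g, n_components = 11)
log_res <- logistic_assoc(qc$g, pheno$response, covars = pcs)
quant_res <- quant_assoc(qc$g, pheno$ros, covars = pcs)
write_assoc_result(log_res, "results/association/logistic_response.tsv")
write_assoc_result(quant_res, "results/association/quantitative_ros.tsv")

top <- log_res[order(log_res$p), ][1, ]
cat(sprintf("Top response SNP: %s, OR = %.2f, P = %.3g\n",
            top$snp_id, top$or, top$p))
topq <- quant_res[order(quant_res$p), ][1, ]
cat(sprintf("Top ROS SNP: %s, beta = %.2f, P = %.3g\n",
            topq$snp_id, topq$beta, topq$p))
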