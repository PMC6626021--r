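# methresponse

Analysis toolkit for longitudinal treatment-response studies that combine
DNA methylation profiling with genetic association — the design used to
study how dimethyl fumarate (DMF) therapy reshapes immune-cell methylomes
in relapsing-remitting multiple sclerosis, and whether oxidative-stress
(ROS) genetics predict who responds. It is aimed at analysts who have (or
want to simulate) CpG beta-value matrices from patients sampled before and
after treatment, pathway gene sets, and SNP dosage tables.

Four statistical components, each testable against planted ground truth:

1. **Reference-free cell-type deconvolution.** The beta matrix is
   factorized as `Y ≈ M Ωᵀ` with cell-type profiles `M ∈ [0,1]` and
   per-sample mixture rows of `Ω` on the probability simplex, by
   alternating constrained least squares (both half-steps exact, so the
   objective is monotone). The number of cell types is chosen by a
   bootstrapped out-of-bag deviance over T = 1..10
   (`select_num_celltypes()`), and the fitted mixtures feed the
   downstream model as covariates.
2. **Paired differential methylation.** Per CpG, OLS of beta on a
   timepoint indicator + covariates + subject fixed effects; with no
   covariates this *is* the classical paired t-test. Probe filters
   (detection P < 0.01 in any sample, known-SNP probes, optional X/Y),
   Benjamini–Hochberg adjustment, and volcano classification at the
   conventional gates (|Δβ| ≥ 5%, raw P < 0.001).
3. **Gene-set clustering by relative risk.** Pairwise co-membership lift
   `RR(A,B) = |A∩B|·N / (|A||B|)` over the collection's gene universe,
   clustered on `log2(RR + 1)` rows with k-means (silhouette) or a
   diagonal Gaussian mixture (BIC), plus a per-cluster overlap score
   against a reference gene list such as GO_RESPONSE_TO_OXIDATIVE_STRESS.
4. **SNP association.** Marker QC (MAF > 0.02, call rate > 0.98,
   Hardy–Weinberg exact P ≥ 1e-4 in controls), genotype PCA (11
   components) for stratification, and per-SNP logistic (treatment
   response, reported as OR) or linear (quantitative ROS readout)
   association with Wald tests.

A synthetic-data module (`simulate_methylome()`, `simulate_genesets()`,
`simulate_genotypes()`) generates every input with known planted
structure, so the whole pipeline runs and is verified without any
external download. See `vignettes/methylome-response-pipeline.Rmd` for
the models, defaults and their rationale.

## Worked example

```r
library(methresponse)

cfg <- methylome_sim_config(n_subjects = 24, n_cpgs = 2000,
                            n_celltypes_true = 3, n_responsive_cpgs = 50,
                            delta_beta = 0.10, noise_sd = 0.03, seed = 7)
sim <- simulate_methylome(cfg)

curve <- select_num_celltypes(sim$Y, T_range = 1:5, n_boot = 50, seed = 7)
curve$chosen_T
#> [1] 3
fit <- fit_reffree(sim$Y, T = curve$chosen_T, seed = 7)
match_mixture_columns(fit$Omega, sim$truth$true_Omega)$per_column_r
#> [1] 1.0000 0.9999 0.9999

resp <- sim$sheet[sim$sheet$group == "responder", ]
dm <- fit_paired_lm(sim$Y[, resp$sample_id], resp,
                    design_spec(contrast = c("BL", "M3"),
                                covariates = c("age", "sex", "ct1", "ct2")),
                    covariate_data = omega_as_covariates(fit))
table(dm$label)
#> hyper  hypo    ns
#>    12    15  1973
head(dm[order(dm$p_raw), ], 3)
#>         cpg_id delta_beta t_stat    p_raw    p_adj label
#> 1124 cpg001124    0.00247   16.7 4.32e-08 8.64e-05    ns
#> 1849 cpg001849   -0.07995  -13.9 2.20e-07 2.20e-04  hypo
#> 346  cpg000346    0.23667   12.0 7.44e-07 4.96e-04 hyper
```

The selection curve recovers the 3 planted cell types; mixture rows are
recovered with per-column correlation > 0.999 after permutation matching.
In the paired model, CpGs are labelled `hyper`/`hypo` only when both the
effect-size gate (≥ 5% methylation change, beta scale) and the
significance gate (raw P < 0.001) pass — note the top hit by P alone stays
`ns` because its raw paired difference is only 0.2%; the gates are doing
their job. `age` and `sex` are absorbed by the subject pairing (a message
says so); the mixture covariates `ct1`/`ct2` vary within subject and are
retained.

The numbered scripts under `analysis/` run the same stages as a file-based
workflow (simulate → deconvolve → differential methylation → gene-set
clusters → association), writing tables under `results/`.

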