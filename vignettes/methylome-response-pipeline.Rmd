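---
title: "Models and methods behind the methresponse pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the methresponse pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`methresponse` implements the computational core of a longitudinal
treatment-response study design in which patients are profiled before and
after starting a therapy (here labelled BL, M3, M6 for baseline, three and
six months, the schedule typical of dimethyl fumarate studies in
relapsing-remitting multiple sclerosis): DNA methylation beta matrices are
deconvolved into latent cell types, per-CpG treatment effects are estimated
with a paired linear model, enriched pathway lists are clustered on their
gene co-membership, and genotypes are tested for association with the
clinical response and with a quantitative oxidative-stress (ROS) readout.
This vignette explains the models, the defaults, and the choices made where
the design was genuinely open. All empirical claims here are the ones the
package's test suite computes.

## Reference-free cell-type deconvolution

Bulk methylation of sorted-cell or whole-blood samples is a mixture: the
observed beta value of CpG *i* in sample *j* is approximately the average
of cell-type-specific methylation levels weighted by that sample's cell
composition. We model the CpG-by-sample matrix as

$$ Y \approx M\,\Omega^{\mathsf T}, \qquad
   M \in [0,1]^{p \times T},\;
   \Omega_{j\cdot} \in \Delta^{T-1}, $$

where the columns of $M$ are cell-type methylation profiles and each row of
$\Omega$ is a sample's mixture proportion vector on the probability
simplex. A notational aside: mixture-model write-ups sometimes render the
transpose superscript ambiguously (e.g. as $\Omega^{-T}$); the factorization
above, with a plain transpose, is the only reading under which the
dimensions and constraints make sense, and it is what the package fits.

`fit_reffree()` minimizes $\|Y - M\Omega^{\mathsf T}\|_F^2$ by alternating
constrained least squares, with both half-steps exact minimizers:

* **Mixture rows**: for fixed $M$, each row of $\Omega$ solves a
  simplex-constrained least-squares problem. The equality-constrained
  (sum-to-one) solution is computed for all samples in one Cholesky solve;
  samples whose solution leaves the nonnegative orthant are finished with
  an active-set method on the KKT system. An `allow_deficit` option relaxes
  the constraint to $\sum_t \omega_{jt} \le 1$ for designs where an
  unmodelled cell type may absorb mass.
* **Profiles**: for fixed $\Omega$, each entry of $M$ is box-constrained to
  $[0,1]$; exact cyclic coordinate descent (each coordinate update a
  clipped exact minimization) handles the box.

Because both block updates are exact, the residual sum of squares is
non-increasing across iterations — the test suite asserts this on random
instances, along with the simplex and box constraints after every fit.
Iteration stops when the relative RSS change drops below `tol` (default
1e-6) or after `max_iter` (default 500) iterations. Initialization is a
deterministic k-means++-style seeding of sample columns from the `seed`
argument; the factorization is identified only up to a permutation of the
cell-type columns, so all recovery comparisons first match columns by
correlation (`match_mixture_columns()`).

### Choosing the number of cell types

`select_num_celltypes()` picks $T$ by a bootstrap: for each candidate $T$
and each of `n_boot` replicates, samples are resampled with replacement,
the factorization is refitted on the resample (warm-started from the
full-data fit), and a residual deviance is evaluated on the out-of-bag
samples with their mixture rows re-estimated holding $M$ fixed. The same
resamples are reused across the whole $T$ range so comparisons are paired.

The default deviance is the Gaussian out-of-sample deviance with per-CpG
residual variances estimated on the training resample,
$\sum_{i,j} r_{ij}^2/\hat\sigma_i^2 + n_{\text{oob}}\sum_i \log\hat\sigma_i^2$.
This matters: the plain out-of-bag *sum of squares* (available as
`metric = "rss"`) decreases slightly but systematically as superfluous
components are added, because re-estimating each held-out sample's mixture
against a richer profile basis can only reduce its residual; the curve then
has no interior minimum. The likelihood-based deviance penalizes exactly
the mechanism by which over-parameterized fits cheat — training variances
shrink below the truth, and the held-out residuals are charged at the
shrunken scale — so the curve turns upward past the true $T$. On the
bundled simulations (3 true cell types, 2000 CpGs, 60 samples, noise sd
0.05) the deviance curve selects $T = 3$ in every seeded replicate of the
acceptance suite.

The candidate range defaults to 1–10, the conventional span for this
selection. `n_boot` defaults to 100 at desk scale; the $10^4$-replicate
setting used on array-scale data is a config choice — at the bundled
problem sizes the curve is stable far below that.

## Paired differential methylation

`filter_probes()` applies the standard array hygiene first: probes whose
detection P-value is at or above 0.01 in *any* sample are dropped
(the strictest common reading), probes overlapping known SNPs are dropped
from a supplied list, and sex-chromosome probes are **kept** by default —
in a before/after design each subject is their own control, so X/Y probes
need not be excluded. The filter reports per-rule removal counts.

`fit_paired_lm()` regresses each CpG's beta value on a timepoint indicator
plus covariates plus subject fixed effects. The subject dummies implement
the pairing: with no covariates the timepoint t-test is algebraically the
classical paired t-test, which the test suite verifies to 1e-10. We chose
fixed effects over duplicate-correlation moderation because the estimator
is then self-contained and exactly reproducible by hand; empirical-Bayes
variance moderation is deliberately not applied, and the null behaviour of
the plain estimator is checked directly (the fraction of null CpGs with
P < 0.001 lies inside the exact binomial 99% interval in a 5000-CpG,
12-pair simulation).

Three consequences of this design are worth knowing:

* Covariates constant within subject (age, sex) are *absorbed* by the
  subject fixed effects — they are exactly collinear with the dummies and
  already adjusted for by the pairing. The function drops them with a
  message rather than failing; cell-mixture covariates vary within subject
  and are retained.
* The reported `delta_beta` is the raw paired mean difference (later minus
  earlier) on the beta scale, not a partially adjusted model coefficient,
  so the volcano's "minimum 5% methylation change" gate refers to visible
  methylation change.
* At least 3 paired subjects are required (fewer leaves essentially no
  residual degrees of freedom).

Batch handling is per-batch mean-centering of each CpG (restoring the
grand mean), which removes an additive per-batch offset exactly — the
structure the simulator plants. Full empirical-Bayes batch correction is
out of scope and should be applied upstream if needed.

`volcano_classify()` labels CpGs hyper/hypo-methylated when both gates
pass: $|\Delta\beta| \ge$ `min_delta` (default 0.05) and raw
$P <$ `p_threshold` (default 0.001). Adjusted P-values are
Benjamini–Hochberg across all tested CpGs. `select_top_cpgs()` orders by
raw P with deterministic tie-breaks (absolute effect, then id), so heat-map
input lists are reproducible under row permutation.

## Gene-set clustering on relative-risk co-membership

Pathway-enrichment tools return many overlapping gene sets; grouping them
by shared genes makes the themes legible. For sets $A, B$ over the
universe $U$ (by default the union of all member genes in the analyzed
collection, $N = |U|$), the package scores co-membership by the relative
risk, observed over independence-expected:

$$ \mathrm{RR}(A,B) \;=\; \frac{|A \cap B|\; N}{|A|\,|B|}. $$

This form is symmetric, needs no case/control framing, equals 0 for
disjoint sets and $N/|A|$ on the diagonal (the self-overlap lift). The
asymmetric epidemiological 2-by-2 form was considered and rejected as the
default because set pairs here have no natural exposure direction. Whether
a genome-wide or collection-restricted universe should be used is
ambiguous in practice; the collection universe is the only one derivable
from the inputs alone, and a `universe` override is accepted.

Clustering operates on rows of $\log_2(\mathrm{RR} + 1)$: raw ratios are
zero-inflated with a heavy upper tail and a dominant diagonal, and the log
transform makes Euclidean distances meaningful. The pseudocount of 1 (the
log1p form) matters more than it looks: with a tiny pseudocount such as
$10^{-3}$, disjoint pairs sit near $\log_2 10^{-3} \approx -10$ while a
pair sharing even one background gene jumps to roughly $-1.6$, so sparse
incidental overlaps become outlying feature coordinates — the
mixture-model backend then prefers splintering singleton clusters off
otherwise clean blocks. With pseudocount 1, disjoint pairs map to exactly
0 and incidental overlaps stay near 0, and both backends recover planted
clusters reliably. `drop_diagonal` removes the self-lift from the feature
vectors if desired. Two backends are provided because both are
used for this task in the literature this design follows — k-means (k by
maximum mean silhouette) and a diagonal-covariance Gaussian mixture fitted
by EM (k by BIC); neither is privileged, and the planted-cluster benchmark
requires both to recover the truth (ARI >= 0.9). Ties in the selection
criterion go to the smaller k; with a fixed seed both backends are
deterministic.

`ros_score()` then measures each cluster's relationship to a reference
gene list — canonically GO_RESPONSE_TO_OXIDATIVE_STRESS, reflecting the
oxidative-stress biology of fumarate response — as the number of distinct
cluster genes found in the reference. Both the count and the fraction of
the cluster's gene pool are reported: the count is the traditional
statement, the fraction comparable across clusters of different sizes.

## Genotype QC and association

Marker QC applies the standard triad with the conventional thresholds:
minor allele frequency > 0.02, call rate > 0.98, and Hardy–Weinberg
equilibrium exact P >= 1e-4 computed among controls (cases may deviate
from HWE through real association). The HWE test is the exact conditional
(Levene–Haldane) test rather than the chi-square approximation, which is
unreliable at exactly the low MAFs the filter targets; the implementation
is verified against full enumeration for every genotype configuration with
up to 20 individuals. Relatedness pruning is not implemented (IBD
estimation is out of scope); the QC report carries a placeholder column so
externally pruned inputs remain representable.

Population stratification is handled with genotype principal components:
dosages are standardized GWAS-style (centred at $2p$, scaled by
$\sqrt{2p(1-p)}$), missing calls mean-imputed for the PCA only, and the 11
leading components (the count conventional for this correction) used as
covariates. Screening components by an association test before inclusion
— as is sometimes done — is not implemented, because the screening test is
rarely specified precisely; including all requested components is the
conservative, documented behaviour.

`logistic_assoc()` and `quant_assoc()` fit per-SNP additive-dosage models
(logistic for the binary response, OLS for the quantitative ROS trait)
with Wald tests on the dosage coefficient. Missing dosages are excluded
casewise per SNP in the fits (not imputed), mirroring common GWAS
practice. Complete separation and non-convergence are flagged per SNP with
`p = NA` rather than aborting a whole scan. Calibration is tested: null
type-I error within the exact binomial interval, planted OR = 1.6
recovered in the mean over seeds, and 2-SE coverage of a planted
quantitative slope at the nominal rate.

## The synthetic-data generators

Every stage is testable offline because the generators plant exactly the
structure the models assume:

* **Methylome**: profiles $M^\*$ are iid Beta(0.5, 0.5) — essentially
  uncorrelated columns, i.e. well-separated cell types; mixtures
  $\Omega^\*$ are Dirichlet per timepoint (uniform concentration by
  default; unequal per-timepoint vectors shift composition over time);
  responsive CpGs get $\pm\delta_\beta$ at post-baseline timepoints in the
  responder half of subjects (a fixed index split, so tests are
  deterministic); batches add per-batch constants; noise is additive
  Gaussian on the beta scale with clipping to $[0,1]$ (a logit-normal
  option exists). Defaults are desk-scale — 12 subjects, 3 timepoints,
  5000 CpGs, noise sd 0.03, $\delta_\beta$ = 0.10 over 100 CpGs — because
  the real design's effect sizes are not published; array-scale is a
  config choice, not a different code path.
* **Gene sets**: clusters draw from disjoint gene pools; cross-cluster
  overlap comes only from a small background admixture (rate 0.02 by
  default) drawn outside every pool.
* **Genotypes**: per-SNP allele frequencies uniform on the configured MAF
  range, genotypes binomial under HWE, a logistic phenotype with a planted
  per-dosage odds ratio (intercept centred for ~0.5 prevalence), a linear
  quantitative trait with unit noise, and an optional two-subpopulation
  allele-frequency divergence for exercising the PCA correction.

What the generators do *not* emulate: probe-type chemistry, genomic
autocorrelation of methylation, realistic LD between SNPs, cell-type
mixtures correlated with outcome, and non-additive batch effects. Passing
recovery tests therefore demonstrates correctness of the estimators under
their stated assumptions, not robustness to everything real arrays do.

## Numerical and reproducibility notes

* One seed drives any stage; pipeline stage seeds derive deterministically
  from the global seed, and all result tables are written with fixed
  column order and 6-decimal floats, so identical configurations produce
  byte-identical files (asserted end-to-end in the tests).
* Degenerate inputs are handled explicitly: all-identical samples make
  model-order selection meaningless (warning, $T = 1$); monomorphic SNPs
  return HWE P = 1 with a flag and are flagged in association fits;
  empty reference gene lists score 0 with a warning.
* Problem sizes in the tests (2000 CpGs / 60 samples for deconvolution
  benchmarks, 5000 CpGs / 12 pairs for null calibration, 2000 subjects for
  OR recovery) were chosen as the smallest sizes at which the planted
  effects are comfortably identifiable; they are the package's own
  benchmark conditions.
* Missing betas must be imputed (per-CpG median via `impute_betas()`)
  before deconvolution or modelling; fitting with missingness is rejected
  rather than silently handled.
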