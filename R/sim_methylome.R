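#' Configuration for the methylome simulator
#'
#' Parameterizes a longitudinal cell-mixture methylome: `n_subjects` subjects
#' sampled at each of the ordered `timepoints`, with betas generated as a
#' mixture of `n_celltypes_true` latent cell-type profiles plus planted
#' treatment effects, batch offsets and measurement noise. Defaults emulate a
#' desk-scale version of a before/after-treatment monocyte methylome design
#' (baseline, three and six months).
#'
#' @param n_subjects number of subjects (each measured at every timepoint).
#' @param timepoints ordered timepoint labels; at least 2 levels.
#' @param n_cpgs number of CpGs.
#' @param n_celltypes_true latent number of cell types T*.
#' @param dirichlet_alpha_by_timepoint numeric matrix (timepoints x T*) of
#'   Dirichlet concentrations for the per-sample mixture rows; a single
#'   vector is recycled across timepoints. Unequal rows shift the expected
#'   mixture over time.
#' @param n_responsive_cpgs number of planted treatment-responsive CpGs
#'   (half hypermethylated, half hypomethylated in responders after
#'   baseline).
#' @param delta_beta planted effect size on the beta scale, in (0,1).
#' @param noise_sd Gaussian measurement noise sd on the beta scale (values
#'   are clipped back to \[0,1\]).
#' @param noise_model `"gaussian"` (additive on the beta scale, default) or
#'   `"logit"` (additive on the logit scale).
#' @param batch_labels per-subject batch assignment (recycled); all samples
#'   of a subject share a batch.
#' @param batch_shift named numeric vector of additive per-batch beta-scale
#'   offsets (or a single number applied to every batch).
#' @param seed integer RNG seed; all outputs are reproducible from it.
#' @return a `methylome_sim_config` list.
#' @export
methylome_sim_config <- function(n_subjects = 12,
                                 timepoints = c("BL", "M3", "M6"),
                                 n_cpgs = 5000,
                                 n_celltypes_true = 3,
                                 dirichlet_alpha_by_timepoint = NULL,
                                 n_responsive_cpgs = 100,
                                 delta_beta = 0.10,
                                 noise_sd = 0.03,
                                 noise_model = c("gaussian", "logit"),
                                 batch_labels = "b1",
                                 batch_shift = 0,
                                 seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (n_celltypes_true < 1) stop_fmt("need at least one true cell type")
  if (length(timepoints) < 2) stop_fmt("need at least 2 timepoint levels")
  if (anyDuplicated(timepoints)) stop_fmt("duplicate timepoint labels")
  if (!(delta_beta > 0 && delta_beta < 1) && n_responsive_cpgs > 0)
    stop_fmt("delta_beta must lie in (0,1)")
  if (noise_sd < 0) stop_fmt("noise_sd must be >= 0")
  if (n_responsive_cpgs > n_cpgs)
    stop_fmt("n_responsive_cpgs exceeds n_cpgs")
  Tk <- n_celltypes_true
  if (is.null(dirichlet_alpha_by_timepoint))
    dirichlet_alpha_by_timepoint <- matrix(1, length(timepoints), Tk)
  if (is.vector(dirichlet_alpha_by_timepoint))
    dirichlet_alpha_by_timepoint <-
      matrix(dirichlet_alpha_by_timepoint, length(timepoints), Tk, byrow = TRUE)
  stopifnot(nrow(dirichlet_alpha_by_timepoint) == length(timepoints),
            ncol(dirichlet_alpha_by_timepoint) == Tk,
            all(dirichlet_alpha_by_timepoint > 0))
  structure(list(n_subjects = n_subjects, timepoints = timepoints,
                 n_cpgs = n_cpgs, n_celltypes_true = Tk,
                 dirichlet_alpha_by_timepoint = dirichlet_alpha_by_timepoint,
                 n_responsive_cpgs = n_responsive_cpgs,
                 delta_beta = delta_beta, noise_sd = noise_sd,
                 noise_model = noise_model,
                 batch_labels = batch_labels, batch_shift = batch_shift,
                 seed = as.integer(seed)),
            class = "methylome_sim_config")
}

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Simulate a longitudinal cell-mixture methylome
#'
#' Generates `Y = clip(M %*% t(Omega) + treatment + batch + noise, 0, 1)`:
#' cell-type profiles `M` (CpG-by-T*, iid Beta(0.5, 0.5) so profiles are
#' essentially uncorrelated), per-sample mixtures `Omega` drawn from the
#' configured Dirichlet, planted responsive CpGs shifted by `+/- delta_beta`
#' at post-baseline timepoints in the responder half of subjects (subjects
#' are split responder/non-responder by index, first half responders), an
#' additive per-batch constant, and Gaussian noise. The paired design (every
#' subject at every timepoint) is recorded in the sample sheet.
#'
#' @param config a [methylome_sim_config()].
#' @return list with elements `Y` (beta matrix), `sheet` (sample sheet) and
#'   `truth` (list: `true_M`, `true_Omega`, `responsive_cpg_ids`,
#'   `responsive_direction`, `responder_subjects`).
#' @export
simulate_methylome <- function(config) {
  stopifnot(inherits(config, "methylome_sim_config"))
  cf <- config
  with_seed(cf$seed, {
    n_tp <- length(cf$timepoints)
    n_samp <- cf$n_subjects * n_tp
    subj <- sprintf("subj%02d", seq_len(cf$n_subjects))
    sid <- as.vector(outer(subj, cf$timepoints, paste, sep = "_"))
    tp <- rep(cf$timepoints, each = cf$n_subjects)
    cpg <- sprintf("cpg%06d", seq_len(cf$n_cpgs))

    M <- matrix(stats::rbeta(cf$n_cpgs * cf$n_celltypes_true, 0.5, 0.5),
                nrow = cf$n_cpgs,
                dimnames = list(cpg, sprintf("ct%d", seq_len(cf$n_celltypes_true))))
    Omega <- matrix(0, n_samp, cf$n_celltypes_true,
                    dimnames = list(sid, colnames(M)))
    for (k in seq_len(n_tp)) {
      rows <- which(tp == cf$timepoints[k])
      Omega[rows, ] <- rdirichlet(length(rows),
                                  cf$dirichlet_alpha_by_timepoint[k, ])
    }
    Y <- M %*% t(Omega)

    responders <- subj[seq_len(floor(cf$n_subjects / 2))]
    resp_ids <- character(0)
    direction <- character(0)
    if (cf$n_responsive_cpgs > 0) {
      resp_ids <- sort(sample(cpg, cf$n_responsive_cpgs))
      n_hyper <- ceiling(cf$n_responsive_cpgs / 2)
      direction <- stats::setNames(
        rep(c("hyper", "hypo"), c(n_hyper, cf$n_responsive_cpgs - n_hyper)),
        resp_ids)
      post <- tp != cf$timepoints[1]
      affected <- post & rep(subj %in% responders, n_tp)
      shift <- ifelse(direction == "hyper", cf$delta_beta, -cf$delta_beta)
      Y[resp_ids, affected] <- Y[resp_ids, affected] + shift
    }

    batch_by_subj <- rep_len(as.character(cf$batch_labels), cf$n_subjects)
    batch <- rep(batch_by_subj, n_tp)
    shifts <- cf$batch_shift
    if (is.null(names(shifts)))
      shifts <- stats::setNames(rep_len(shifts, length(unique(batch))),
                                unique(batch))
    Y <- Y + rep(shifts[batch], each = cf$n_cpgs)

    if (cf$noise_sd > 0) {
      eps <- matrix(stats::rnorm(length(Y), 0, cf$noise_sd), nrow(Y))
      if (cf$noise_model == "gaussian") {
        Y <- Y + eps
      } else {
        yc <- pmin(pmax(Y, 1e-6), 1 - 1e-6)
        Y <- stats::plogis(stats::qlogis(yc) + eps)
      }
    }
    Y <- pmin(pmax(Y, 0), 1)

    age_by_subj <- sample(25:60, cf$n_subjects, replace = TRUE)
    sex_by_subj <- sample(c("F", "M"), cf$n_subjects, replace = TRUE)
    sheet <- data.frame(
      sample_id = sid,
      subject_id = rep(subj, n_tp),
      timepoint = factor(tp, levels = cf$timepoints),
      group = ifelse(rep(subj %in% responders, n_tp),
                     "responder", "non-responder"),
      age = rep(age_by_subj, n_tp),
      sex = rep(sex_by_subj, n_tp),
      batch = batch,
      stringsAsFactors = FALSE)

    validate_beta_matrix(Y, "simulated beta matrix")
    list(Y = Y, sheet = sheet,
         truth = list(true_M = M, true_Omega = Omega,
                      responsive_cpg_ids = resp_ids,
                      responsive_direction = direction,
                      responder_subjects = responders))
  })
}
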