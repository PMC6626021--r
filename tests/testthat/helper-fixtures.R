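# Shared fixture builders; everything is generated in code at test time.

# Minimal paired two-timepoint design with iid N(mu, sd) betas (no signal).
null_beta_design <- function(n_subjects, n_cpgs, sd = 0.03, mu = 0.5,
                             seed = 1) {
  set.seed(seed)
  subj <- sprintf("s%02d", seq_len(n_subjects))
  sid <- c(paste0(subj, "_BL"), paste0(subj, "_M3"))
  Y <- matrix(pmin(pmax(rnorm(n_cpgs * length(sid), mu, sd), 0), 1),
              nrow = n_cpgs,
              dimnames = list(sprintf("cpg%05d", seq_len(n_cpgs)), sid))
  sheet <- data.frame(
    sample_id = sid,
    subject_id = rep(subj, 2),
    timepoint = rep(c("BL", "M3"), each = n_subjects),
    group = "responder",
    age = rep(seq(30, by = 2, length.out = n_subjects), 2),
    sex = rep(rep(c("F", "M"), length.out = n_subjects), 2),
    batch = "b1", stringsAsFactors = FALSE)
  list(Y = Y, sheet = sheet)
}

# Random gene-set collection for round-trip / oracle property tests.
random_collection <- function(n_sets, universe_size, seed) {
  set.seed(seed)
  universe <- sprintf("G%04d", seq_len(universe_size))
  sets <- lapply(seq_len(n_sets), function(i)
    sample(universe, sample(3:min(40, universe_size), 1)))
  names(sets) <- sprintf("set%03d", seq_len(n_sets))
  gene_set_collection(sets, rep("random", n_sets))
}

# Brute-force RR oracle: enumerates the universe and counts co-memberships
# per pair, computing observed over independence-expected co-membership.
rr_oracle <- function(collection, universe = NULL) {
  if (is.null(universe))
    universe <- unique(unlist(collection, use.names = FALSE))
  N <- length(universe)
  n <- length(collection)
  rr <- matrix(0, n, n, dimnames = list(names(collection), names(collection)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    co <- sum(vapply(universe, function(g)
      g %in% collection[[i]] && g %in% collection[[j]], logical(1)))
    p_co <- co / N
    p_i <- length(intersect(collection[[i]], universe)) / N
    p_j <- length(intersect(collection[[j]], universe)) / N
    rr[i, j] <- if (i == j) 1 / p_i else p_co / (p_i * p_j)
  }
  rr
}

# Exact HWE enumeration oracle: direct factorial formula for the
# Levene-Haldane conditional probability of every genotype configuration
# with the observed allele totals.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_A <- 2 * n_AA + n_Aa
  n_a <- 2 * n_aa + n_Aa
  if (n_A == 0 || n_a == 0) return(1)
  hs <- seq(0, min(n_A, n_a))
  hs <- hs[(n_A - hs) %% 2 == 0]
  prob <- vapply(hs, function(h) {
    aa <- (n_A - h) / 2; bb <- (n_a - h) / 2
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2) + lfactorial(n_A) + lfactorial(n_a) -
          lfactorial(2 * n))
  }, numeric(1))
  p_obs <- prob[match(n_Aa, hs)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-10)]))
}

# Rank-based AUROC of a score against a binary truth vector.
auroc <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
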