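# Reference-free cell-type deconvolution: factorize a beta matrix
# Y (CpG x sample) as M %*% t(Omega) with M in [0,1] and each Omega row on
# the probability simplex, by alternating constrained least squares.

# Exact minimizer of ||y - M w||^2 subject to w >= 0, sum(w) = 1 (or
# sum(w) <= 1 with allow_deficit), by an active-set method on the KKT
# system. A is crossprod(M) (T x T), b is crossprod(M, y).
simplex_ls <- function(A, b, allow_deficit = FALSE) {
  Tn <- length(b)
  if (allow_deficit) {
    # slack component absorbs the mass deficit; ridge keeps the bordered
    # system nonsingular in the slack coordinate
    A <- rbind(cbind(A, 0), 0)
    diag(A) <- diag(A) + 1e-10
    b <- c(b, 0)
  }
  n <- length(b)
  if (n == 1) return(1)
  free <- rep(TRUE, n)
  w <- rep(0, n)
  for (iter in seq_len(4L * n + 8L)) {
    F <- which(free)
    AF <- A[F, F, drop = FALSE]
    R <- tryCatch(chol(AF), error = function(e) {
      chol(AF + diag(1e-10 * max(diag(AF), 1), length(F)))
    })
    Ainv_b <- backsolve(R, forwardsolve(t(R), b[F]))
    Ainv_1 <- backsolve(R, forwardsolve(t(R), rep(1, length(F))))
    lambda <- (sum(Ainv_b) - 1) / sum(Ainv_1)
    wF <- Ainv_b - lambda * Ainv_1
    if (min(wF) < -1e-10) {
      drop <- F[which.min(wF)]
      free[drop] <- FALSE
      if (sum(free) == 0) { # numerically degenerate; fall back to vertex
        free[which.max(b - 0.5 * diag(A))] <- TRUE
      }
      next
    }
    w[] <- 0
    w[F] <- pmax(wF, 0)
    # KKT: zeroed coordinates must have nonnegative reduced gradient
    grad <- drop(A %*% w) - b + lambda
    Z <- which(!free)
    viol <- Z[grad[Z] < -1e-8]
    if (length(viol) == 0) break
    free[viol[which.min(grad[viol])]] <- TRUE
  }
  if (allow_deficit) w <- w[seq_len(Tn)]
  w
}

# Re-estimate mixture rows for samples in Y (CpG x n) holding M fixed.
# The simplex-constrained solve lives in compiled code; the relaxed
# sum <= 1 variant goes through the R active-set solver.
estimate_omega <- function(Y, M, allow_deficit = FALSE) {
  if (!allow_deficit) return(omega_update_cpp(unname(Y), unname(M)))
  A <- crossprod(M)
  B <- crossprod(M, Y)                 # T x n
  t(apply(B, 2, function(b) simplex_ls(A, b, allow_deficit = TRUE)))
}

# Box-constrained update of M by exact cyclic coordinate descent (each
# coordinate update is an exact clipped minimization, so the objective never
# increases). Vectorized over CpGs.
update_M <- function(Y, M, Omega, sweeps = 8L, tol = 1e-9) {
  G <- crossprod(Omega)                # T x T
  B <- Y %*% Omega                     # p x T
  Tn <- ncol(M)
  for (s in seq_len(sweeps)) {
    delta <- 0
    for (t in seq_len(Tn)) {
      if (G[t, t] <= 0) next
      mt <- (B[, t] - M %*% G[, t] + M[, t] * G[t, t]) / G[t, t]
      mt <- pmin(pmax(mt, 0), 1)
      delta <- max(delta, max(abs(mt - M[, t])))
      M[, t] <- mt
    }
    if (delta < tol) break
  }
  M
}

# Deterministic k-means++-style seeding: pick T sample columns, the first
# uniformly, later ones with probability proportional to squared distance to
# the nearest already-chosen column.
seed_columns <- function(Y, Tn) {
  n <- ncol(Y)
  chosen <- sample.int(n, 1)
  if (Tn > 1) {
    d2 <- colSums((Y - Y[, chosen[1]])^2)
    for (k in 2:Tn) {
      if (all(d2 <= 0)) {
        pick <- sample(setdiff(seq_len(n), chosen), 1)
      } else {
        pick <- sample.int(n, 1, prob = d2 / sum(d2))
      }
      chosen <- c(chosen, pick)
      d2 <- pmin(d2, colSums((Y - Y[, pick])^2))
    }
  }
  chosen
}

#' Fit a reference-free cell-type deconvolution
#'
#' Factorizes a complete beta matrix `Y` (CpG-by-sample) as
#' `M %*% t(Omega)`, with cell-type methylation profiles `M` box-constrained
#' to \[0,1\] and each sample's mixture row of `Omega` constrained to the
#' probability simplex, by alternating constrained least squares:
#' mixture rows are solved exactly by active-set simplex-constrained least
#' squares, profile rows by exact box-clipped coordinate descent. Both block
#' updates are exact minimizations, so the residual sum of squares is
#' non-increasing across iterations. Initialization is a deterministic
#' k-means++-style seeding of `T` sample columns driven by `seed`.
#'
#' @param Y numeric CpG-by-sample beta matrix without missing values (impute
#'   first, e.g. with [impute_betas()]).
#' @param T number of cell types, `1 <= T <= ncol(Y)`.
#' @param max_iter maximum alternating iterations.
#' @param tol relative RSS change below which iteration stops.
#' @param seed integer seed for the initialization.
#' @param allow_deficit relax the mixture constraint from `sum = 1` to
#'   `sum <= 1`.
#' @param init_M optional CpG-by-T matrix used as starting profiles
#'   (bypasses seeding; used for warm starts).
#' @return object of class `deconvolution_fit`: `M`, `Omega`, `T`,
#'   `objective_trajectory` (RSS after each iteration), `converged`, `seed`.
#' @export
fit_reffree <- function(Y, T, max_iter = 500L, tol = 1e-6, seed = 1L,
                        allow_deficit = FALSE, init_M = NULL) {
  if (any(!is.finite(Y))) stop_fmt("Y contains missing or non-finite values; impute first")
  if (T < 1) stop_fmt("T must be >= 1")
  if (T > ncol(Y)) stop_fmt("T = %d exceeds the number of samples (%d)", T, ncol(Y))
  Yv <- unname(Y)
  with_seed(seed, {
    M <- if (is.null(init_M)) Yv[, seed_columns(Yv, T), drop = FALSE]
         else unname(init_M)
    if (allow_deficit) {
      traj <- numeric(0)
      prev <- Inf
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        Omega <- estimate_omega(Yv, M, allow_deficit = TRUE)
        M <- update_M(Yv, M, Omega)
        rss <- sum((Yv - M %*% t(Omega))^2)
        traj <- c(traj, rss)
        if (is.finite(prev) && (prev - rss) <= tol * max(prev, 1e-12)) {
          converged <- TRUE
          break
        }
        prev <- rss
      }
    } else {
      res <- als_fit_cpp(Yv, M, as.integer(max_iter), tol)
      M <- res$M
      Omega <- res$Omega
      traj <- res$trajectory
      converged <- res$converged
    }
    dimnames(M) <- list(rownames(Y), sprintf("ct%d", seq_len(T)))
    dimnames(Omega) <- list(colnames(Y), colnames(M))
    structure(list(M = M, Omega = Omega, T = T,
                   objective_trajectory = traj, converged = converged,
                   seed = as.integer(seed)),
              class = "deconvolution_fit")
  })
}

#' Median-impute missing beta values per CpG
#'
#' @param Y beta matrix possibly containing NAs.
#' @return the matrix with each CpG's missing entries replaced by that
#'   CpG's median across samples.
#' @export
impute_betas <- function(Y) {
  miss <- which(is.na(Y), arr.ind = TRUE)
  if (nrow(miss) == 0) return(Y)
  med <- apply(Y, 1, stats::median, na.rm = TRUE)
  Y[miss] <- med[miss[, 1]]
  Y
}

#' Choose the number of cell types by bootstrapped out-of-bag deviance
#'
#' For each candidate `T` and each bootstrap replicate, samples are resampled
#' with replacement, the factorization is fitted on the resample (warm-started
#' from a fit on the full data), and an out-of-bag residual deviance is
#' recorded over the samples not drawn, with their mixture rows re-estimated
#' holding `M` fixed. The default `metric = "deviance"` is the Gaussian
#' deviance with per-CpG residual variances estimated on the training
#' resample (`sum(r^2 / sigma2_cpg) + n_oob * sum(log sigma2_cpg)`): an
#' over-parameterized model shrinks its training variances below the truth
#' and is punished on the held-out samples, so the curve turns upward past
#' the true number of cell types. `metric = "rss"` is the plain out-of-bag
#' sum of squared residuals. The same resamples are used for every `T`, so
#' replicates are paired across the candidate range. `epsilon` is the mean
#' per `T`; the chosen `T` minimizes it, ties going to the smaller model.
#'
#' @param Y complete beta matrix.
#' @param T_range candidate numbers of cell types (default 1..10).
#' @param n_boot bootstrap replicates (>= 2).
#' @param seed integer seed.
#' @param max_iter,tol passed to the bootstrap refits.
#' @param metric `"deviance"` (default) or `"rss"`.
#' @return object of class `selection_curve`: `T_values`, `epsilon`,
#'   `epsilon_se`, `chosen_T`, plus the full-data fits' final RSS.
#' @export
select_num_celltypes <- function(Y, T_range = 1:10, n_boot = 100L, seed = 1L,
                                 max_iter = 100L, tol = 1e-5,
                                 metric = c("deviance", "rss")) {
  metric <- match.arg(metric)
  if (n_boot < 2) stop_fmt("n_boot must be >= 2")
  T_range <- sort(unique(as.integer(T_range)))
  if (any(T_range < 1)) stop_fmt("T_range must be >= 1")
  n <- ncol(Y)
  if (max(T_range) > n) stop_fmt("largest T in T_range exceeds sample count")
  if (max(apply(Y, 2, stats::var)) < 1e-12 ||
      sum((Y - rowMeans(Y))^2) < 1e-10) {
    warn_fmt("samples are (near-)identical; selection is degenerate, chosen_T = 1")
    return(structure(list(T_values = 1L, epsilon = 0, epsilon_se = 0,
                          chosen_T = 1L, full_rss = NA_real_, seed = seed),
                     class = "selection_curve"))
  }
  with_seed(seed, {
    boots <- replicate(n_boot, {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(idx)) < n) return(idx)
      }
    }, simplify = FALSE)
    fit_seeds <- sample.int(2^30, length(T_range))
    eps <- se <- full_rss <- numeric(length(T_range))
    for (i in seq_along(T_range)) {
      Tt <- T_range[i]
      full <- fit_reffree(Y, Tt, max_iter = 200L, tol = tol,
                          seed = fit_seeds[i])
      full_rss[i] <- utils::tail(full$objective_trajectory, 1)
      dev <- vapply(boots, function(idx) {
        oob <- setdiff(seq_len(n), unique(idx))
        Yb <- Y[, idx, drop = FALSE]
        fb <- fit_reffree(Yb, Tt, max_iter = max_iter,
                          tol = tol, seed = 1L, init_M = full$M)
        Yo <- Y[, oob, drop = FALSE]
        Om <- estimate_omega(Yo, fb$M)
        R2 <- (Yo - fb$M %*% t(Om))^2
        if (metric == "rss") return(sum(R2))
        sig2 <- pmax(rowMeans((Yb - fb$M %*% t(fb$Omega))^2), 1e-8)
        sum(R2 / sig2) + length(oob) * sum(log(sig2))
      }, numeric(1))
      eps[i] <- mean(dev)
      se[i] <- stats::sd(dev) / sqrt(n_boot)
    }
    structure(list(T_values = T_range, epsilon = eps, epsilon_se = se,
                   chosen_T = T_range[which.min(eps)], full_rss = full_rss,
                   seed = as.integer(seed)),
              class = "selection_curve")
  })
}

#' Mixture proportions as model covariates
#'
#' Returns the fitted mixture matrix with its last column dropped: because
#' each row sums to one, the full matrix is exactly collinear with a model
#' intercept, so T-1 columns carry all the information.
#'
#' @param fit a [fit_reffree()] result.
#' @return sample-by-(T-1) data.frame of mixture covariates (0 columns when
#'   `T = 1`).
#' @export
omega_as_covariates <- function(fit) {
  stopifnot(inherits(fit, "deconvolution_fit"))
  om <- fit$Omega[, -ncol(fit$Omega), drop = FALSE]
  as.data.frame(om)
}
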