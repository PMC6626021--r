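# Pathway-clustering by relative-risk co-membership: pairwise RR between
# gene sets over the collection universe, clustering of the log2 RR matrix,
# and a per-cluster overlap score against a reference oxidative-stress set.

#' Pairwise relative-risk matrix of gene-set co-membership
#'
#' For sets A and B over the universe U (the union of all member genes in
#' the collection, N = |U|), the relative risk is the observed
#' co-membership over its expectation under independence:
#' `RR(A,B) = |A ∩ B| * N / (|A| * |B|)`. It is symmetric, equals 0 for
#' disjoint sets, and on the diagonal equals the self-overlap lift
#' `N / |A|`. A log2 transform with a pseudocount
#' (`log2(RR + pseudocount)`, default pseudocount 1, i.e. log1p) tames the
#' zero/heavy-tail structure for distance-based clustering: disjoint pairs
#' map to 0 and a single shared background gene no longer produces an
#' outlying feature coordinate.
#'
#' @param collection a [gene_set_collection()] with at least 2 non-empty
#'   sets.
#' @param pseudocount small positive value added before the log2 transform.
#' @param universe optional character vector overriding the gene universe
#'   (defaults to the union of the collection's members).
#' @return object of class `rr_matrix`: `set_names`, `rr`, `log2_rr`,
#'   `pseudocount`, `universe_size`.
#' @export
compute_rr_matrix <- function(collection, pseudocount = 1,
                              universe = NULL) {
  if (length(collection) < 2) stop_fmt("need at least 2 gene sets")
  if (any(lengths(collection) == 0)) stop_fmt("empty gene sets not allowed")
  genes <- unique(trimws(unlist(collection, use.names = FALSE)))
  if (is.null(universe)) universe <- genes
  N <- length(universe)
  # binary membership matrix: intersections come from one crossprod
  memb <- vapply(collection, function(g) as.numeric(universe %in% g),
                 numeric(N))
  a <- crossprod(memb)                       # |A ∩ B|
  sizes <- diag(a)
  rr <- a * N / outer(sizes, sizes)
  diag(rr) <- N / sizes
  dimnames(rr) <- list(names(collection), names(collection))
  structure(list(set_names = names(collection), rr = rr,
                 log2_rr = log2(rr + pseudocount),
                 pseudocount = pseudocount, universe_size = N),
            class = "rr_matrix")
}

mean_silhouette <- function(features, labels) {
  if (length(unique(labels)) < 2) return(0)
  mean(cluster::silhouette(labels, stats::dist(features))[, "sil_width"])
}

#' Cluster gene sets on their relative-risk profiles
#'
#' Rows of the log2 RR matrix are the feature vectors. Two backends are
#' provided because both appear in practice for this task: `kmeans`
#' (restarted Lloyd iterations, k chosen by maximum mean silhouette width)
#' and `gmm` (Gaussian mixture with diagonal covariance fitted by EM via
#' mclust, k chosen by BIC). Ties go to the smaller k; labels are
#' deterministic given the seed.
#'
#' @param rr an [compute_rr_matrix()] result.
#' @param method `"gmm"` (default, matching model-based practice) or
#'   `"kmeans"`.
#' @param k_range candidate cluster counts; a single value fixes k.
#' @param seed integer seed.
#' @param drop_diagonal zero the self-lift diagonal of the feature matrix
#'   before clustering.
#' @param nstart kmeans restarts.
#' @return object of class `cluster_result`: `labels` (named integer
#'   vector), `k`, `method`, `selection` (data.frame of per-k quality
#'   scores), `seed`.
#' @export
cluster_gene_sets <- function(rr, method = c("gmm", "kmeans"),
                              k_range = 2:10, seed = 1L,
                              drop_diagonal = FALSE, nstart = 10L) {
  method <- match.arg(method)
  stopifnot(inherits(rr, "rr_matrix"))
  n <- length(rr$set_names)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0) stop_fmt("k_range is empty")
  if (any(k_range < 1) || any(k_range > n))
    stop_fmt("k_range must lie within 1..%d", n)
  if (n < 3 && length(k_range) > 1)
    stop_fmt("k selection needs >= 3 sets; fit a fixed k instead")
  if (any(!is.finite(rr$log2_rr))) stop_fmt("non-finite RR features")
  features <- rr$log2_rr
  if (drop_diagonal) diag(features) <- 0

  with_seed(seed, {
    if (method == "kmeans") {
      n_distinct <- nrow(unique(features))
      sel <- data.frame(k = k_range, score = -Inf)
      fits <- vector("list", length(k_range))
      for (i in seq_along(k_range)) {
        k <- k_range[i]
        if (k > n_distinct) next     # unfittable: fewer distinct profiles
        fits[[i]] <- if (k == 1)
          list(cluster = rep(1L, n))
        else stats::kmeans(features, centers = k, nstart = nstart,
                           iter.max = 100)
        sel$score[i] <- mean_silhouette(features, fits[[i]]$cluster)
      }
      if (all(!is.finite(sel$score))) stop_fmt("no fittable k in k_range")
      best <- which(sel$score == max(sel$score))[1]   # ties -> smaller k
      labels <- fits[[best]]$cluster
      k <- k_range[best]
    } else {
      fit <- Mclust(features, G = k_range,
                    modelNames = c("EII", "VII", "EEI", "VEI", "VVI"),
                    verbose = FALSE)
      if (is.null(fit)) stop_fmt("Gaussian-mixture fit failed")
      bic <- apply(fit$BIC, 1, max, na.rm = TRUE)
      sel <- data.frame(k = as.integer(names(bic)), score = as.numeric(bic))
      labels <- fit$classification
      k <- fit$G
    }
    structure(list(labels = stats::setNames(as.integer(labels),
                                            rr$set_names),
                   k = as.integer(k), method = method, selection = sel,
                   seed = as.integer(seed)),
              class = "cluster_result")
  })
}

#' Per-cluster overlap score against a reference gene set
#'
#' For each cluster, pools the distinct member genes of its sets and counts
#' how many appear in the reference set (canonically
#' GO_RESPONSE_TO_OXIDATIVE_STRESS, giving a per-cluster "ROS score"). Both
#' the raw matched count and the fraction of the pool are reported, the
#' latter comparable across clusters of different size.
#'
#' @param clusters a [cluster_gene_sets()] result.
#' @param collection the clustered [gene_set_collection()].
#' @param reference character vector of reference gene symbols.
#' @return data.frame: cluster, n_sets, cluster_gene_total, matched_genes,
#'   fraction.
#' @export
ros_score <- function(clusters, collection, reference) {
  stopifnot(inherits(clusters, "cluster_result"))
  miss <- setdiff(names(collection), names(clusters$labels))
  if (length(miss))
    stop_fmt("cluster labels missing for set(s): %s",
             paste(utils::head(miss, 5), collapse = ", "))
  reference <- unique(trimws(reference))
  if (length(reference) == 0)
    warn_fmt("empty reference set; all scores are 0")
  ids <- sort(unique(clusters$labels))
  out <- lapply(ids, function(cl) {
    sets <- names(clusters$labels)[clusters$labels == cl]
    pool <- unique(unlist(collection[sets], use.names = FALSE))
    m <- length(intersect(pool, reference))
    data.frame(cluster = cl, n_sets = length(sets),
               cluster_gene_total = length(pool), matched_genes = m,
               fraction = if (length(pool)) m / length(pool) else 0)
  })
  do.call(rbind, out)
}
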