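#' Simulate a gene-set collection with planted cluster structure
#'
#' Gene sets within a cluster draw their members from a shared pool of
#' `within_cluster_pool` genes (high pairwise overlap); pools of different
#' clusters are disjoint, so cross-cluster overlap arises only through a
#' small admixture of background genes drawn from the remainder of the
#' universe at rate `background_overlap_rate`.
#'
#' @param n_clusters number of planted clusters.
#' @param sets_per_cluster gene sets per cluster.
#' @param genes_per_set members per set.
#' @param within_cluster_pool pool size per cluster; must be >=
#'   `genes_per_set`.
#' @param universe_size total genes available; must cover all pools.
#' @param background_overlap_rate fraction of each set drawn from the shared
#'   background (outside every pool), in \[0, 1).
#' @param seed integer RNG seed.
#' @return list with `collection` (a [gene_set_collection()]) and `truth`
#'   (named integer vector of planted cluster labels per set).
#' @export
simulate_genesets <- function(n_clusters = 3, sets_per_cluster = 10,
                              genes_per_set = 30, within_cluster_pool = 60,
                              universe_size = 1000,
                              background_overlap_rate = 0.02,
                              seed = 1L) {
  if (within_cluster_pool < genes_per_set)
    stop_fmt("within_cluster_pool must be >= genes_per_set")
  if (universe_size < n_clusters * within_cluster_pool)
    stop_fmt("universe too small for %d disjoint pools of %d genes",
             n_clusters, within_cluster_pool)
  if (background_overlap_rate < 0 || background_overlap_rate >= 1)
    stop_fmt("background_overlap_rate must lie in [0,1)")
  with_seed(seed, {
    universe <- sprintf("g%05d", seq_len(universe_size))
    pool_idx <- matrix(seq_len(n_clusters * within_cluster_pool),
                       ncol = n_clusters)
    background <- universe[-seq_len(n_clusters * within_cluster_pool)]
    n_bg <- round(background_overlap_rate * genes_per_set)
    if (n_bg > 0 && length(background) == 0)
      stop_fmt("no background genes available for the requested overlap rate")
    sets <- list()
    labels <- integer(0)
    for (cl in seq_len(n_clusters)) {
      pool <- universe[pool_idx[, cl]]
      for (s in seq_len(sets_per_cluster)) {
        nm <- sprintf("set%03d", length(sets) + 1L)
        members <- sample(pool, genes_per_set - n_bg)
        if (n_bg > 0)
          members <- c(members, sample(background, n_bg))
        sets[[nm]] <- members
        labels[nm] <- cl
      }
    }
    list(collection = gene_set_collection(sets,
           rep("simulated gene set", length(sets))),
         truth = labels)
  })
}
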