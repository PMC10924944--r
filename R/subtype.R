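## Feature selection and consensus clustering of tumor samples on the
## interaction-perturbation matrix.

#' Select representative perturbation features
#'
#' An edge is representative when it (1) separates tumor from normal
#' samples and (2) stays heterogeneous across tumors.  Edges are ranked by
#' the absolute two-sided Wilcoxon rank-sum statistic (tumor vs normal
#' perturbation values) and, separately, by their standard deviation over
#' tumor samples; the intersection of the two top-k lists is returned.
#' Defaults follow the convention of taking the top 6000 of each list;
#' values exceeding the edge count are clamped with a warning.
#'
#' @param pmat edges x samples perturbation matrix (normal + tumor).
#' @param condition per-sample condition, `"normal"` / `"tumor"`.
#' @param k_diff,k_sd top-list sizes (default 6000 each).
#' @return list: `selected_edges`, `diff_stat` (per-edge |z|), `sd`
#'   (per-edge tumor SD), `k_diff`, `k_sd`.
#' @export
select_features <- function(pmat, condition, k_diff = 6000, k_sd = 6000) {
  condition <- as.character(condition)
  stopifnot(length(condition) == ncol(pmat))
  if (!all(c("normal", "tumor") %in% condition))
    stopf("both conditions must be present")
  ne <- nrow(pmat)
  if (k_diff > ne || k_sd > ne) {
    warning(sprintf("top-k (%d/%d) exceeds edge count %d; clamping",
                    k_diff, k_sd, ne))
    k_diff <- min(k_diff, ne); k_sd <- min(k_sd, ne)
  }
  tumor <- condition == "tumor"
  z <- abs(row_wilcox_z(pmat, tumor))
  sd_t <- row_sds(pmat[, tumor, drop = FALSE])
  top_diff <- rownames(pmat)[order(-z)][seq_len(k_diff)]
  top_sd <- rownames(pmat)[order(-sd_t)][seq_len(k_sd)]
  sel <- rownames(pmat)[rownames(pmat) %in% intersect(top_diff, top_sd)]
  list(selected_edges = sel,
       diff_stat = stats::setNames(z, rownames(pmat)),
       sd = stats::setNames(sd_t, rownames(pmat)),
       k_diff = k_diff, k_sd = k_sd)
}

## Spearman distance between columns: 1 - Pearson cor of column ranks.
spearman_distance <- function(mat) {
  ranks <- apply(mat, 2, rank, ties.method = "average")
  const <- apply(mat, 2, function(v) length(unique(v)) == 1)
  if (any(const))
    stopf("constant feature column(s) make Spearman undefined: %s",
          paste(colnames(mat)[const], collapse = ", "))
  1 - stats::cor(ranks)
}

#' Consensus clustering with PAM on 1-Spearman distance
#'
#' For each of `iters` iterations a fraction `subsample` of samples is
#' drawn without replacement; pairwise distance is 1 minus the Spearman
#' correlation of the sample columns; partitioning around medoids (PAM,
#' deterministic build+swap) is run for every K in `k_range`.  The
#' consensus matrix entry M_K(i, j) is the fraction of iterations in which
#' i and j were clustered together among iterations sampling both.  Final
#' per-K labels come from average-linkage hierarchical clustering of
#' 1 - M_K; the CDF of off-diagonal consensus values, its area, and the
#' relative delta-area then select the recommended K (see
#' [cdf_delta_area()]).
#'
#' @param feature_matrix features (edges) x samples matrix.
#' @param k_range integer vector of cluster numbers (default 2:10).
#' @param iters subsampling iterations (default 1000).
#' @param subsample fraction of samples per iteration (default 0.8).
#' @param seed integer master seed.
#' @param delta_threshold relative delta-area threshold for K selection
#'   (default 0.1).
#' @return a `consensus_result`: list with `k_range`, `consensus` (list of
#'   per-K matrices), `labels` (list of per-K named label vectors), `cdf`
#'   (per-K function-ready ecdf objects), `areas`, `deltas`,
#'   `recommended_k`.
#' @export
consensus_cluster <- function(feature_matrix, k_range = 2:10, iters = 1000,
                              subsample = 0.8, seed = 1L,
                              delta_threshold = 0.1) {
  n <- ncol(feature_matrix)
  k_range <- sort(unique(as.integer(k_range)))
  if (n < max(k_range) + 1)
    stopf("need at least max(k_range)+1 = %d samples, got %d",
          max(k_range) + 1, n)
  samples <- colnames(feature_matrix) %||% paste0("s", seq_len(n))
  ## distance depends only on full feature columns -> compute once,
  ## subset per iteration
  D <- spearman_distance(feature_matrix)
  m <- max(2L, floor(subsample * n))
  set.seed(as.integer(seed))
  co_cluster <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_cluster) <- as.character(k_range)
  co_sample <- matrix(0, n, n)
  for (it in seq_len(iters)) {
    idx <- sort(sample.int(n, m))
    co_sample[idx, idx] <- co_sample[idx, idx] + 1
    d_sub <- stats::as.dist(D[idx, idx])
    for (k in k_range) {
      cl <- cluster::pam(d_sub, k, diss = TRUE, cluster.only = TRUE,
                         pamonce = 5)
      same <- outer(cl, cl, "==")
      kk <- as.character(k)
      co_cluster[[kk]][idx, idx] <- co_cluster[[kk]][idx, idx] + same
    }
  }
  off <- upper.tri(co_sample)
  if (any(co_sample[off] == 0))
    stopf("some sample pairs were never co-sampled; increase iters")
  consensus <- lapply(co_cluster, function(cc) {
    M <- cc / pmax(co_sample, 1)
    diag(M) <- 1
    dimnames(M) <- list(samples, samples)
    M
  })
  labels <- stats::setNames(vector("list", length(k_range)),
                            as.character(k_range))
  for (k in k_range) {
    M <- consensus[[as.character(k)]]
    hc <- stats::hclust(stats::as.dist(1 - M), method = "average")
    labels[[as.character(k)]] <- stats::setNames(stats::cutree(hc, k),
                                                 samples)
  }
  cdfs <- lapply(consensus, function(M) stats::ecdf(M[upper.tri(M)]))
  sel <- cdf_delta_area(consensus, delta_threshold = delta_threshold)
  structure(list(k_range = k_range, consensus = consensus, labels = labels,
                 cdf = cdfs, areas = sel$areas, deltas = sel$deltas,
                 recommended_k = sel$recommended_k),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: K in {%s}; recommended K = %d\n",
              paste(x$k_range, collapse = ","), x$recommended_k))
  invisible(x)
}

#' CDF area and delta-area K selection
#'
#' For each K, A(K) is the area under the empirical CDF of the
#' off-diagonal consensus values.  The relative area change is
#' Delta(2) = A(2) and Delta(K) = (A(K) - A(K-1)) / A(K-1) for K > 2; the
#' recommended K is the largest K whose relative gain still reaches
#' `delta_threshold` — the point after which further splitting adds only
#' an insignificant increase.
#'
#' @param consensus_per_k named list (K -> consensus matrix), or a
#'   `consensus_result`.
#' @param delta_threshold minimum relative gain (default 0.1).
#' @return list: `areas`, `deltas` (named by K), `recommended_k`.
#' @export
cdf_delta_area <- function(consensus_per_k, delta_threshold = 0.1) {
  if (inherits(consensus_per_k, "consensus_result"))
    consensus_per_k <- consensus_per_k$consensus
  ks <- as.integer(names(consensus_per_k))
  stopifnot(length(ks) >= 2, !is.unsorted(ks))
  ## integrate the empirical CDF over [0,1] using left step heights
  areas <- vapply(consensus_per_k, function(M) {
    x <- sort(M[upper.tri(M)])
    grid <- unique(c(0, x, 1))
    cdf <- stats::ecdf(x)
    heights <- cdf(grid[-length(grid)])
    sum(diff(grid) * heights)
  }, numeric(1))
  deltas <- numeric(length(ks))
  names(deltas) <- names(areas) <- as.character(ks)
  deltas[1] <- areas[1]
  if (length(ks) > 1)
    for (i in 2:length(ks))
      deltas[i] <- (areas[i] - areas[i - 1]) / areas[i - 1]
  ok <- which(deltas >= delta_threshold)
  recommended_k <- if (length(ok)) ks[max(ok)] else ks[1]
  list(areas = areas, deltas = deltas, recommended_k = recommended_k)
}
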