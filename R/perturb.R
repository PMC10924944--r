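## The core statistic: per-sample interaction-perturbation of network
## edges against a normal-tissue benchmark.
##
## Four steps: (1) within-sample gene ranks; (2) per-edge delta ranks
## (rank difference of the two endpoints, canonical orientation);
## (3) benchmark = delta rank of the mean normal expression profile;
## (4) perturbation = delta rank minus benchmark.

check_network_genes <- function(expr, network) {
  missing <- setdiff(network$nodes, rownames(expr))
  if (length(missing))
    stopf("expression matrix lacks %d network gene(s): %s%s",
          length(missing), paste(utils::head(missing, 5), collapse = ", "),
          if (length(missing) > 5) ", ..." else "")
}

#' Within-sample gene rank matrix
#'
#' Ranks every gene within each sample by expression, ascending (1 = lowest
#' expression); ties receive average (fractional) ranks.  Because only the
#' ordering enters, all downstream statistics are invariant to any strictly
#' monotone per-sample transform of the expression values.
#'
#' @param expr genes x samples numeric matrix (log2 expression).
#' @param network optional `interaction_network`; if supplied, `expr` is
#'   first restricted to the network genes (erroring on missing genes).
#' @return genes x samples matrix of ranks.
#' @export
rank_matrix <- function(expr, network = NULL) {
  if (!is.null(network)) {
    check_network_genes(expr, network)
    expr <- expr[network$nodes, , drop = FALSE]
  }
  if (nrow(expr) < 2) stopf("need >= 2 genes to rank")
  apply(expr, 2, rank, ties.method = "average")
}

#' Per-edge delta-rank matrix
#'
#' For every canonical edge (a, b) and sample j,
#' `delta(e, j) = rank(a, j) - rank(b, j)`.  The fixed canonical
#' orientation guarantees subtraction "in the same direction" for every
#' sample; reversing an edge's orientation negates its row.
#'
#' @param ranks genes x samples rank matrix (from [rank_matrix()]).
#' @param network an `interaction_network`.
#' @return edges x samples matrix, rownames `geneA|geneB`.
#' @export
delta_rank <- function(ranks, network) {
  e <- network$edges
  missing <- setdiff(unique(c(e$gene_a, e$gene_b)), rownames(ranks))
  if (length(missing))
    stopf("rank matrix lacks edge endpoint(s): %s",
          paste(utils::head(missing, 5), collapse = ", "))
  d <- ranks[e$gene_a, , drop = FALSE] - ranks[e$gene_b, , drop = FALSE]
  rownames(d) <- e$edge_id
  d
}

#' Normal-tissue benchmark delta-rank vector
#'
#' The benchmark of each edge is its average delta rank across the normal
#' samples: every normal sample is ranked within itself, per-edge rank
#' differences are taken, and these delta ranks are averaged per edge.
#' Because it is computed entirely in rank space, the benchmark — and with
#' it the whole perturbation matrix — is exactly invariant to any strictly
#' monotone per-sample transform of the expression values.
#'
#' @param expr_normal genes x normal-samples expression matrix.
#' @param network an `interaction_network`.
#' @return named numeric vector, one benchmark delta rank per edge.
#' @export
benchmark_delta_rank <- function(expr_normal, network) {
  if (is.null(dim(expr_normal)))
    expr_normal <- matrix(expr_normal, ncol = 1,
                          dimnames = list(names(expr_normal), "normal"))
  if (ncol(expr_normal) < 1)
    stopf("benchmark undefined: no normal samples")
  check_network_genes(expr_normal, network)
  d <- delta_rank(rank_matrix(expr_normal, network), network)
  stats::setNames(rowMeans(d), rownames(d))
}

#' Interaction-perturbation matrix
#'
#' Elementwise subtraction of the benchmark vector from the delta-rank
#' matrix; rows keep the canonical edge order.
#'
#' @param delta edges x samples delta-rank matrix.
#' @param benchmark_vec named per-edge benchmark vector.
#' @return edges x samples perturbation matrix.
#' @export
perturbation_matrix <- function(delta, benchmark_vec) {
  if (!identical(rownames(delta), names(benchmark_vec)))
    stopf("edge sets of delta matrix and benchmark are not aligned")
  delta - benchmark_vec
}

#' Full interaction-perturbation pipeline for one cohort
#'
#' Restricts the expression matrix to network genes (edges whose endpoint
#' is absent from the cohort are dropped network-wide, with a message),
#' ranks within samples, computes delta ranks for all samples, benchmarks
#' against the normal samples, and returns the perturbation matrix for all
#' samples.
#'
#' @param expr genes x samples matrix (normal + tumor).
#' @param condition character vector per sample, values in
#'   `c("normal", "tumor")`.
#' @param network an `interaction_network`.
#' @return list: `pmat` (edges x samples), `delta`, `benchmark`, `network`
#'   (possibly reduced), `condition`.
#' @export
interaction_perturbation <- function(expr, condition, network) {
  stopifnot(length(condition) == ncol(expr))
  condition <- as.character(condition)
  if (!all(condition %in% c("normal", "tumor")))
    stopf("condition must be 'normal' or 'tumor'")
  if (sum(condition == "normal") < 1)
    stopf("benchmark undefined: no normal samples")
  missing <- setdiff(network$nodes, rownames(expr))
  if (length(missing)) {
    keep <- !(network$edges$gene_a %in% missing |
                network$edges$gene_b %in% missing)
    message(sprintf(
      "dropping %d edge(s) with endpoints absent from this cohort (%d gene(s))",
      sum(!keep), length(missing)))
    e <- network$edges[keep, , drop = FALSE]
    if (nrow(e) == 0) stopf("no network edges left after dropping missing genes")
    network <- structure(list(nodes = sort(unique(c(e$gene_a, e$gene_b))),
                              edges = e), class = "interaction_network")
  }
  ranks <- rank_matrix(expr, network)
  d <- delta_rank(ranks, network)
  b <- benchmark_delta_rank(expr[, condition == "normal", drop = FALSE],
                            network)
  list(pmat = perturbation_matrix(d, b), delta = d, benchmark = b,
       network = network, condition = condition)
}

#' Summaries of an interaction-perturbation matrix
#'
#' Per-sample mean absolute perturbation, per-condition distributions of
#' per-edge variance and range, and a two-sided Wilcoxon rank-sum test of
#' per-sample mean |p| between the two conditions (tumors are expected to
#' be more strongly perturbed than normals).
#'
#' @param pmat edges x samples perturbation matrix.
#' @param condition character vector per sample (two conditions).
#' @return list: `sample_mean_abs` (named vector), `condition_mean_abs`,
#'   `edge_variance` / `edge_range` (per-condition lists), `wilcox_p`.
#' @export
perturbation_summary <- function(pmat, condition) {
  stopifnot(length(condition) == ncol(pmat))
  condition <- as.character(condition)
  lv <- unique(condition)
  if (any(table(condition)[lv] == 0) || length(lv) < 2)
    stopf("need two nonempty conditions")
  sample_mean_abs <- colMeans(abs(pmat))
  by_cond <- function(f) lapply(stats::setNames(lv, lv), function(cd) {
    x <- pmat[, condition == cd, drop = FALSE]
    f(x)
  })
  edge_variance <- by_cond(function(x)
    if (ncol(x) > 1) row_sds(x)^2 else rep(0, nrow(x)))
  edge_range <- by_cond(function(x)
    apply(x, 1, function(v) diff(range(v))))
  wt <- stats::wilcox.test(sample_mean_abs[condition == lv[1]],
                           sample_mean_abs[condition == lv[2]],
                           exact = FALSE)
  list(sample_mean_abs = sample_mean_abs,
       condition_mean_abs = vapply(lv, function(cd)
         mean(sample_mean_abs[condition == cd]), numeric(1)),
       edge_variance = edge_variance,
       edge_range = edge_range,
       wilcox_p = wt$p.value)
}
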