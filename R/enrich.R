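## Single-sample gene-set scoring (ssGSEA) and grouped comparisons with
## FDR control.

#' Single-sample gene set enrichment (ssGSEA) scores
#'
#' Weighted empirical-CDF running sum per sample: genes are ordered by
#' decreasing expression; walking down that ordering, in-set genes add
#' their rank value raised to `alpha` (normalized over the set) while
#' out-of-set genes subtract uniformly; the enrichment score is the sum of
#' the running-sum deviations (the integrated difference of the weighted
#' in-set and uniform out-of-set ECDFs).  Scores depend only on each
#' sample's gene ordering.  With `normalize = TRUE` the whole matrix is
#' divided by its score range (max - min).
#'
#' @param expr genes x samples expression matrix.
#' @param gene_sets named list of character vectors.
#' @param alpha rank-weight exponent (default 0.25; 0 gives uniform
#'   in-set increments).
#' @param normalize divide all scores by the matrix-wide range
#'   (default TRUE).
#' @return gene sets x samples score matrix; sets with no gene present in
#'   `expr` get NA rows with a warning.
#' @export
ssgsea <- function(expr, gene_sets, alpha = 0.25, normalize = TRUE) {
  if (is.null(dim(expr)) || nrow(expr) == 0 || ncol(expr) == 0)
    stopf("empty expression matrix")
  stopifnot(length(gene_sets) > 0, !is.null(names(gene_sets)))
  G <- nrow(expr)
  genes <- rownames(expr)
  present <- lapply(gene_sets, function(g) g[g %in% genes])
  none <- vapply(present, length, 1L) == 0
  if (any(none))
    warning(sprintf("gene set(s) with no gene in expression: %s",
                    paste(names(gene_sets)[none], collapse = ", ")))
  scores <- matrix(NA_real_, length(gene_sets), ncol(expr),
                   dimnames = list(names(gene_sets), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    ## rank value: top-expressed gene carries weight G, lowest weight 1
    r <- rank(expr[, j], ties.method = "average")
    ord <- order(r, decreasing = TRUE)
    w <- abs(r[ord])^alpha
    in_set_mat <- vapply(present, function(g) genes[ord] %in% g,
                         logical(G))
    ## tied ranks are walked as one block (deviations evaluated at block
    ## ends), so scores are invariant to the arbitrary order within ties
    rv <- unname(r[ord])
    rid <- cumsum(c(1, diff(rv) != 0))
    run_end <- stats::ave(seq_len(G), rid, FUN = max)
    for (i in seq_along(gene_sets)) {
      if (none[i]) next
      in_set <- in_set_mat[, i]
      n_in <- sum(in_set)
      p_in <- cumsum(ifelse(in_set, w, 0)) / sum(w[in_set])
      p_out <- if (G > n_in) cumsum(!in_set) / (G - n_in) else numeric(G)
      scores[i, j] <- sum(p_in[run_end] - p_out[run_end])
    }
  }
  if (normalize) {
    rng <- range(scores, na.rm = TRUE)
    if (diff(rng) > 0) scores <- scores / diff(rng)
  }
  scores
}

#' Grouped comparisons with BH-FDR across rows
#'
#' Runs one test per row of `values` across `groups` —
#' Kruskal-Wallis (any number of groups), two-sided Wilcoxon rank-sum
#' (two groups), or chi-square of the row's categorical values against the
#' grouping — and adjusts the p-values across rows by Benjamini-Hochberg.
#'
#' @param values numeric matrix (rows = gene sets / variables, columns =
#'   samples), a numeric vector, or for `test = "chisq"` a vector/matrix
#'   of categorical labels.
#' @param groups group label per column/element (>= 2 nonempty groups).
#' @param test one of "kruskal", "wilcoxon", "chisq".
#' @return data.frame: variable, test, statistic, p, q, and per-group
#'   medians (numeric tests only).
#' @export
compare_groups <- function(values, groups,
                           test = c("kruskal", "wilcoxon", "chisq")) {
  test <- match.arg(test)
  if (is.null(dim(values)))
    values <- matrix(values, nrow = 1,
                     dimnames = list("value", names(values)))
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(values))
  lv <- unique(groups)
  if (length(lv) < 2) stopf("need >= 2 groups")
  if (test == "wilcoxon" && length(lv) != 2)
    stopf("wilcoxon requires exactly 2 groups")
  one <- function(v) {
    switch(test,
      kruskal = {
        ht <- stats::kruskal.test(as.numeric(v), factor(groups))
        c(ht$statistic, ht$p.value)
      },
      wilcoxon = {
        ht <- stats::wilcox.test(as.numeric(v[groups == lv[1]]),
                                 as.numeric(v[groups == lv[2]]))
        c(ht$statistic, ht$p.value)
      },
      chisq = {
        ht <- suppressWarnings(stats::chisq.test(table(v, groups)))
        c(ht$statistic, ht$p.value)
      })
  }
  res <- t(apply(values, 1, one))
  out <- data.frame(variable = rownames(values) %||% seq_len(nrow(values)),
                    test = test, statistic = res[, 1], p = res[, 2],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$q <- stats::p.adjust(out$p, method = "BH")
  if (test != "chisq") {
    for (g in lv)
      out[[paste0("median_", g)]] <-
        apply(values[, groups == g, drop = FALSE], 1,
              function(v) stats::median(as.numeric(v)))
  }
  out
}
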