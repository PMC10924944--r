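## Subtype signatures and nearest-template prediction (NTP): propagate
## discovered subtypes to external cohorts / single cells.

#' Derive subtype signature genes
#'
#' One-vs-rest two-sided Wilcoxon rank-sum test per gene and subtype, with
#' Benjamini-Hochberg FDR across genes within each subtype.  Up-regulated
#' genes (mean log2 difference > `lfc_min`, q < `fdr_max`) are kept, ranked
#' by effect size, and capped at `top_n` per subtype.  A gene passing for
#' several subtypes is assigned only to the subtype where its effect is
#' largest, so signature sets are pairwise disjoint.
#'
#' @param expr genes x samples log2 expression matrix (tumor samples).
#' @param labels subtype label per sample (integer or factor).
#' @param fdr_max BH-FDR cutoff (default 0.05).
#' @param lfc_min minimum mean log2 difference (default 0.2).
#' @param top_n cap per subtype (default 200).
#' @return a `subtype_model`: list with `signatures` (subtype -> genes),
#'   `stats` (data.frame gene, subtype, effect, p, q), `subtypes`.
#' @export
derive_signatures <- function(expr, labels, fdr_max = 0.05, lfc_min = 0.2,
                              top_n = 200) {
  stopifnot(length(labels) == ncol(expr))
  labels <- as.character(labels)
  subtypes <- sort(unique(labels))
  if (length(subtypes) < 2) stopf("need >= 2 subtypes")
  if (any(table(labels) < 3)) stopf("each subtype needs >= 3 samples")
  res <- list()
  for (s in subtypes) {
    in_s <- labels == s
    eff <- rowMeans(expr[, in_s, drop = FALSE]) -
      rowMeans(expr[, !in_s, drop = FALSE])
    p <- apply(expr, 1, function(v)
      stats::wilcox.test(v[in_s], v[!in_s], exact = FALSE)$p.value)
    q <- stats::p.adjust(p, method = "BH")
    res[[s]] <- data.frame(gene = rownames(expr), subtype = s,
                           effect = eff, p = p, q = q,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  all_stats <- do.call(rbind, res)
  pass <- all_stats[all_stats$effect > lfc_min & all_stats$q < fdr_max, ]
  if (nrow(pass)) {
    ## disjointness: each gene goes to the subtype with the largest effect
    pass <- pass[order(pass$gene, -pass$effect), ]
    pass <- pass[!duplicated(pass$gene), ]
  }
  signatures <- lapply(stats::setNames(subtypes, subtypes), function(s) {
    g <- pass[pass$subtype == s, ]
    g <- g[order(-g$effect), ]
    utils::head(g$gene, top_n)
  })
  empty <- names(signatures)[vapply(signatures, length, 1L) == 0]
  if (length(empty))
    stopf("empty signature for subtype(s): %s", paste(empty, collapse = ", "))
  structure(list(signatures = signatures, stats = all_stats,
                 subtypes = subtypes),
            class = "subtype_model")
}

#' @export
print.subtype_model <- function(x, ...) {
  cat(sprintf("subtype_model: %d subtypes; signature sizes %s\n",
              length(x$subtypes),
              paste(vapply(x$signatures, length, 1L), collapse = "/")))
  invisible(x)
}

cosine_distance_to_templates <- function(Z, templates) {
  ## Z: genes x samples (z-scored); templates: genes x K indicator matrix
  zn <- sqrt(colSums(Z^2))
  tn <- sqrt(colSums(templates^2))
  sim <- crossprod(templates, Z) / outer(tn, zn)
  1 - sim  # K x samples
}

#' Nearest-template prediction with permutation confidence
#'
#' Each sample is restricted to the union of the model's signature genes,
#' z-scored across genes within the sample, and assigned to the subtype
#' whose indicator template has the smallest cosine distance.  Confidence:
#' `n_perm` draws of random same-size gene-set templates (one per subtype,
#' minimum distance taken, mirroring the argmin selection) give
#' `p = (1 + #{null min distance <= observed}) / (n_perm + 1)`; BH-FDR is
#' applied across samples and samples with q below `fdr_threshold` count
#' as successfully classified.
#'
#' @param expr_new genes x samples log2 expression matrix.
#' @param model a `subtype_model` from [derive_signatures()].
#' @param n_perm permutation draws (default 1000).
#' @param fdr_threshold FDR cutoff for the classified flag (default 0.2).
#' @param seed integer seed for the permutation null.
#' @return data.frame: sample, predicted, one `dist_<subtype>` column per
#'   subtype, p, q, classified, tie (argmin tie broken by subtype order).
#' @export
ntp_classify <- function(expr_new, model, n_perm = 1000, fdr_threshold = 0.2,
                         seed = 1L) {
  sig <- model$signatures
  union_genes <- unique(unlist(sig, use.names = FALSE))
  present <- union_genes[union_genes %in% rownames(expr_new)]
  if (length(present) < 0.5 * length(union_genes))
    stopf("only %d/%d signature genes present (< 50%%); missing e.g.: %s",
          length(present), length(union_genes),
          paste(utils::head(setdiff(union_genes, present), 5),
                collapse = ", "))
  X <- expr_new[present, , drop = FALSE]
  Z <- scale(X)  # z-score each sample (column) across genes
  Z[is.na(Z)] <- 0
  templates <- vapply(sig, function(g) as.numeric(present %in% g),
                      numeric(length(present)))
  rownames(templates) <- present
  dist_obs <- cosine_distance_to_templates(Z, templates)  # K x samples
  pred_idx <- apply(dist_obs, 2, which.min)
  tie <- apply(dist_obs, 2, function(d) sum(d == min(d)) > 1)
  obs_min <- apply(dist_obs, 2, min)

  ## permutation null: per draw, one random same-size set per subtype,
  ## min distance across them (shared across samples for speed)
  set.seed(as.integer(seed))
  sizes <- colSums(templates)
  G <- length(present)
  null_min <- matrix(Inf, n_perm, ncol(Z))
  for (b in seq_len(n_perm)) {
    Tb <- vapply(sizes, function(k) {
      v <- numeric(G); v[sample.int(G, min(k, G))] <- 1; v
    }, numeric(G))
    db <- cosine_distance_to_templates(Z, Tb)
    null_min[b, ] <- apply(db, 2, min)
  }
  p <- (1 + colSums(null_min <= rep(obs_min, each = n_perm))) / (n_perm + 1)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(sample = colnames(expr_new) %||% seq_len(ncol(expr_new)),
                    predicted = model$subtypes[pred_idx],
                    stringsAsFactors = FALSE)
  dmat <- t(dist_obs)
  colnames(dmat) <- paste0("dist_", model$subtypes)
  out <- cbind(out, as.data.frame(dmat))
  out$p <- p
  out$q <- q
  out$classified <- q < fdr_threshold
  out$tie <- tie
  rownames(out) <- NULL
  out
}

#' Assign cells to subtypes by maximal ssGSEA signature score
#'
#' Scores every cell (column) against each subtype's signature gene set
#' with [ssgsea()] and assigns the argmax; exact ties are broken by the
#' model's subtype order and flagged with margin 0.
#'
#' @param cell_expr genes x cells expression matrix.
#' @param model a `subtype_model`.
#' @param alpha ssGSEA rank-weight exponent (default 0.25).
#' @return data.frame: cell, assigned, margin (top minus runner-up score),
#'   plus one score column per subtype.
#' @export
ssgsea_assign <- function(cell_expr, model, alpha = 0.25) {
  if (any(vapply(model$signatures, length, 1L) == 0))
    stopf("model has an empty signature")
  scores <- ssgsea(cell_expr, model$signatures, alpha = alpha,
                   normalize = FALSE)
  assigned_idx <- apply(scores, 2, which.max)
  margin <- apply(scores, 2, function(v) {
    s <- sort(v, decreasing = TRUE)
    if (length(s) > 1) s[1] - s[2] else s[1]
  })
  out <- data.frame(cell = colnames(cell_expr) %||% seq_len(ncol(cell_expr)),
                    assigned = model$subtypes[assigned_idx],
                    margin = margin, stringsAsFactors = FALSE)
  smat <- t(scores)
  colnames(smat) <- paste0("score_", model$subtypes)
  cbind(out, as.data.frame(smat, row.names = NULL))
}
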