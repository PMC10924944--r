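## Background interaction network: assembly from gene sets + scored edge
## list, and degree-distribution characterization.

#' Read a GMT gene-set file
#'
#' @param path path to a GMT file (set name, description, members; tab
#'   separated).
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, unique)
}

#' Write a GMT gene-set file
#'
#' @param gene_sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(gene_sets, path) {
  stopifnot(length(gene_sets) > 0, !is.null(names(gene_sets)))
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a scored edge list TSV
#'
#' Expects columns `gene_a`, `gene_b`, `confidence` (header required).
#'
#' @param path TSV path.
#' @return data.frame with the three columns.
#' @export
read_edges <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "confidence")
  if (!all(need %in% colnames(df)))
    stopf("edge list %s must have columns %s", path,
          paste(need, collapse = ", "))
  bad <- which(!is.finite(df$confidence) | !nzchar(df$gene_a) |
                 !nzchar(df$gene_b))
  if (length(bad))
    stopf("malformed edge row(s) at line(s): %s",
          paste(bad + 1, collapse = ", "))
  df[need]
}

#' Assemble the pathway-restricted interaction network
#'
#' Edges are kept when their confidence is strictly greater than
#' `confidence_threshold` and both endpoints belong to the gene-set
#' universe (the union of all set members).  Self loops are dropped;
#' duplicate unordered pairs are collapsed to the maximum confidence; each
#' edge is stored in canonical orientation (`gene_a < gene_b`
#' lexicographically), which fixes the direction used for all downstream
#' delta ranks.  Genes left without any edge are not part of the network.
#'
#' @param gene_sets named list of character vectors (pathway members).
#' @param edge_list data.frame with columns gene_a, gene_b, confidence.
#' @param confidence_threshold retain edges with confidence strictly above
#'   this value (default 0.8).
#' @return an `interaction_network` object: list with `nodes` (character)
#'   and `edges` (data.frame gene_a, gene_b, confidence, edge_id).
#' @export
build_network <- function(gene_sets, edge_list, confidence_threshold = 0.8) {
  stopifnot(is.list(gene_sets), length(gene_sets) > 0)
  if (any(!vapply(gene_sets, length, 1L)))
    stopf("empty gene set in collection")
  universe <- unique(unlist(gene_sets, use.names = FALSE))
  el <- edge_list
  need <- c("gene_a", "gene_b", "confidence")
  if (!all(need %in% colnames(el))) stopf("edge_list needs columns %s",
                                          paste(need, collapse = ", "))
  el$gene_a <- as.character(el$gene_a)
  el$gene_b <- as.character(el$gene_b)
  keep <- el$confidence > confidence_threshold &
    el$gene_a %in% universe & el$gene_b %in% universe &
    el$gene_a != el$gene_b
  el <- el[keep, , drop = FALSE]
  if (nrow(el) == 0)
    stopf("no edges pass confidence > %g within the gene-set universe",
          confidence_threshold)
  ## canonical orientation, then collapse duplicates keeping max confidence
  flip <- el$gene_a > el$gene_b
  tmp <- el$gene_a[flip]; el$gene_a[flip] <- el$gene_b[flip]
  el$gene_b[flip] <- tmp
  key <- paste(el$gene_a, el$gene_b, sep = "|")
  ord <- order(key, -el$confidence)
  el <- el[ord, , drop = FALSE]
  el <- el[!duplicated(key[ord]), , drop = FALSE]
  el <- el[order(el$gene_a, el$gene_b), , drop = FALSE]
  rownames(el) <- NULL
  el$edge_id <- paste(el$gene_a, el$gene_b, sep = "|")
  structure(
    list(nodes = sort(unique(c(el$gene_a, el$gene_b))), edges = el),
    class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Network degrees
#' @param network an `interaction_network`.
#' @return named integer vector of node degrees.
#' @export
network_degrees <- function(network) {
  g <- igraph::graph_from_data_frame(network$edges[c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = network$nodes)
  igraph::degree(g)
}

#' Power-law (scale-free) fit of the degree distribution
#'
#' Least-squares fit of log10(frequency) on log10(degree) over degrees
#' observed at least once.  A strongly negative Pearson correlation r
#' indicates the power-law (scale-free) degree behavior typical of
#' biological networks.
#'
#' @param network an `interaction_network`, or a named/plain integer vector
#'   of node degrees.
#' @return list with `degrees` (table degree -> count), `r`, `p_value`,
#'   `slope`.
#' @export
scale_free_fit <- function(network) {
  deg <- if (inherits(network, "interaction_network"))
    network_degrees(network) else network
  deg <- deg[deg > 0]
  tab <- table(deg)
  k <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  if (length(k) < 3)
    stopf("insufficient variation: need >= 3 distinct degree values, got %d",
          length(k))
  lx <- log10(k); ly <- log10(cnt)
  ct <- stats::cor.test(lx, ly)
  fit <- stats::lm(ly ~ lx)
  list(degrees = tab,
       r = unname(ct$estimate),
       p_value = ct$p.value,
       slope = unname(stats::coef(fit)[2]))
}
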