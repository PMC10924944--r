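## small shared helpers (internal)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Match predicted cluster labels to reference labels
#'
#' Greedily maps each predicted label to the reference label with which it
#' shares the most samples (majority vote in the confusion table).  Useful
#' for comparing cluster assignments, whose label identities are arbitrary,
#' with planted or reference subtypes.
#'
#' @param predicted vector of predicted labels.
#' @param reference vector of reference labels, same length.
#' @return vector of `predicted` recoded into reference label space.
#' @export
match_labels <- function(predicted, reference) {
  stopifnot(length(predicted) == length(reference))
  tab <- table(predicted, reference)
  map <- colnames(tab)[apply(tab, 1, which.max)]
  names(map) <- rownames(tab)
  unname(map[as.character(predicted)])
}

## matrix TSV with row-ID first column; stable, header always written
write_matrix_tsv <- function(mat, path, id_col = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

## row-wise SD without matrixStats
row_sds <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1))
}

## row-wise two-sided Wilcoxon rank-sum z statistic (normal approximation
## with tie correction); used where thousands of rows are tested and only
## the ordering by |statistic| matters
row_wilcox_z <- function(x, in_group) {
  n1 <- sum(in_group)
  n2 <- sum(!in_group)
  stopifnot(n1 > 0, n2 > 0)
  n <- n1 + n2
  apply(x, 1, function(v) {
    r <- rank(v)
    U <- sum(r[in_group]) - n1 * (n1 + 1) / 2
    ties <- table(v)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(0)
    (U - n1 * n2 / 2) / sqrt(sigma2)
  })
}
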