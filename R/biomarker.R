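## Subtype marker screen: per-gene ROC AUC for target-subtype prediction,
## univariate Cox filter, mean C-index ranking across cohorts, dichotomized
## KM validation, and IHC H-scores.

#' Multi-cohort marker screen for a target subtype
#'
#' For every candidate gene and cohort: ROC AUC of expression for
#' target-subtype-vs-rest, univariate Cox HR/p against overall survival,
#' and Harrell's C-index of expression as risk.  A gene passes the AUC
#' filter when AUC > `auc_min` in *all* cohorts, and the Cox filter when
#' p < `p_max` and HR > 1 in *all* cohorts; genes passing both are ranked
#' by mean C-index across cohorts.  Genes absent from any cohort fail with
#' a logged reason.
#'
#' @param cohorts list of cohorts, each a list with `expr` (genes x tumor
#'   samples), `labels` (subtype per sample) and `surv` (data.frame
#'   sample, time, event aligned to the expression columns by sample ID).
#' @param target_subtype the subtype whose markers are sought.
#' @param candidate_genes character vector of genes to screen; defaults to
#'   the target subtype's signature in `model`.
#' @param model optional `subtype_model` supplying the default candidates.
#' @param auc_min AUC threshold (default 0.9).
#' @param p_max Cox p threshold (default 0.05).
#' @return a `marker_screen`: list with `table` (per-gene results),
#'   `ranking` (double-pass genes by decreasing mean C-index), `winner`,
#'   `failed` (gene -> reason).
#' @export
screen_markers <- function(cohorts, target_subtype, candidate_genes = NULL,
                           model = NULL, auc_min = 0.9, p_max = 0.05) {
  if (length(cohorts) < 2) stopf("need >= 2 cohorts")
  if (is.null(candidate_genes)) {
    if (is.null(model)) stopf("supply candidate_genes or a subtype_model")
    candidate_genes <- model$signatures[[as.character(target_subtype)]]
    if (is.null(candidate_genes))
      stopf("model has no signature for subtype %s", target_subtype)
  }
  nm <- names(cohorts) %||% paste0("cohort", seq_along(cohorts))
  for (i in seq_along(cohorts)) {
    lab <- cohorts[[i]]$labels
    if (!any(as.character(lab) == as.character(target_subtype)))
      stopf("target subtype %s absent from cohort %s", target_subtype, nm[i])
  }
  failed <- character(0)
  rows <- list()
  for (g in candidate_genes) {
    absent <- nm[vapply(cohorts, function(co)
      !(g %in% rownames(co$expr)), logical(1))]
    if (length(absent)) {
      failed[g] <- sprintf("absent from cohort(s): %s",
                           paste(absent, collapse = ", "))
      next
    }
    per <- lapply(cohorts, function(co) {
      x <- co$expr[g, ]
      is_t <- as.character(co$labels) == as.character(target_subtype)
      auc <- roc_auc(is_t, x)
      idx <- match(co$surv$sample, colnames(co$expr))
      xs <- x[idx]
      cox <- cox_univariate(co$surv, xs)
      c(auc = auc, hr = cox$hr, p = cox$p, c_index = cox$c_index)
    })
    m <- do.call(rbind, per)
    rows[[g]] <- data.frame(
      gene = g,
      auc_min_cohort = min(m[, "auc"]),
      pass_auc = all(m[, "auc"] > auc_min),
      pass_cox = all(m[, "p"] < p_max & m[, "hr"] > 1),
      mean_c_index = mean(m[, "c_index"]),
      t(c(stats::setNames(m[, "auc"], paste0("auc_", nm)),
          stats::setNames(m[, "hr"], paste0("hr_", nm)),
          stats::setNames(m[, "p"], paste0("p_", nm)),
          stats::setNames(m[, "c_index"], paste0("c_", nm)))),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0))
  if (length(failed))
    message(sprintf("%d candidate gene(s) failed screening: %s",
                    length(failed),
                    paste(names(failed), collapse = ", ")))
  pass <- if (nrow(tab)) tab[tab$pass_auc & tab$pass_cox, ] else tab
  ranking <- if (nrow(pass)) pass$gene[order(-pass$mean_c_index)] else
    character(0)
  structure(list(table = tab, ranking = ranking,
                 winner = if (length(ranking)) ranking[1] else NA_character_,
                 failed = failed,
                 auc_min = auc_min, p_max = p_max,
                 target_subtype = target_subtype),
            class = "marker_screen")
}

#' @export
print.marker_screen <- function(x, ...) {
  cat(sprintf(
    "marker_screen: %d gene(s) screened, %d pass AUC>%g & Cox; winner: %s\n",
    nrow(x$table), length(x$ranking), x$auc_min,
    x$winner %||% "none"))
  invisible(x)
}

#' Dichotomized Kaplan-Meier validation of one gene
#'
#' Splits samples into high/low expression at the configured cutpoint
#' (default median) and compares survival by log-rank.
#'
#' @param expr_gene named numeric vector of the gene's expression (names =
#'   sample IDs).
#' @param surv data.frame: sample, time, event.
#' @param cutpoint `"median"` or a numeric quantile in (0, 1).
#' @return list: groups (high/low per survival row), logrank (chi2, df, p),
#'   km (from [km_curve()]).
#' @export
dichotomize_km <- function(expr_gene, surv, cutpoint = "median") {
  x <- expr_gene[surv$sample]
  if (any(is.na(x))) stopf("expression missing for some survival samples")
  qt <- if (identical(cutpoint, "median")) 0.5 else as.numeric(cutpoint)
  cut <- stats::quantile(x, qt)
  if (length(unique(x)) == 1) stopf("degenerate split: all values equal")
  groups <- ifelse(x > cut, "high", "low")
  if (min(table(groups)) < 4)
    stopf("fewer than 4 samples in a group after the split")
  list(groups = groups, logrank = logrank(surv, groups),
       km = km_curve(surv, groups))
}

#' IHC H-score
#'
#' Staining intensity (0 = none, 1 = weak, 2 = moderate, 3 = strong)
#' times the percentage of stained tumor cells, giving a score in
#' \[0, 300\].
#'
#' @param intensity integer(s) in {0, 1, 2, 3}.
#' @param proportion percent stained in \[0, 100\].
#' @return numeric H-score(s).
#' @export
h_score <- function(intensity, proportion) {
  if (!all(intensity %in% 0:3)) stopf("intensity must be in {0,1,2,3}")
  if (any(proportion < 0 | proportion > 100))
    stopf("proportion must be in [0, 100]")
  intensity * proportion
}

#' Group IHC records by H-score cutpoint
#'
#' @param records data.frame with columns intensity, proportion (and
#'   optionally specimen).
#' @param cutpoint `"median"` or a numeric H-score cutoff.
#' @return `records` with added h_score and group ("high"/"low") columns.
#' @export
h_score_group <- function(records, cutpoint = "median") {
  hs <- h_score(records$intensity, records$proportion)
  cut <- if (identical(cutpoint, "median")) stats::median(hs) else
    as.numeric(cutpoint)
  records$h_score <- hs
  records$group <- ifelse(hs > cut, "high", "low")
  records
}
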