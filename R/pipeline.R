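## Orchestration: configuration and the end-to-end synthetic demonstration.

#' Pipeline configuration
#'
#' Collects every stage parameter with the pipeline's standard defaults:
#' edge confidence > 0.8, top-6000 feature lists, 1000 consensus iterations
#' at subsample 0.8, K range 2-10, NTP FDR < 0.2, marker AUC > 0.9 and Cox
#' p < 0.05.  The synthetic demonstration scales `iters` down; all other
#' defaults are left at their standard values.
#'
#' @param sim a [sim_config()] for the synthetic inputs.
#' @param confidence_threshold edge confidence filter (default 0.8).
#' @param k_diff,k_sd feature top-list sizes (default 6000).
#' @param k_range consensus K values (default 2:10).
#' @param iters,subsample consensus iterations and resample rate
#'   (defaults 1000 and 0.8).
#' @param delta_threshold delta-area threshold for K selection (0.1).
#' @param ntp_fdr NTP classification FDR (default 0.2).
#' @param fdr_max,lfc_min,top_n signature derivation parameters.
#' @param auc_min,p_max marker screen thresholds (defaults 0.9, 0.05).
#' @param n_gene_sets,gene_set_size ssGSEA fixture sets (defaults 28, 20).
#' @param ssgsea_alpha rank-weight exponent (default 0.25).
#' @param n_validation_cohorts cohorts generated for NTP/screen (default 3).
#' @param seed master seed; per-stage seeds are derived by fixed offsets.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            confidence_threshold = 0.8,
                            k_diff = 6000, k_sd = 6000,
                            k_range = 2:10, iters = 1000, subsample = 0.8,
                            delta_threshold = 0.1,
                            ntp_fdr = 0.2,
                            fdr_max = 0.05, lfc_min = 0.2, top_n = 200,
                            auc_min = 0.9, p_max = 0.05,
                            n_gene_sets = 28, gene_set_size = 20,
                            ssgsea_alpha = 0.25,
                            n_validation_cohorts = 3,
                            seed = 1L) {
  if (length(k_range) < 2 || is.unsorted(k_range, strictly = TRUE))
    stopf("invalid k_range: need at least two strictly increasing K values")
  if (subsample <= 0 || subsample > 1) stopf("subsample must be in (0,1]")
  if (iters < 1) stopf("iters must be >= 1")
  cfg <- list(sim = sim, confidence_threshold = confidence_threshold,
              k_diff = k_diff, k_sd = k_sd, k_range = k_range,
              iters = iters, subsample = subsample,
              delta_threshold = delta_threshold, ntp_fdr = ntp_fdr,
              fdr_max = fdr_max, lfc_min = lfc_min, top_n = top_n,
              auc_min = auc_min, p_max = p_max,
              n_gene_sets = n_gene_sets, gene_set_size = gene_set_size,
              ssgsea_alpha = ssgsea_alpha,
              n_validation_cohorts = n_validation_cohorts,
              seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

## fixed per-stage seed offsets from the master seed (documented in the
## manifest)
stage_seed <- function(cfg, stage) {
  offsets <- c(simulate = 0L, cluster = 101L, classify = 202L,
               gene_sets = 303L, cohortB = 1000L, cohortC = 2000L,
               cohortD = 3000L)
  cfg$seed + offsets[[stage]]
}

#' Run the full synthetic end-to-end pipeline
#'
#' Executes, in order: simulate, build-net, perturb, select, cluster,
#' signatures, classify, score, survival, screen.  Every stage writes its
#' artifacts (TSV/GMT/JSON) under `outdir`, and a manifest records the
#' parameters and derived per-stage seeds; rerunning with the same config
#' produces bit-identical files.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return (invisibly) list of in-memory stage results; artifacts and
#'   `manifest.json` / `summary.md` under `outdir`.
#' @export
run_all <- function(config, outdir) {
  cfg <- config
  if (!inherits(cfg, "pipeline_config")) stopf("config must be a pipeline_config")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages_done <- character(0)
  res <- list()
  note <- function(stage) {
    stages_done <<- c(stages_done, stage)
    message(sprintf("[deathnet] stage %02d: %s", length(stages_done), stage))
  }

  ## 1 simulate --------------------------------------------------------
  sim <- cfg$sim
  sim$seed <- stage_seed(cfg, "simulate")
  network0 <- generate_network(sim$n_genes, sim$attach_m, sim$seed)
  cohortA <- simulate_cohort(sim, network = network0, cohort = "A",
                             sample_seed = sim$seed)
  ## 11 "pathways" partitioning the gene universe (union covers all genes)
  set.seed(stage_seed(cfg, "gene_sets"))
  pathway_sets <- split(sample(network0$nodes),
                        rep_len(sprintf("pathway%02d", 1:11),
                                length(network0$nodes)))
  write_matrix_tsv(round(cohortA$expr, 6), file.path(outdir, "expr_A.tsv"),
                   id_col = "gene")
  utils::write.table(cohortA$annotation, file.path(outdir, "annotation_A.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohortA$network$edges[c("gene_a", "gene_b", "confidence")],
                     file.path(outdir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohortA$survival, file.path(outdir, "survival_A.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(pathway_sets, file.path(outdir, "pathways.gmt"))
  jsonlite::write_json(
    list(marker_gene = cohortA$truth$marker_gene,
         worst_subtype = cohortA$truth$worst_subtype,
         sample_labels = as.list(cohortA$truth$sample_labels),
         perturbed_edges = cohortA$truth$perturbed_edges),
    file.path(outdir, "truth_A.json"), auto_unbox = TRUE, digits = NA)
  res$cohortA <- cohortA
  note("simulate")

  ## 2 build-net -------------------------------------------------------
  network <- build_network(pathway_sets,
                           cohortA$network$edges[c("gene_a", "gene_b",
                                                   "confidence")],
                           confidence_threshold = 0)
  fit <- scale_free_fit(network)
  jsonlite::write_json(list(nodes = length(network$nodes),
                            edges = nrow(network$edges),
                            degree_fit_r = fit$r, slope = fit$slope,
                            p_value = fit$p_value),
                       file.path(outdir, "network_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  res$network <- network; res$degree_fit <- fit
  note("build-net")

  ## 3 perturb ---------------------------------------------------------
  ip <- interaction_perturbation(cohortA$expr, cohortA$annotation$condition,
                                 network)
  write_matrix_tsv(ip$pmat, file.path(outdir, "perturbation_A.tsv"),
                   id_col = "edge")
  psum <- perturbation_summary(ip$pmat, cohortA$annotation$condition)
  jsonlite::write_json(list(condition_mean_abs = as.list(psum$condition_mean_abs),
                            wilcox_p = psum$wilcox_p),
                       file.path(outdir, "perturbation_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  res$perturbation <- ip; res$perturbation_summary <- psum
  note("perturb")

  ## 4 select ----------------------------------------------------------
  feat <- select_features(ip$pmat, cohortA$annotation$condition,
                          k_diff = min(cfg$k_diff, nrow(ip$pmat)),
                          k_sd = min(cfg$k_sd, nrow(ip$pmat)))
  writeLines(feat$selected_edges, file.path(outdir, "selected_edges.txt"))
  res$features <- feat
  note("select")

  ## 5 cluster ---------------------------------------------------------
  tumor <- cohortA$annotation$condition == "tumor"
  fmat <- ip$pmat[feat$selected_edges, tumor, drop = FALSE]
  cc <- consensus_cluster(fmat, k_range = cfg$k_range, iters = cfg$iters,
                          subsample = cfg$subsample,
                          seed = stage_seed(cfg, "cluster"),
                          delta_threshold = cfg$delta_threshold)
  k <- cc$recommended_k
  labels_A <- cc$labels[[as.character(k)]]
  utils::write.table(data.frame(sample = names(labels_A), subtype = labels_A),
                     file.path(outdir, "subtypes_A.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(areas = as.list(cc$areas),
                            deltas = as.list(cc$deltas),
                            recommended_k = k),
                       file.path(outdir, "consensus_selection.json"),
                       auto_unbox = TRUE, digits = NA)
  res$consensus <- cc; res$labels_A <- labels_A
  note("cluster")

  ## 6 signatures ------------------------------------------------------
  model <- derive_signatures(cohortA$expr[, tumor, drop = FALSE], labels_A,
                             fdr_max = cfg$fdr_max, lfc_min = cfg$lfc_min,
                             top_n = cfg$top_n)
  write_gmt(model$signatures, file.path(outdir, "signatures.gmt"))
  res$model <- model
  note("signatures")

  ## 7 classify (validation cohorts by NTP) ----------------------------
  val_names <- utils::head(c("B", "C", "D"), cfg$n_validation_cohorts)
  validation <- list()
  for (i in seq_along(val_names)) {
    nm <- val_names[i]
    co <- simulate_cohort(sim, network = network0, cohort = nm,
                          sample_seed = stage_seed(cfg, paste0("cohort", nm)))
    expr_t <- co$expr[, co$annotation$condition == "tumor", drop = FALSE]
    ntp <- ntp_classify(expr_t, model, n_perm = 1000,
                        fdr_threshold = cfg$ntp_fdr,
                        seed = stage_seed(cfg, "classify") + i)
    utils::write.table(ntp, file.path(outdir, sprintf("ntp_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    validation[[nm]] <- list(cohort = co, ntp = ntp, expr_tumor = expr_t)
  }
  res$validation <- validation
  note("classify")

  ## 8 score (ssGSEA + group comparison) -------------------------------
  imm_sets <- generate_gene_sets(network0$nodes, cfg$n_gene_sets,
                                 cfg$gene_set_size,
                                 seed = stage_seed(cfg, "gene_sets") + 1L)
  scores <- ssgsea(cohortA$expr[, tumor, drop = FALSE], imm_sets,
                   alpha = cfg$ssgsea_alpha)
  write_matrix_tsv(scores, file.path(outdir, "ssgsea_scores_A.tsv"),
                   id_col = "gene_set")
  cmp <- compare_groups(scores, labels_A, test = "kruskal")
  utils::write.table(cmp, file.path(outdir, "score_comparison_A.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res$scores <- scores; res$score_comparison <- cmp
  note("score")

  ## 9 survival --------------------------------------------------------
  surv_A <- load_survival(cohortA$survival)
  lab_surv <- labels_A[surv_A$sample]
  lr <- logrank(surv_A, lab_surv)
  km <- km_curve(surv_A, lab_surv)
  utils::write.table(km$curves, file.path(outdir, "km_subtypes_A.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(chi2 = lr$chi2, df = lr$df, p = lr$p,
                            median = as.list(km$median)),
                       file.path(outdir, "survival_A.json"),
                       auto_unbox = TRUE, digits = NA)
  res$survival_logrank <- lr; res$survival_km <- km
  note("survival")

  ## 10 screen ---------------------------------------------------------
  ## target = discovered subtype with the worst survival (highest event
  ## hazard proxy: lowest KM median, falling back to labels' mean time)
  target <- names(which.min(km$median))
  if (is.na(km$median[target]) || all(is.na(km$median))) {
    mt <- tapply(surv_A$time, lab_surv, mean)
    target <- names(which.min(mt))
  }
  cohorts <- lapply(validation, function(v) {
    keep <- v$ntp$classified
    list(expr = v$expr_tumor[, keep, drop = FALSE],
         labels = v$ntp$predicted[keep],
         surv = load_survival(
           v$cohort$survival[v$cohort$survival$sample %in%
                               v$ntp$sample[keep], , drop = FALSE]))
  })
  screen <- screen_markers(cohorts, target_subtype = target, model = model,
                           auc_min = cfg$auc_min, p_max = cfg$p_max)
  utils::write.table(screen$table, file.path(outdir, "marker_screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res$screen <- screen; res$target_subtype <- target
  note("screen")

  ## manifest + summary ------------------------------------------------
  manifest <- list(
    stages = stages_done,
    n_stages = length(stages_done),
    master_seed = cfg$seed,
    stage_seeds = list(simulate = stage_seed(cfg, "simulate"),
                       cluster = stage_seed(cfg, "cluster"),
                       classify = stage_seed(cfg, "classify"),
                       gene_sets = stage_seed(cfg, "gene_sets")),
    parameters = cfg[setdiff(names(cfg), "sim")],
    sim = unclass(cfg$sim))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  summary_lines <- c(
    "# deathnet synthetic run",
    "",
    sprintf("- network: %d nodes, %d edges (degree-fit r = %.3f)",
            length(network$nodes), nrow(network$edges), fit$r),
    sprintf("- features selected: %d edges", length(feat$selected_edges)),
    sprintf("- recommended K: %d (subtype sizes: %s)", k,
            paste(table(labels_A), collapse = "/")),
    sprintf("- survival split across subtypes: log-rank p = %.3g", lr$p),
    sprintf("- NTP classified fractions: %s",
            paste(vapply(validation, function(v)
              sprintf("%.0f%%", 100 * mean(v$ntp$classified)), ""),
              collapse = ", ")),
    sprintf("- marker screen winner: %s (planted marker: %s)",
            screen$winner, cohortA$truth$marker_gene))
  writeLines(summary_lines, file.path(outdir, "summary.md"))
  invisible(res)
}
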