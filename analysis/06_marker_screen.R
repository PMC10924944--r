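#!/usr/bin/env Rscript
# Step 6 — prognostic marker screen for the worst-prognosis subtype.
#
# Screens the worst subtype's signature genes across the three NTP-
# classified validation cohorts: target-vs-rest ROC AUC > 0.9 in every
# cohort, univariate Cox p < 0.05 with HR > 1 in every cohort, ranking by
# mean Harrell's C-index.  The winner is validated by a pooled
# median-split Kaplan-Meier comparison, and an IHC-style H-score grouping
# is demonstrated on simulated staining records.

library(deathnet)

dat <- "results/data"
sub <- read.delim("results/subtypes_A.tsv")
lab <- setNames(sub$subtype, sub$sample)
survA <- load_survival(file.path(dat, "survival_A.tsv"))
km <- km_curve(survA, lab[survA$sample])
target <- names(which.min(km$median))
cat(sprintf("target (worst-prognosis) subtype: %s\n", target))

expr_df <- read.delim(file.path(dat, "expr_A.tsv"), check.names = FALSE)
expr <- as.matrix(expr_df[, -1]); rownames(expr) <- expr_df$gene
ann <- read.delim(file.path(dat, "annotation_A.tsv"))
model <- derive_signatures(expr[, ann$condition == "tumor"], lab)

cohorts <- lapply(c(B = "B", C = "C", D = "D"), function(nm) {
  e_df <- read.delim(sprintf("results/data/expr_tumor_%s.tsv", nm),
                     check.names = FALSE)
  e <- as.matrix(e_df[, -1]); rownames(e) <- e_df$gene
  ntp <- read.delim(sprintf("results/ntp_%s.tsv", nm))
  keep <- ntp$classified
  surv <- load_survival(sprintf("results/data/survival_%s.tsv", nm))
  list(expr = e[, ntp$sample[keep], drop = FALSE],
       labels = as.character(ntp$predicted[keep]),
       surv = surv[surv$sample %in% ntp$sample[keep], , drop = FALSE])
})

scr <- screen_markers(cohorts, target, model = model)
cat(sprintf("%d candidate gene(s); %d pass AUC > 0.9 and Cox in all cohorts\n",
            nrow(scr$table), length(scr$ranking)))
cat(sprintf("winner by mean C-index: %s\n", scr$winner))
truth <- jsonlite::read_json(file.path(dat, "truth_A.json"))
cat(sprintf("planted marker: %s (recovered: %s)\n", truth$marker_gene,
            identical(scr$winner, truth$marker_gene)))
write.table(scr$table, "results/marker_screen.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

surv_pool <- do.call(rbind, lapply(cohorts, `[[`, "surv"))
x_pool <- unlist(lapply(cohorts, function(co) co$expr[scr$winner, ]))
names(x_pool) <- unlist(lapply(cohorts, function(co) colnames(co$expr)))
dk <- dichotomize_km(x_pool, surv_pool)
cat(sprintf(
  "pooled median split of %s: log-rank p = %.2g (high median %.0f vs low %.0f days)\n",
  scr$winner, dk$logrank$p, dk$km$median[["high"]], dk$km$median[["low"]]))

# IHC-style validation on simulated staining records linked to expression
set.seed(99)
n_ihc <- 103
grp_expr <- x_pool[sample(names(x_pool), n_ihc)]
intensity <- pmin(3, pmax(0, round((grp_expr - min(grp_expr)) /
                                     diff(range(grp_expr)) * 3 +
                                     rnorm(n_ihc, 0, 0.5))))
prop <- pmin(100, pmax(0, round(30 + 15 * intensity + rnorm(n_ihc, 0, 10))))
ihc <- h_score_group(data.frame(specimen = names(grp_expr),
                                intensity = intensity, proportion = prop))
lr_ihc <- logrank(surv_pool[match(ihc$specimen, surv_pool$sample), ],
                  ihc$group)
cat(sprintf("H-score high/low split (n = %d): log-rank p = %.2g\n",
            n_ihc, lr_ihc$p))
write.table(ihc, "results/ihc_h_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
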