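#!/usr/bin/env Rscript
# Step 1 — simulate the study inputs.
#
# Builds a scale-free background interaction network and a discovery
# cohort (normal + tumor expression, subtype-linked survival) with four
# planted tumor subtypes and one planted marker gene, then writes every
# input the downstream steps need under results/data/.

library(deathnet)

SEED <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = SEED)
net <- generate_network(cfg$n_genes, cfg$attach_m, cfg$seed)
A <- simulate_cohort(cfg, network = net, cohort = "A", sample_seed = SEED)

write.table(net$edges[c("gene_a", "gene_b", "confidence")],
            file.path(out, "edges.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
expr_df <- data.frame(gene = rownames(A$expr), A$expr, check.names = FALSE)
write.table(expr_df, file.path(out, "expr_A.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(A$annotation, file.path(out, "annotation_A.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(A$survival, file.path(out, "survival_A.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
# pathway sets: an 11-way partition of the gene universe
set.seed(SEED + 303L)
pathways <- split(sample(net$nodes),
                  rep_len(sprintf("pathway%02d", 1:11), length(net$nodes)))
write_gmt(pathways, file.path(out, "pathways.gmt"))
jsonlite::write_json(
  list(seed = SEED, marker_gene = A$truth$marker_gene,
       worst_subtype = A$truth$worst_subtype,
       sample_labels = as.list(A$truth$sample_labels)),
  file.path(out, "truth_A.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("network: %d nodes, %d edges\n",
            length(net$nodes), nrow(net$edges)))
cat(sprintf("cohort A: %d normal + %d tumor samples, %d subtypes\n",
            cfg$n_normal, cfg$n_tumor, cfg$n_subtypes))
cat(sprintf("planted marker: %s (up in subtype %d, the worst hazard)\n",
            A$truth$marker_gene, A$truth$worst_subtype))
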