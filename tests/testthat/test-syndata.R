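# Synthetic-data generator: network construction, planted perturbation,
# survival and gene-set fixtures.

test_that("preferential attachment yields the forced edge count and a tree at m=1", {
  net1 <- generate_network(10, attach_m = 1, seed = 7)
  expect_equal(nrow(net1$edges), 9)          # n-1 edges: a tree
  g <- igraph::graph_from_data_frame(net1$edges[1:2], directed = FALSE)
  expect_true(igraph::is_connected(g))
  expect_equal(igraph::count_components(g), 1)

  net2 <- generate_network(500, attach_m = 2, seed = 1)
  expect_equal(nrow(net2$edges), (500 - 2) * 2)   # (n - m) * m
  g2 <- igraph::graph_from_data_frame(net2$edges[1:2], directed = FALSE,
                                      vertices = net2$nodes)
  expect_true(igraph::is_connected(g2))
  expect_true(all(net2$edges$confidence == 1))
  expect_error(generate_network(3, attach_m = 5), "attach_m")
})

test_that("generators are bit-reproducible given the seed", {
  cfg <- sim_config(n_genes = 60, n_normal = 8, n_tumor = 20, seed = 3)
  net <- generate_network(60, 2, 3)
  a <- generate_expression(net, cfg)
  b <- generate_expression(net, cfg)
  expect_identical(a$expr, b$expr)
  expect_identical(a$truth$marker_gene, b$truth$marker_gene)
  sa <- generate_survival(a$truth$sample_labels, cfg)
  sb <- generate_survival(a$truth$sample_labels, cfg)
  expect_identical(sa, sb)
  gs1 <- generate_gene_sets(net$nodes, 3, 10, seed = 9)
  gs2 <- generate_gene_sets(net$nodes, 3, 10, seed = 9)
  expect_identical(gs1, gs2)
})

test_that("no noise and no effective perturbation gives a zero perturbation matrix", {
  cfg <- sim_config(n_genes = 50, n_normal = 5, n_tumor = 12, noise_sd = 0,
                    frac_edges_perturbed_per_subtype = 0.02,
                    perturb_strength = 1e-9, marker_gene_effect = 1e-9,
                    seed = 2)
  net <- generate_network(50, 2, 2)
  ex <- generate_expression(net, cfg)
  ip <- interaction_perturbation(ex$expr, ex$annotation$condition, net)
  expect_true(all(abs(ip$pmat) < 1e-6))
})

test_that("a planted edge perturbation is strongest in its owning subtype", {
  cfg <- sim_config(n_genes = 80, n_normal = 10, n_tumor = 40, noise_sd = 0,
                    frac_edges_perturbed_per_subtype = 0.05,
                    perturb_strength = 4, seed = 5)
  net <- generate_network(80, 2, 5)
  ex <- generate_expression(net, cfg)
  ip <- interaction_perturbation(ex$expr, ex$annotation$condition, net)
  labels <- ex$truth$sample_labels
  tumor_cols <- names(labels)
  shifted <- rownames(ex$truth$shift_by_subtype)[
    ex$truth$shift_by_subtype[, 1] != 0]
  e1 <- intersect(ex$truth$perturbed_edges[[1]], rownames(ip$pmat))
  e1 <- e1[vapply(strsplit(e1, "\\|"), function(ab)
    any(ab %in% shifted), logical(1))]
  own <- abs(ip$pmat[e1, tumor_cols[labels == 1], drop = FALSE])
  other <- abs(ip$pmat[e1, tumor_cols[labels != 1], drop = FALSE])
  expect_gt(mean(own), mean(other))
})

test_that("perturbation magnitude grows (weakly) with perturb_strength", {
  means <- vapply(c(1, 2.5, 4), function(st) {
    cfg <- sim_config(n_genes = 80, n_normal = 10, n_tumor = 40,
                      noise_sd = 0.3, perturb_strength = st, seed = 8)
    net <- generate_network(80, 2, 8)
    ex <- generate_expression(net, cfg)
    ip <- interaction_perturbation(ex$expr, ex$annotation$condition, net)
    labels <- ex$truth$sample_labels
    m <- 0; cnt <- 0
    for (s in seq_len(cfg$n_subtypes)) {
      es <- intersect(ex$truth$perturbed_edges[[s]], rownames(ip$pmat))
      cols <- names(labels)[labels == s]
      m <- m + sum(abs(ip$pmat[es, cols])); cnt <- cnt + length(es) * length(cols)
    }
    m / cnt
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("survival generator respects hazards, censoring and the 30-day floor", {
  cfg0 <- sim_config(n_subtypes = 2, subtype_hazards = c(1, 1),
                     censor_rate = 0, n_tumor = 100, seed = 4)
  labs <- setNames(rep(1:2, each = 150), paste0("T", 1:300))
  s0 <- generate_survival(labs, cfg0)
  expect_true(all(s0$event == 1))              # censor_rate 0
  expect_true(all(s0$time > 30))
  lr0 <- logrank(s0, labs)
  expect_gt(lr0$p, 0.001)                      # null sanity bound

  cfg1 <- sim_config(subtype_hazards = c(1, 1, 1, 4), seed = 4)
  labs4 <- setNames(rep(1:4, each = 100), paste0("T", 1:400))
  s1 <- generate_survival(labs4, cfg1)
  lr1 <- logrank(s1, labs4)
  expect_lt(lr1$p, 0.01)
  km <- km_curve(s1, labs4)
  expect_equal(names(which.min(km$median)), "4")  # worst subtype lowest curve
  expect_error(sim_config(censor_rate = 1), "censor_rate")
})

test_that("gene-set generator covers the universe and stays disjoint when possible", {
  genes <- sprintf("G%03d", 1:40)
  one <- generate_gene_sets(genes, 1, 40, seed = 1)
  expect_setequal(one[[1]], genes)
  many <- generate_gene_sets(genes, 4, 10, seed = 1)
  expect_equal(length(unique(unlist(many))), 40)  # disjoint partition
  expect_error(generate_gene_sets(genes, 1, 50), "set_size")
})
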