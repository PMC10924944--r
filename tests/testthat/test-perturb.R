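# Rank / delta-rank / benchmark / perturbation statistics.

toy_network <- function(edges_df) {
  build_network(list(all = unique(unlist(edges_df[, 1:2]))),
                cbind(edges_df, confidence = 1), confidence_threshold = 0)
}

test_that("within-sample ranks are ascending with average ties", {
  expr <- cbind(s1 = c(g1 = 1, g2 = 2, g3 = 3), s2 = c(2, 2, 5))
  r <- rank_matrix(expr)
  expect_equal(unname(r[, "s1"]), c(1, 2, 3))
  expect_equal(unname(r[, "s2"]), c(1.5, 1.5, 3))
  set.seed(21)
  m <- matrix(sample(1:8, 100, TRUE), 20, 5,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:5)))
  expect_equal(rank_matrix(m), oracle_rank_matrix(m))
})

test_that("delta ranks subtract in the fixed edge direction and antisymmetrize", {
  edges <- data.frame(gene_a = c("A", "A", "B", "C", "D"),
                      gene_b = c("B", "C", "D", "E", "E"))
  net <- toy_network(edges)
  expr <- matrix(c(1, 3, 2, 5, 4), 5, 1,
                 dimnames = list(c("A", "B", "C", "D", "E"), "s1"))
  d <- delta_rank(rank_matrix(expr), net)
  # hand-computed: ranks A1 B3 C2 D5 E4
  expect_equal(d[, 1], c("A|B" = -2, "A|C" = -1, "B|D" = -2,
                         "C|E" = -2, "D|E" = 1))
  # reversal negates
  r <- rank_matrix(expr)
  expect_equal(unname(r["D", 1] - r["B", 1]), 2)
  expect_equal(unname(r["B", 1] - r["D", 1]), -2)
})

test_that("benchmark is the average normal delta rank per edge", {
  edges <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"))
  net <- toy_network(edges)
  # single normal sample: benchmark equals its delta-rank column
  e1 <- matrix(c(3, 1, 2), 3, 1, dimnames = list(c("A", "B", "C"), "n1"))
  b1 <- benchmark_delta_rank(e1, net)
  expect_equal(unname(b1), unname(delta_rank(rank_matrix(e1), net)[, 1]))
  # normals sharing one ordering (different values): benchmark equals the
  # shared delta-rank column
  e_same <- cbind(n1 = c(A = 5, B = 1, C = 3), n2 = c(9, 2, 4))
  expect_equal(unname(benchmark_delta_rank(e_same, net)),
               unname(delta_rank(rank_matrix(e_same), net)[, 1]))
  # three unequal normals: oracle rank -> delta -> average chain
  set.seed(3)
  e3 <- matrix(rnorm(9), 3, 3, dimnames = list(c("A", "B", "C"), NULL))
  b3 <- benchmark_delta_rank(e3, net)
  r3 <- oracle_rank_matrix(e3)
  expect_equal(unname(b3),
               c(mean(r3["A", ] - r3["B", ]), mean(r3["B", ] - r3["C", ])))
})

test_that("perturbation equals delta minus benchmark, with alignment checks", {
  edges <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"))
  net <- toy_network(edges)
  set.seed(4)
  expr <- matrix(rnorm(12), 3, 4, dimnames = list(c("A", "B", "C"),
                                                  paste0("s", 1:4)))
  d <- delta_rank(rank_matrix(expr), net)
  b <- benchmark_delta_rank(expr[, 1:2], net)
  p <- perturbation_matrix(d, b)
  expect_equal(p, d - b)
  expect_equal(perturbation_matrix(d, setNames(numeric(2), names(b))), d)
  bad <- b; names(bad) <- rev(names(bad))
  expect_error(perturbation_matrix(d, bad), "aligned")
})

test_that("ranks (and perturbations) are invariant to monotone per-sample transforms", {
  set.seed(5)
  net <- generate_network(30, 2, 5)
  expr <- matrix(rexp(30 * 8), 30, 8,
                 dimnames = list(net$nodes, paste0("s", 1:8)))
  cond <- rep(c("normal", "tumor"), each = 4)
  p1 <- interaction_perturbation(expr, cond, net)$pmat
  p2 <- interaction_perturbation(log1p(expr), cond, net)$pmat
  p3 <- interaction_perturbation(expr^3, cond, net)$pmat
  expect_equal(p1, p2)
  expect_equal(p1, p3)
  # bound: |p| <= 2(G-1)
  expect_lte(max(abs(p1)), 2 * (nrow(expr) - 1))
})

test_that("missing network genes drop the affected edges cohort-wide", {
  net <- generate_network(20, 1, 9)
  expr <- matrix(rnorm(19 * 6), 19, 6,
                 dimnames = list(net$nodes[-1], paste0("s", 1:6)))
  cond <- rep(c("normal", "tumor"), each = 3)
  expect_message(ip <- interaction_perturbation(expr, cond, net), "dropping")
  gone <- net$edges$edge_id[net$edges$gene_a == net$nodes[1] |
                              net$edges$gene_b == net$nodes[1]]
  expect_false(any(gone %in% rownames(ip$pmat)))
  expect_error(rank_matrix(expr, net), "lacks")
})

test_that("tumors show stronger perturbation than normals in planted data", {
  cfg <- sim_config(n_genes = 100, n_normal = 15, n_tumor = 40, seed = 6)
  net <- generate_network(100, 2, 6)
  ex <- generate_expression(net, cfg)
  ip <- interaction_perturbation(ex$expr, ex$annotation$condition, net)
  ps <- perturbation_summary(ip$pmat, ex$annotation$condition)
  expect_gt(ps$condition_mean_abs["tumor"], ps$condition_mean_abs["normal"])
  expect_lt(ps$wilcox_p, 0.01)
  # identical groups: difference test p ~ 1
  same <- cbind(ip$pmat[, 1:5], ip$pmat[, 1:5])
  ps2 <- perturbation_summary(same, rep(c("normal", "tumor"), each = 5))
  expect_gte(ps2$wilcox_p, 0.99)
  # all-zero matrix: all summaries zero
  z <- matrix(0, 4, 6, dimnames = list(paste0("e", 1:4), paste0("s", 1:6)))
  ps3 <- perturbation_summary(z, rep(c("normal", "tumor"), each = 3))
  expect_true(all(ps3$sample_mean_abs == 0))
  expect_true(all(unlist(ps3$edge_variance) == 0))
})
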