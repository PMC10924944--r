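# Feature selection and consensus clustering.

test_that("feature selection intersects the differential and SD top lists", {
  # two edges: one strongly differential AND high-SD, one neither
  pm <- rbind(e1 = c(0, 0, 0, 10, 12, 14, 8, 20),
              e2 = c(1, 1, 1, 1.01, 1.02, 1.0, 1.01, 1.0))
  colnames(pm) <- paste0("s", 1:8)
  cond <- rep(c("normal", "tumor"), each = 4)
  sel <- select_features(pm, cond, k_diff = 1, k_sd = 1)
  expect_equal(sel$selected_edges, "e1")
  expect_warning(sel_all <- select_features(pm, cond, 50, 50), "clamp")
  expect_setequal(sel_all$selected_edges, c("e1", "e2"))
})

test_that("selection matches independently recomputed top-k lists", {
  set.seed(12)
  pm <- matrix(rnorm(200 * 30), 200, 30,
               dimnames = list(paste0("e", 1:200), paste0("s", 1:30)))
  cond <- rep(c("normal", "tumor"), c(10, 20))
  pm[1:40, cond == "tumor"] <- pm[1:40, cond == "tumor"] +
    rep(runif(40, 0, 3), 20)
  sel <- select_features(pm, cond, k_diff = 60, k_sd = 80)
  # oracle: rank by |U - n1 n2 / 2| from wilcox.test, and by sd()
  u0 <- apply(pm, 1, function(v)
    abs(stats::wilcox.test(v[cond == "tumor"],
                           v[cond == "normal"])$statistic - 10 * 20 / 2))
  top_diff <- names(sort(u0, decreasing = TRUE))[1:60]
  sds <- apply(pm[, cond == "tumor"], 1, sd)
  top_sd <- names(sort(sds, decreasing = TRUE))[1:80]
  expect_setequal(sel$selected_edges, intersect(top_diff, top_sd))
})

test_that("consensus clustering separates planted groups and is reproducible", {
  m <- make_two_block_matrix(n_per = 12, n_feat = 40, gap = 6, seed = 2)
  cc1 <- consensus_cluster(m, k_range = 2:4, iters = 60, seed = 7)
  cc2 <- consensus_cluster(m, k_range = 2:4, iters = 60, seed = 7)
  expect_identical(cc1$consensus, cc2$consensus)
  lab <- cc1$labels[["2"]]
  truth <- rep(1:2, each = 12)
  expect_equal(ari(lab, truth), 1)
  M2 <- cc1$consensus[["2"]]
  within <- M2[1:12, 1:12][upper.tri(M2[1:12, 1:12])]
  between <- M2[1:12, 13:24]
  expect_gte(min(within), 0.9)
  expect_lte(max(between), 0.1)
  # CDF at 1 is 1 for every K
  expect_true(all(vapply(cc1$cdf, function(f) f(1), numeric(1)) == 1))
  # consensus matrices are symmetric with unit diagonal
  expect_true(all(vapply(cc1$consensus, function(M)
    isTRUE(all.equal(M, t(M))) && all(diag(M) == 1), logical(1))))
})

test_that("duplicated samples always co-cluster with consensus 1", {
  m <- make_two_block_matrix(n_per = 6, n_feat = 30, gap = 6, seed = 3)
  m2 <- cbind(m, m)
  colnames(m2) <- paste0("s", seq_len(ncol(m2)))
  cc <- consensus_cluster(m2, k_range = 2:3, iters = 50, seed = 1)
  M <- cc$consensus[["2"]]
  dup_pairs <- cbind(seq_len(ncol(m)), seq_len(ncol(m)) + ncol(m))
  expect_true(all(M[dup_pairs] == 1))
})

test_that("subsample = 1 with deterministic PAM gives a binary consensus", {
  m <- make_two_block_matrix(n_per = 8, n_feat = 30, gap = 5, seed = 4)
  cc <- consensus_cluster(m, k_range = 2:3, iters = 20, subsample = 1,
                          seed = 5)
  vals <- unique(as.vector(cc$consensus[["2"]]))
  expect_true(all(vals %in% c(0, 1)))
})

test_that("constant sample columns are rejected (undefined Spearman)", {
  m <- make_two_block_matrix(n_per = 6, n_feat = 20, gap = 5, seed = 5)
  m[, 3] <- 2
  expect_error(consensus_cluster(m, k_range = 2:3, iters = 10, seed = 1),
               "constant|Spearman")
})

test_that("delta-area rule: base case and hand-built step-CDF areas", {
  # all gains below threshold after K=2 -> recommended K = 2
  mk_M <- function(vals, n = 8) {
    M <- matrix(0, n, n); M[upper.tri(M)] <- vals
    M <- M + t(M); diag(M) <- 1; M
  }
  npairs <- choose(8, 2)
  # point mass at v -> step CDF, area under CDF on [0,1] is 1 - v
  # K=2: all consensus 0.5 -> area 0.5; K=3: all 0.48 -> area 0.52,
  # relative gain 0.04 < 0.1 -> recommended K = 2
  sel <- cdf_delta_area(list("2" = mk_M(rep(0.5, npairs)),
                             "3" = mk_M(rep(0.48, npairs))))
  expect_equal(unname(sel$areas), c(0.5, 0.52))
  expect_equal(unname(sel$deltas[2]), 0.04)
  expect_equal(sel$recommended_k, 2)
  # half the mass at 0.2, half at 1.0: area = 0.8 * 0.5 = 0.4 (step CDF)
  vals <- rep(c(0.2, 1), length.out = npairs)
  a <- cdf_delta_area(list("2" = mk_M(vals), "3" = mk_M(vals)))
  expect_equal(unname(a$areas[1]), 0.4, tolerance = 1e-12)
  # last K with relative gain >= 0.1 is selected
  sel2 <- cdf_delta_area(list("2" = mk_M(rep(0.60, npairs)),
                              "3" = mk_M(rep(0.55, npairs)),
                              "4" = mk_M(rep(0.40, npairs)),
                              "5" = mk_M(rep(0.39, npairs))))
  expect_equal(unname(sel2$areas), c(0.4, 0.45, 0.6, 0.61))
  expect_equal(sel2$recommended_k, 4)
})

test_that("consensus matrices are invariant to sample permutation", {
  m <- make_two_block_matrix(n_per = 7, n_feat = 24, gap = 5, seed = 6)
  perm <- sample(ncol(m))
  cc1 <- consensus_cluster(m, k_range = 2:3, iters = 10, subsample = 1,
                           seed = 9)
  cc2 <- consensus_cluster(m[, perm], k_range = 2:3, iters = 10,
                           subsample = 1, seed = 9)
  M1 <- cc1$consensus[["2"]][perm, perm]
  M2 <- cc2$consensus[["2"]]
  expect_equal(unname(M1), unname(M2))
})
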