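# Independent brute-force oracles used to check the package's
# implementations.  These deliberately avoid the code paths they verify.

# within-sample ranks with average ties, by explicit counting
oracle_rank_vec <- function(v) {
  vapply(v, function(x) sum(v < x) + (sum(v == x) + 1) / 2, numeric(1))
}

oracle_rank_matrix <- function(expr) {
  out <- apply(expr, 2, oracle_rank_vec)
  rownames(out) <- rownames(expr)
  out
}

# full perturbation chain: rank -> delta -> average-over-normals ->
# subtract, by explicit loops
oracle_perturbation <- function(expr, normal_cols, edges) {
  r <- oracle_rank_matrix(expr)
  p <- matrix(NA_real_, nrow(edges), ncol(expr),
              dimnames = list(paste(edges$gene_a, edges$gene_b, sep = "|"),
                              colnames(expr)))
  for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    deltas <- numeric(ncol(expr))
    for (j in seq_len(ncol(expr))) deltas[j] <- r[a, j] - r[b, j]
    bench <- mean(deltas[normal_cols])
    p[i, ] <- deltas - bench
  }
  p
}

# Kaplan-Meier product-limit estimator by explicit risk-set loop
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out$surv[i] <- s
  }
  out
}

# two-group log-rank chi-square by explicit O-E tabulation
oracle_logrank2 <- function(time, event, group) {
  g <- unique(group)
  stopifnot(length(g) == 2)
  ts <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g[1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (O1 - E1)^2 / V
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

# Cox log partial likelihood (no tied event times) and grid maximizer
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

oracle_cox_grid <- function(time, event, x, grid = seq(-4, 4, by = 5e-4)) {
  ll <- vapply(grid, oracle_cox_loglik, numeric(1),
               time = time, event = event, x = x)
  grid[which.max(ll)]
}

# Harrell's C by exhaustive pair enumeration
oracle_c_index <- function(time, event, risk) {
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}

# AUC by exhaustive positive/negative pair counting
oracle_auc <- function(label, score) {
  pos <- score[as.logical(label)]
  neg <- score[!as.logical(label)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# ssGSEA running sum for one sample, by explicit walk over positions
oracle_ssgsea_one <- function(v, set, alpha) {
  G <- length(v)
  r <- rank(v, ties.method = "average")
  ord <- order(r, decreasing = TRUE)
  genes <- names(v)[ord]
  w <- unname(r[ord])^alpha
  in_set <- genes %in% set
  denom_in <- sum(w[in_set])
  denom_out <- G - sum(in_set)
  run_in <- run_out <- 0
  es <- 0
  for (k in seq_len(G)) {
    if (in_set[k]) run_in <- run_in + w[k] / denom_in
    else run_out <- run_out + 1 / denom_out
    es <- es + (run_in - run_out)
  }
  es
}

# small separated two-group feature matrix for clustering checks
make_two_block_matrix <- function(n_per = 10, n_feat = 40, gap = 5,
                                  seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_feat * 2 * n_per), n_feat)
  m[1:(n_feat / 2), 1:n_per] <- m[1:(n_feat / 2), 1:n_per] + gap
  m[(n_feat / 2 + 1):n_feat, (n_per + 1):(2 * n_per)] <-
    m[(n_feat / 2 + 1):n_feat, (n_per + 1):(2 * n_per)] + gap
  colnames(m) <- paste0("s", seq_len(2 * n_per))
  rownames(m) <- paste0("f", seq_len(n_feat))
  m
}

# adjusted Rand index (prefers mclust when available)
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab)); si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab))); n <- comb2(sum(tab))
  (sij - si * sj / n) / ((si + sj) / 2 - si * sj / n)
}
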