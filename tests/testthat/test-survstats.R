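# Survival statistics: KM, log-rank, Cox, C-index, AUC.

test_that("the >30-day inclusion filter drops short-survival records", {
  surv <- data.frame(sample = paste0("s", 1:5),
                     time = c(10, 30, 31, 100, 400),
                     event = c(1, 0, 1, 1, 0))
  expect_message(kept <- load_survival(surv), "2 record")
  expect_equal(kept$sample, c("s3", "s4", "s5"))
  expect_error(load_survival(data.frame(sample = 1, time = 50, event = 2)),
               "event")
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  # times 1,2,3 all events: S = 2/3, 1/3, 0
  s <- data.frame(sample = 1:3, time = 1:3, event = 1)
  km <- km_curve(s)
  expect_equal(km$curves$surv, c(2 / 3, 1 / 3, 0))
  # no events: curve constant at 1 (survfit reports no drops)
  s0 <- data.frame(sample = 1:4, time = c(2, 4, 6, 8), event = 0)
  km0 <- km_curve(s0)
  expect_true(all(km0$curves$surv == 1) || nrow(km0$curves) == 0)
  # 10 mixed censored records vs oracle
  set.seed(13)
  s10 <- data.frame(sample = 1:10, time = sample(1:20, 10),
                    event = rbinom(10, 1, 0.7))
  km10 <- km_curve(s10)
  orc <- oracle_km(s10$time, s10$event)
  got <- km10$curves[km10$curves$n_event > 0, ]
  expect_equal(got$surv, orc$surv[match(got$time, orc$time)])
})

test_that("log-rank matches hand O-E tabulation and degenerate cases", {
  # duplicated groups: chi2 = 0, p = 1
  s <- data.frame(sample = 1:8, time = rep(c(5, 9, 14, 20), 2),
                  event = rep(c(1, 1, 0, 1), 2))
  lr <- logrank(s, rep(c("a", "b"), each = 4))
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  # small 2-group dataset vs explicit risk-set oracle
  set.seed(14)
  s2 <- data.frame(sample = 1:12, time = sample(1:40, 12),
                   event = rbinom(12, 1, 0.8))
  g <- rep(c("a", "b"), 6)
  lr2 <- logrank(s2, g)
  orc <- oracle_logrank2(s2$time, s2$event, g)
  expect_equal(lr2$chi2, orc$chi2, tolerance = 1e-8)
  expect_equal(lr2$p, orc$p, tolerance = 1e-8)
  # all censored: warning and p = 1
  sc <- data.frame(sample = 1:6, time = 40:45, event = 0)
  expect_warning(lr3 <- logrank(sc, rep(c("a", "b"), 3)), "censored")
  expect_equal(lr3$p, 1)
  # chi2 is invariant to group relabeling
  relab <- c(a = "x", b = "y")[g]
  expect_equal(logrank(s2, relab)$chi2, lr2$chi2)
})

test_that("Cox beta matches grid maximization of the partial likelihood", {
  x <- c(0.4, -1.0, 1.2, 0.2, -0.6, 1.5)
  t6 <- c(6, 11, 3, 8, 2, 10)      # no ties, no perfect separation
  e6 <- c(1, 1, 1, 0, 1, 1)
  s6 <- data.frame(sample = 1:6, time = t6, event = e6)
  fit <- cox_univariate(s6, x)
  beta_grid <- oracle_cox_grid(t6, e6, x)
  expect_equal(fit$beta, beta_grid, tolerance = 1e-3)
  expect_equal(fit$hr, exp(fit$beta))
  # doubling the covariate scale halves beta
  fit2 <- cox_univariate(s6, 2 * x)
  expect_equal(fit2$beta, fit$beta / 2, tolerance = 1e-6)
  # independence null: permuted covariate, one seeded draw
  set.seed(16)
  n <- 500
  tt <- rexp(n); ee <- rbinom(n, 1, 0.8)
  sN <- data.frame(sample = 1:n, time = tt, event = ee)
  fitN <- cox_univariate(sN, rnorm(n))
  expect_lt(abs(fitN$beta), 0.3)
  expect_gt(fitN$p, 0.01)
})

test_that("C-index equals exhaustive pair enumeration", {
  s <- data.frame(sample = 1:6, time = c(3, 7, 1, 9, 4, 6),
                  event = c(1, 1, 1, 1, 1, 1))
  expect_equal(c_index(s, -s$time), 1)
  expect_equal(c_index(s, s$time), 0)
  set.seed(17)
  s8 <- data.frame(sample = 1:8, time = sample(1:30, 8),
                   event = rbinom(8, 1, 0.6))
  risk <- c(1, 2, 2, 5, 3, 3, 0, 4)   # includes risk ties
  expect_equal(c_index(s8, risk), oracle_c_index(s8$time, s8$event, risk))
  # agreement with the survival package's concordance
  cs <- survival::concordance(survival::Surv(time, event) ~ risk,
                              data = cbind(s8, risk), reverse = TRUE)
  expect_equal(c_index(s8, risk), unname(cs$concordance))
  expect_error(c_index(data.frame(time = c(5, 5), event = c(0, 0)), 1:2),
               "comparable")
})

test_that("AUC equals the U-statistic pair count and handles ties", {
  y <- c(1, 1, 1, 0, 0, 0)
  expect_equal(roc_auc(y, c(10, 9, 8, 3, 2, 1)), 1)
  expect_equal(roc_auc(y, rep(4, 6)), 0.5)
  set.seed(18)
  y10 <- rbinom(10, 1, 0.5); y10[1] <- 1; y10[2] <- 0
  sc <- sample(1:5, 10, TRUE)
  expect_equal(roc_auc(y10, sc), oracle_auc(y10, sc))
  if (requireNamespace("pROC", quietly = TRUE))
    expect_equal(roc_auc(y10, sc),
                 as.numeric(pROC::auc(pROC::roc(y10, sc, quiet = TRUE,
                                                direction = "<"))))
  expect_error(roc_auc(rep(1, 4), 1:4), "classes")
})

test_that("HR > 1 coincides with C-index > 0.5 on tie-free draws", {
  set.seed(19)
  for (i in 1:5) {
    n <- 80
    x <- rnorm(n)
    tt <- rexp(n, exp(0.7 * x * sample(c(-1, 1), 1)))
    s <- data.frame(sample = 1:n, time = tt, event = 1)
    fit <- cox_univariate(s, x)
    expect_equal(fit$hr > 1, c_index(s, x) > 0.5)
  }
})
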