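test_that("KM estimator matches hand values and the risk-set product oracle", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))

  km2 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km2$surv == 1))

  set.seed(40)
  for (r in 1:20) {
    n <- sample(5:50, 1)
    times <- round(rexp(n, 0.2), 2)
    events <- rbinom(n, 1, 0.6)
    if (sum(events) == 0) events[1] <- 1
    km <- km_estimate(times, events)
    oracle <- km_oracle(times, events)
    got <- km$surv[match(oracle$time, km$time)]
    expect_equal(got, oracle$surv, tolerance = 1e-12)
    expect_true(all(diff(km$surv) <= 1e-12))
  }
})

test_that("log-rank matches the hand-summed toy and is symmetric", {
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  # O-E = 7/6, hypergeometric variance 17/36 over the four risk sets
  expect_equal(lr$statistic, (7 / 6)^2 / (17 / 36), tolerance = 1e-6)
  expect_equal(lr$statistic, 2.882, tolerance = 1e-3)
  expect_equal(lr$df, 1)

  # identical groups: statistic 0, p 1
  lr0 <- logrank_test(c(1, 2, 1, 2), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)

  # label swap invariance
  lrs <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("B", "B", "A", "A"))
  expect_equal(lrs$statistic, lr$statistic)
  expect_error(logrank_test(1:3, c(1, 1, 1), c("A", "A", "A")), ">= 2")
})

test_that("cox_fit agrees with the grid-search oracle and flags collinearity", {
  times <- c(1, 2, 3, 4); events <- c(1, 1, 1, 1); x <- c(1, 0, 1, 0)
  fit <- cox_fit(data.frame(x = x), times, events)
  expect_equal(fit$beta, efron_grid_beta(times, events, x), tolerance = 2e-3)

  expect_error(cox_fit(data.frame(a = x, b = x), times, events),
               "rank-deficient")
})

test_that("cox_fit recovers a planted two-group hazard ratio of 2", {
  hrs <- numeric(10)
  for (s in 1:10) {
    set.seed(500 + s)
    n <- 600
    g <- rbinom(n, 1, 0.5)
    t_event <- rexp(n, 0.03 * 2^g)
    cens <- rexp(n, 0.01)
    fit <- cox_fit(data.frame(g = g), pmin(t_event, cens),
                   as.integer(t_event <= cens))
    hrs[s] <- fit$HR
  }
  expect_gt(mean(hrs), 1.8)
  expect_lt(mean(hrs), 2.2)
})

test_that("cox_fit score equations are satisfied at the optimum", {
  set.seed(41)
  n <- 150
  x <- rnorm(n)
  t_event <- rexp(n, 0.05 * exp(0.4 * x))
  cens <- rexp(n, 0.02)
  times <- pmin(t_event, cens)
  events <- as.integer(t_event <= cens)
  fit <- cox_fit(data.frame(x = x), times, events)
  # numeric derivative of the Efron partial likelihood at beta-hat ~ 0
  eps <- 1e-5
  dll <- (efron_loglik(fit$beta + eps, times, events, x) -
            efron_loglik(fit$beta - eps, times, events, x)) / (2 * eps)
  expect_lt(abs(dll), 1e-3)
})

test_that("time-dependent AUC: perfect marker, null marker, and U-statistic oracle", {
  set.seed(42)
  n <- 120
  times <- rexp(n, 0.05)
  events <- rep(1L, n)
  marker <- -times  # perfectly orders events
  expect_equal(time_dependent_auc(marker, times, events, median(times)), 1)

  # no censoring: equals the direct case/control rank statistic
  m2 <- rnorm(n)
  h <- quantile(times, 0.4)
  expect_equal(time_dependent_auc(m2, times, events, h),
               auc_u_oracle(m2, times, h), tolerance = 1e-12)

  # independence: AUC near 0.5 most of the time
  inside <- 0
  for (r in 1:40) {
    set.seed(600 + r)
    tt <- rexp(500, 0.05); ev <- rbinom(500, 1, 0.8); mk <- rnorm(500)
    a <- time_dependent_auc(mk, tt, ev, quantile(tt, 0.5))
    inside <- inside + (a > 0.45 && a < 0.55)
  }
  expect_gte(inside / 40, 0.9)

  expect_error(time_dependent_auc(m2, times, events, max(times) + 1), "follow-up")
  expect_error(time_dependent_auc(m2, times, rep(0L, n), median(times)), "no cases")
})

test_that("rank tests reproduce exact enumeration toys", {
  # same values in both groups: symmetric ranks, p = 1
  rt <- suppressWarnings(rank_tests(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3)))
  expect_equal(rt$p_value, 1)

  # (1,2,3) vs (4,5,6): one-sided exact p = 1/20
  rt2 <- rank_tests(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
                    alternative = "less")
  expect_equal(rt2$p_value, 1 / 20)

  kw <- rank_tests(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(unname(kw$statistic), 0)
  expect_match(kw$method, "Kruskal")
  expect_error(rank_tests(1:4, c("a", "a", "a", "a")), ">= 2")
})

test_that("contingency tests match hand-computed chi-squared and Fisher values", {
  ct <- contingency_tests(matrix(c(10, 20, 20, 10), 2, 2))
  expect_equal(ct$chisq_statistic, 20 / 3, tolerance = 1e-12)

  ct2 <- contingency_tests(matrix(c(5, 0, 0, 5), 2, 2))
  expect_equal(ct2$fisher_p, 2 / 252, tolerance = 1e-12)
  expect_true(is.finite(ct2$odds_ratio))  # Haldane correction applied

  # independence table: chi-squared 0
  ct3 <- contingency_tests(matrix(c(10, 10, 10, 10), 2, 2))
  expect_equal(ct3$chisq_statistic, 0)
  expect_error(contingency_tests(matrix(c(-1, 2, 3, 4), 2, 2)), "nonnegative")
})

test_that("Spearman correlation matches the hand formula and is rank-invariant", {
  sp <- spearman_corr(c(1, 2, 3), c(3, 1, 2))
  expect_equal(sp$rho, -0.5)

  x <- c(2, 5, 9, 11, 20)
  expect_equal(spearman_corr(x, exp(x))$rho, 1)
  y <- c(3, 1, 7, 2, 8)
  expect_equal(spearman_corr(x, y)$rho,
               spearman_corr(rank(x), rank(y))$rho)
  expect_error(spearman_corr(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("mutation summaries count frequencies, TMB and co-occurrence correctly", {
  samples <- sprintf("s%d", 1:10)
  empty <- data.frame(Hugo_Symbol = character(),
                      Tumor_Sample_Barcode = character(),
                      Variant_Classification = character())
  ms0 <- mutation_summaries(empty, samples, genes = c("X"))
  expect_true(all(ms0$frequency$frequency == 0))
  expect_true(all(ms0$tmb$tmb == 0))

  mut <- data.frame(
    Hugo_Symbol = c("X", "X", "Y", "Y", "Y", "Y", "Y", "Z"),
    Tumor_Sample_Barcode = c("s1", "s2", "s1", "s2", "s3", "s4", "s5", "s1"),
    Variant_Classification = c(rep("Missense_Mutation", 7), "Silent"))
  ms <- mutation_summaries(mut, samples, genes = c("X", "Y", "Z"))
  expect_equal(ms$frequency$frequency[ms$frequency$gene == "X"], 0.2)
  expect_equal(ms$tmb$tmb[ms$tmb$sample_id == "s1"], 2)  # silent excluded

  # planted always-together pair: Fisher p equals the enumeration oracle
  co_mut <- data.frame(
    Hugo_Symbol = rep(c("A", "B"), each = 5),
    Tumor_Sample_Barcode = rep(sprintf("s%d", 1:5), 2),
    Variant_Classification = "Missense_Mutation")
  samples20 <- sprintf("s%d", 1:20)
  ms2 <- mutation_summaries(co_mut, samples20, genes = c("A", "B"))
  pair <- ms2$cooccurrence[1, ]
  expect_equal(pair$p_value, fisher.test(matrix(c(5, 0, 0, 15), 2, 2))$p.value)
  expect_equal(pair$direction, "co-occurrence")

  expect_warning(
    mutation_summaries(data.frame(Hugo_Symbol = "A", Tumor_Sample_Barcode = "s1",
                                  Variant_Classification = "Weird"),
                       samples), "unknown variant")
})

test_that("CNV gain/loss frequencies partition correctly", {
  calls <- cbind(g1 = c(1, 1, 0, 0), g2 = c(-1, -2, 0, 1), g3 = c(0, 0, 0, 0))
  fr <- cnv_frequencies(calls)
  expect_equal(fr$gain_freq, c(0.5, 0.25, 0))
  expect_equal(fr$loss_freq, c(0, 0.5, 0))
  expect_true(all(fr$gain_freq + fr$loss_freq <= 1))
  expect_error(cnv_frequencies(cbind(g1 = c(3, 0))), "-2..2")
})

test_that("survival statistics are invariant to sample-order permutation", {
  set.seed(43)
  n <- 60
  times <- rexp(n, 0.1); events <- rbinom(n, 1, 0.7)
  g <- rep(c("a", "b"), each = 30)
  perm <- sample(n)
  lr1 <- logrank_test(times, events, g)
  lr2 <- logrank_test(times[perm], events[perm], g[perm])
  expect_equal(lr1$statistic, lr2$statistic)
  v <- rnorm(n)
  expect_equal(rank_tests(v, g)$p_value, rank_tests(v[perm], g[perm])$p_value)
  expect_equal(spearman_corr(times, v)$rho,
               spearman_corr(times[perm], v[perm])$rho)
})
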