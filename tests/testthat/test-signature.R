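test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  set.seed(1)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "within")
})

test_that("variance squeezing follows the posterior formula and its limits", {
  sq <- methpattern:::.squeeze_var
  expect_equal(sq(2, 4, 4, 1), 1.5)  # (4*1 + 4*2) / 8
  expect_equal(sq(c(2, 10), 4, Inf, 1), c(1, 1))  # d0 -> Inf: pooled prior
  expect_equal(sq(3, 5, 0, 1), 3)  # d0 = 0: no shrinkage
})

test_that("trigamma inversion solves trigamma(y) = x", {
  inv <- methpattern:::.trigamma_inverse
  for (x in c(0.01, 0.1, 1, 5, 50)) expect_equal(trigamma(inv(x)), x, tolerance = 1e-6)
})

test_that("moderated F matches limma's empirical-Bayes machinery", {
  skip_if_not_installed("limma")
  set.seed(10)
  n_per <- 5
  groups <- factor(rep(c("a", "b", "c"), each = n_per))
  # heteroskedastic genes so the prior df is finite and actively estimated
  sds <- sqrt(rchisq(300, 4) / 4)
  X <- matrix(rnorm(300 * 15, sd = rep(sds, 15)), 300, 15,
              dimnames = list(sprintf("g%d", 1:300), sprintf("s%d", 1:15)))
  X[1:30, groups == "b"] <- X[1:30, groups == "b"] + 1.5
  out <- moderated_f_test(X, groups)

  design <- stats::model.matrix(~groups)
  fit <- limma::eBayes(limma::lmFit(X, design))
  tt <- limma::topTable(fit, coef = 2:3, sort.by = "none", number = Inf)
  expect_equal(attr(out, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(out, "s0_sq"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(out$F_statistic, tt$F, tolerance = 1e-8)
  expect_equal(out$p_value, tt$P.Value, tolerance = 1e-8)
})

test_that("moderated F shrinks variance estimates relative to raw variances", {
  set.seed(11)
  groups <- factor(rep(1:3, each = 3))
  X <- matrix(rnorm(500 * 9, sd = rep(sqrt(rchisq(500, 4) / 4), 9)), 500, 9,
              dimnames = list(sprintf("g%d", 1:500), sprintf("s%d", 1:9)))
  out <- moderated_f_test(X, groups)
  d0 <- attr(out, "d0"); s0 <- attr(out, "s0_sq"); dfr <- attr(out, "df_residual")
  expect_true(is.finite(d0) && d0 > 0)
  # reconstruct raw and squeezed variances; squeezed must be strictly less
  # dispersed at small n
  raw <- apply(X, 1, function(r) sum(tapply(r, groups, function(g)
    sum((g - mean(g))^2))) / dfr)
  squeezed <- methpattern:::.squeeze_var(raw, dfr, d0, s0)
  expect_lt(var(log(squeezed)), var(log(raw)))
})

test_that("moderated F is calibrated under the global null", {
  # gene variances drawn from the scaled inverse-chi-square family the
  # moderation model assumes, so calibration is a fair ask
  clean <- 0; uniform <- 0
  for (s in 1:5) {
    set.seed(100 + s)
    groups <- factor(rep(1:3, each = 8))
    sds <- sqrt(4 / rchisq(2000, 4))
    X <- matrix(rnorm(2000 * 24, sd = rep(sds, 24)), 2000, 24,
                dimnames = list(sprintf("g%d", 1:2000), sprintf("s%d", 1:24)))
    out <- moderated_f_test(X, groups)
    clean <- clean + (sum(out$adj_p < 0.05) == 0)
    ks <- suppressWarnings(stats::ks.test(out$p_value, "punif"))
    uniform <- uniform + (ks$p.value > 0.01)
  }
  expect_gte(clean, 4)
  expect_gte(uniform, 4)
})

test_that("all-constant genes are flagged with p = 1", {
  X <- rbind(g1 = rep(2, 8), g2 = rnorm(8))
  colnames(X) <- sprintf("s%d", 1:8)
  out <- moderated_f_test(X, rep(1:2, each = 4))
  expect_true(out$flagged[out$gene == "g1"])
  expect_equal(out$p_value[out$gene == "g1"], 1)
  expect_error(moderated_f_test(X, c(1, 1, 1, 1, 1, 1, 1, 2)), ">= 2 samples")
})

test_that("Cox screen beta matches the grid-search Efron oracle on a toy", {
  # earlier deaths in the x = 1 arm, interleaved so the MLE is finite
  times <- c(1, 2, 3, 4)
  events <- c(1, 1, 1, 1)
  x <- c(1, 0, 1, 0)
  expr <- rbind(g1 = x)
  colnames(expr) <- sprintf("s%d", 1:4)
  clin <- data.frame(sample_id = colnames(expr), os_time = times,
                     os_event = events)
  out <- univariate_cox_screen(expr + 0, clin, genes = "g1")
  oracle <- efron_grid_beta(times, events, x)
  expect_equal(out$beta, oracle, tolerance = 2e-3)
  expect_gt(out$beta, 0)
  expect_true(out$ci_low <= out$HR && out$HR <= out$ci_high)
})

test_that("constant genes are flagged out of the Cox screen", {
  set.seed(12)
  expr <- rbind(flat = rep(3, 30), ok = rnorm(30))
  colnames(expr) <- sprintf("s%d", 1:30)
  clin <- data.frame(sample_id = colnames(expr),
                     os_time = rexp(30, 0.1), os_event = rbinom(30, 1, 0.7))
  out <- univariate_cox_screen(expr, clin)
  expect_false("flat" %in% out$gene)
  expect_equal(attr(out, "flagged"), "flat")
})

test_that("planted log-hazard beta = 0.5 is recovered on average", {
  betas <- numeric(10)
  for (s in 1:10) {
    set.seed(200 + s)
    n <- 600
    x <- rnorm(n)
    t_event <- rexp(n, rate = 0.05 * exp(0.5 * x))
    cens <- rexp(n, rate = 0.02)
    expr <- rbind(g1 = x)
    colnames(expr) <- sprintf("s%d", 1:n)
    clin <- data.frame(sample_id = colnames(expr),
                       os_time = pmin(t_event, cens),
                       os_event = as.integer(t_event <= cens))
    betas[s] <- univariate_cox_screen(expr + 0, clin, genes = "g1")$beta
  }
  expect_lt(abs(mean(betas) - 0.5), 0.1)
})

test_that("Wald and likelihood-ratio tests agree on rejection for signal genes", {
  set.seed(13)
  agree <- 0; total <- 0
  n <- 200
  for (g in 1:30) {
    x <- rnorm(n)
    t_event <- rexp(n, rate = 0.05 * exp(0.6 * x))
    cens <- rexp(n, rate = 0.02)
    times <- pmin(t_event, cens); events <- as.integer(t_event <= cens)
    fit <- survival::coxph(survival::Surv(times, events) ~ x)
    wald_p <- 2 * pnorm(-abs(coef(fit) / sqrt(fit$var[1, 1])))
    lr_p <- pchisq(2 * diff(fit$loglik), 1, lower.tail = FALSE)
    total <- total + 1
    agree <- agree + ((wald_p < 0.01) == (lr_p < 0.01))
  }
  expect_gte(agree / total, 0.95)
})

test_that("derive_signature applies the intersection filter deterministically", {
  deg <- data.frame(gene = c("A", "B", "C"), adj_p = c(0.001, 0.001, 0.001),
                    flagged = FALSE)
  cox <- data.frame(gene = c("A", "B", "C"), beta = c(0.5, -0.2, -1),
                    p_value = c(0.005, 0.5, 0.009))
  sig <- derive_signature(deg, cox)
  expect_equal(sig$genes, c("A", "C"))
  expect_equal(unname(sig$direction), c(1, -1))

  all_sig <- derive_signature(deg, cox, deg_threshold = 1, cox_threshold = 1)
  expect_setequal(all_sig$genes, c("A", "B", "C"))

  expect_error(derive_signature(deg, cox, deg_threshold = 1e-9), "empty signature")
})
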