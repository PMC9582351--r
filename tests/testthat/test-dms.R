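toy_clinical <- function(n, seed = 1, rate = 0.1) {
  set.seed(seed)
  t_event <- rexp(n, rate)
  cens <- rexp(n, rate / 3)
  data.frame(sample_id = sprintf("s%02d", seq_len(n)),
             os_time = pmin(t_event, cens),
             os_event = as.integer(t_event <= cens))
}

test_that("PCA loadings and projections match the dense eigen-decomposition oracle", {
  set.seed(20)
  X <- matrix(rnorm(8 * 40), 8, 40,
              dimnames = list(sprintf("g%d", 1:8), sprintf("s%02d", 1:40)))
  X[1:4, 1:20] <- X[1:4, 1:20] + 2
  clin <- toy_clinical(40, seed = 21)
  m <- fit_dms(X, clin, rownames(X), scale. = TRUE, orient = FALSE)

  Xs <- scale(t(X))
  ev <- eigen(crossprod(Xs) / (nrow(Xs) - 1))
  for (j in 1:2) {
    v <- if (j == 1) m$v1 else m$v2
    o <- ev$vectors[, j]
    expect_equal(abs(sum(v * o)), 1, tolerance = 1e-8)  # same direction up to sign
  }
  s <- score_dms(m, X)
  s_o1 <- drop(Xs %*% ev$vectors[, 1]); s_o2 <- drop(Xs %*% ev$vectors[, 2])
  # match oracle projections after aligning each component's sign
  a1 <- sign(sum(m$v1 * ev$vectors[, 1])); a2 <- sign(sum(m$v2 * ev$vectors[, 2]))
  expect_equal(unname(s), unname(a1 * s_o1 + a2 * s_o2), tolerance = 1e-8)
})

test_that("degenerate inputs fail loudly", {
  X <- matrix(5, 4, 10, dimnames = list(sprintf("g%d", 1:4), sprintf("s%02d", 1:10)))
  clin <- toy_clinical(10)
  expect_error(suppressWarnings(fit_dms(X, clin, rownames(X))), "usable")
  expect_error(fit_dms(X[, 1:2], clin, rownames(X)), ">= 3 samples")
})

test_that("training scores are centered, order-invariant and frozen", {
  co <- small_cohort(n = 100, genes = 120, n_sig_genes = 40, seed = 22)
  genes <- co$truth$deg_genes
  m <- fit_dms(co$expression, co$clinical, genes)
  s <- score_dms(m, co$expression)
  expect_lt(abs(mean(s)), 1e-8)
  expect_equal(s, m$scores[names(s)])

  # permuting gene row order changes nothing
  perm <- co$expression[sample(nrow(co$expression)), ]
  expect_equal(score_dms(m, perm), s)

  # a duplicated sample scores identically (frozen model)
  dup <- co$expression[, c(1, 1, 2)]
  colnames(dup) <- c("d1", "d2", "d3")
  sd_ <- score_dms(m, dup)
  expect_equal(sd_[["d1"]], sd_[["d2"]])
  expect_equal(sd_[["d1"]], unname(s[colnames(co$expression)[1]]))

  expect_error(score_dms(m, co$expression[-match(genes[1], rownames(co$expression)), ]),
               "missing")
})

test_that("adding a constant to one gene does not change training-set scores", {
  co <- small_cohort(n = 60, genes = 80, n_sig_genes = 20, seed = 23)
  genes <- co$truth$deg_genes[1:10]
  m1 <- fit_dms(co$expression, co$clinical, genes, orient = FALSE)
  shifted <- co$expression
  shifted[genes[1], ] <- shifted[genes[1], ] + 7
  m2 <- fit_dms(shifted, co$clinical, genes, orient = FALSE)
  s1 <- score_dms(m1, co$expression)
  s2 <- score_dms(m2, shifted)
  # sign of a PC is arbitrary without orientation; compare up to per-PC sign
  agree <- min(max(abs(s1 - s2)), max(abs(s1 + s2)))
  expect_lt(agree, 1e-8)
})

test_that("orientation puts the high-hazard stratum above the low-hazard one", {
  # orientation fixes the score's sign, so the planted highest-hazard group
  # must sit above the planted lowest-hazard group; the ordering of the two
  # high-risk groups among themselves is expression geometry, not sign
  ok <- 0
  for (s in 1:8) {
    co <- small_cohort(n = 250, genes = 300, n_sig_genes = 60, seed = 300 + s)
    m <- fit_dms(co$expression, co$clinical, co$truth$deg_genes)
    med <- tapply(m$scores, co$truth$pattern[names(m$scores)], median)
    hz <- co$config$surv_hazards
    ok <- ok + (med[which.max(hz)] > med[which.min(hz)] &&
                  which.min(med) == which.min(hz))
  }
  expect_equal(ok, 8)
})

test_that("DMS model round-trips through JSON", {
  co <- small_cohort(n = 60, genes = 80, n_sig_genes = 20, seed = 24)
  m <- fit_dms(co$expression, co$clinical, co$truth$deg_genes[1:10])
  f <- tempfile(fileext = ".json")
  write_dms_model(m, f)
  m2 <- read_dms_model(f)
  expect_equal(m2$genes, m$genes)
  expect_equal(m2$v1, m$v1, tolerance = 1e-12)
  s1 <- score_dms(m, co$expression); s2 <- score_dms(m2, co$expression)
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("cutpoint search equals brute-force enumeration over admissible splits", {
  set.seed(25)
  n <- 120
  scores <- setNames(runif(n, -1, 1), sprintf("s%03d", 1:n))
  rate <- ifelse(scores > 0.2, 1.0, 0.2)
  t_event <- rexp(n, rate)
  cens <- rexp(n, 0.1)
  clin <- data.frame(sample_id = names(scores),
                     os_time = pmin(t_event, cens),
                     os_event = as.integer(t_event <= cens))
  cp <- optimal_cutpoint(scores, clin, minprop = 0.1)

  # independent enumeration using survdiff on every admissible midpoint
  s <- sort(scores)
  lo <- ceiling(0.1 * n); hi <- ceiling(0.9 * n) - 1
  cands <- (s[lo:hi] + s[(lo:hi) + 1]) / 2
  zs <- vapply(cands, function(cc) {
    g <- scores > cc
    sd_ <- survival::survdiff(survival::Surv(clin$os_time, clin$os_event) ~ g)
    sqrt(sd_$chisq)
  }, numeric(1))
  expect_equal(cp$statistic, max(zs), tolerance = 1e-8)
  expect_equal(cp$cutpoint, unname(cands[which.max(zs)]))
})

test_that("minprop = 0.4 on 10 samples evaluates exactly the middle two splits", {
  scores <- setNames(1:10 + 0, sprintf("s%02d", 1:10))
  clin <- data.frame(sample_id = names(scores), os_time = c(2, 4, 6, 8, 10, 1, 3, 5, 7, 9),
                     os_event = 1)
  cp <- optimal_cutpoint(scores, clin, minprop = 0.4)
  expect_equal(nrow(cp$candidates), 2)
  expect_equal(cp$candidates$cutpoint, c(4.5, 5.5))
})

test_that("cutpoint recovers a planted step hazard near score zero", {
  hits <- 0
  for (s in 1:10) {
    set.seed(400 + s)
    n <- 300
    scores <- setNames(runif(n, -1, 1), sprintf("s%03d", 1:n))
    rate <- ifelse(scores > 0, 1.0, 0.2)
    t_event <- rexp(n, rate)
    cens <- rexp(n, 0.05)
    clin <- data.frame(sample_id = names(scores),
                       os_time = pmin(t_event, cens),
                       os_event = as.integer(t_event <= cens))
    cp <- optimal_cutpoint(scores, clin, minprop = 0.1)
    hits <- hits + (abs(cp$cutpoint) <= 0.15)
  }
  expect_gte(hits, 9)
})

test_that("tied scores and tiny candidate sets are rejected", {
  clin <- toy_clinical(10)
  expect_error(optimal_cutpoint(setNames(rep(1, 10), clin$sample_id), clin),
               "tied")
  expect_error(optimal_cutpoint(setNames(1:10 + 0, clin$sample_id), clin,
                                minprop = 0.49), "admissible")
})
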