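# Independent oracles used across the suite. These deliberately use naive,
# direct computations (loops, enumeration, grid search) so they stay
# independent of the package's implementation paths.

# Brute-force Benjamini-Hochberg step-up.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- prev
  }
  pmin(adj, 1)
}

# Product-limit estimator by explicit risk-set products at event times.
km_oracle <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    n_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  data.frame(time = ut, surv = out)
}

# Efron-tie Cox log partial likelihood for a single covariate.
efron_loglik <- function(beta, times, events, x) {
  ll <- 0
  for (tt in sort(unique(times[events == 1]))) {
    D <- which(times == tt & events == 1)
    R <- which(times >= tt)
    d <- length(D)
    sumD <- sum(exp(beta * x[D]))
    sumR <- sum(exp(beta * x[R]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_len(d) - 1) ll <- ll - log(sumR - (l / d) * sumD)
  }
  ll
}

# Grid-search maximizer of the Efron partial likelihood.
efron_grid_beta <- function(times, events, x, lo = -5, hi = 5, step = 1e-3) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, efron_loglik, numeric(1), times = times, events = events,
               x = x)
  grid[which.max(ll)]
}

# Step-by-step ssGSEA enrichment score for one sample.
ssgsea_oracle <- function(values, set_genes, alpha) {
  r <- rank(values, ties.method = "average")
  ord <- order(r, decreasing = TRUE)
  genes <- names(values)[ord]
  rr <- r[ord]
  in_set <- genes %in% set_genes
  num_in <- 0; num_out <- 0
  tot_in <- sum(abs(rr[in_set])^alpha)
  tot_out <- sum(!in_set)
  es <- 0
  for (i in seq_along(genes)) {
    if (in_set[i]) num_in <- num_in + abs(rr[i])^alpha else num_out <- num_out + 1
    es <- es + (num_in / tot_in - num_out / tot_out)
  }
  unname(es)
}

# Classical weighted KS running-sum ES (signed extremum) for a preranked
# list, direct loop.
gsea_es_oracle <- function(ranking, set_genes, weight) {
  ord <- order(ranking, decreasing = TRUE)
  stat <- ranking[ord]
  hit <- names(stat) %in% set_genes
  denom <- sum(abs(stat[hit])^weight)
  nmiss <- sum(!hit)
  run <- 0; best <- 0
  for (i in seq_along(stat)) {
    run <- run + if (hit[i]) abs(stat[i])^weight / denom else -1 / nmiss
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Case/control rank statistic (no censoring) for the time-dependent AUC.
auc_u_oracle <- function(marker, times, horizon) {
  case <- which(times <= horizon)
  ctrl <- which(times > horizon)
  num <- 0
  for (i in case) for (j in ctrl)
    num <- num + (marker[i] > marker[j]) + 0.5 * (marker[i] == marker[j])
  num / (length(case) * length(ctrl))
}

# Small deterministic expression fixture: k well-separated blocks.
block_matrix <- function(n_genes = 20, n_samples = 30, k = 3, shift = 10,
                         seed = 1) {
  set.seed(seed)
  lab <- rep(seq_len(k), length.out = n_samples)
  X <- matrix(runif(n_genes * n_samples, 1, 2), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  blocks <- split(seq_len(n_genes), rep(seq_len(k), length.out = n_genes))
  for (p in seq_len(k)) X[blocks[[p]], lab == p] <- X[blocks[[p]], lab == p] + shift
  list(X = X, labels = lab)
}

small_cohort <- function(n = 120, genes = 400, seed = 1, ...) {
  generate_cohort(synthetic_config(n_samples = n, n_genes = genes,
                                   seed = seed, ...))
}
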