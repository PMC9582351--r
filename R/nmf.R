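#' Nonnegative matrix factorization by multiplicative updates
#'
#' Factorizes a nonnegative matrix `X ~ W %*% H` (genes x k, k x samples)
#' by multiplicative updates. The default objective is the generalized
#' Kullback-Leibler divergence (the Brunet variant classically used for
#' expression subtype discovery); a Frobenius variant is available. Updates
#' stop at `max_iter` or when the relative objective change falls below
#' `tol`. On return, rows of `H` are scaled to unit sum (the scale moved
#' into `W`) so that argmax-`H` sample labels are scale-free.
#'
#' @param X nonnegative numeric matrix. If your matrix can be negative
#'   (e.g. after batch adjustment), shift it first — see [shift_nonnegative()].
#' @param k factorization rank, `1 <= k <= min(dim(X))`.
#' @param max_iter maximum iterations.
#' @param tol relative objective-change stopping tolerance (checked each
#'   iteration).
#' @param seed RNG seed for the uniform initialization.
#' @param method `"kl"` (generalized KL divergence) or `"frobenius"`.
#' @return List of class `nmf_result`: `W`, `H`, `objective_trace`,
#'   `iterations`, `converged`, `seed`, `method`.
#' @export
nmf_factorize <- function(X, k, max_iter = 500, tol = 1e-6, seed = NULL,
                          method = c("kl", "frobenius")) {
  method <- match.arg(method)
  if (!is.matrix(X) || !is.numeric(X)) .stopf("X must be a numeric matrix")
  if (any(X < 0))
    .stopf("X has negative entries; shift to nonnegative first (shift_nonnegative)")
  k <- as.integer(k)
  if (k < 1 || k > min(dim(X)))
    .stopf("k = %d out of range [1, %d]", k, min(dim(X)))
  m <- nrow(X); n <- ncol(X)
  eps <- .Machine$double.eps
  .with_seed(seed, {
    sc <- sqrt(mean(X) / k)
    W <- matrix(runif(m * k, 0, 1), m, k) * sc + eps
    H <- matrix(runif(k * n, 0, 1), k, n) * sc + eps
    trace <- numeric(0)
    obj <- function(WH) {
      if (method == "kl") {
        sum(ifelse(X > 0, X * log(X / WH), 0) - X + WH)
      } else {
        0.5 * sum((X - WH)^2)
      }
    }
    prev <- Inf
    iter <- 0L
    converged <- FALSE
    while (iter < max_iter) {
      iter <- iter + 1L
      if (method == "kl") {
        WH <- W %*% H + eps
        H <- H * (crossprod(W, X / WH)) / (colSums(W) + eps)
        WH <- W %*% H + eps
        W <- W * ((X / WH) %*% t(H)) / (rep(rowSums(H), each = m) + eps)
        cur <- obj(W %*% H + eps)
      } else {
        H <- H * crossprod(W, X) / (crossprod(W, W) %*% H + eps)
        W <- W * (X %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
        cur <- obj(W %*% H)
      }
      trace <- c(trace, cur)
      if (is.finite(prev) && abs(prev - cur) <= tol * max(abs(prev), eps)) {
        converged <- TRUE
        break
      }
      prev <- cur
    }
    d <- rowSums(H)
    d[d == 0] <- 1
    W <- W * rep(d, each = m)
    H <- H / d
    dimnames(W) <- list(rownames(X), NULL)
    dimnames(H) <- list(NULL, colnames(X))
    structure(list(W = W, H = H, objective_trace = trace, iterations = iter,
                   converged = converged, seed = seed, method = method),
              class = "nmf_result")
  })
}

#' Shift a matrix to be nonnegative
#'
#' Adds a global constant so the minimum is zero (no-op when already
#' nonnegative); the shift applied is recorded as the `shift` attribute.
#' Used to feed batch-adjusted (possibly negative) expression into NMF.
#'
#' @param X numeric matrix.
#' @return Shifted matrix with attribute `shift`.
#' @export
shift_nonnegative <- function(X) {
  s <- min(X)
  shift <- if (s < 0) -s else 0
  out <- X + shift
  attr(out, "shift") <- shift
  out
}

#' Remove per-gene baselines before NMF
#'
#' Subtracts each gene's minimum so every row starts at zero. On log-scale
#' expression the shared per-gene baseline dominates the factorization and
#' makes KL-NMF non-identifiable up to "complement" solutions (components
#' describing which cluster a sample is NOT in, at the same divergence);
#' removing the baseline leaves the between-sample contrast that clustering
#' actually uses, and also guarantees nonnegativity after batch adjustment.
#' The subtracted baselines are recorded as the `baseline` attribute.
#'
#' @param X numeric genes x samples matrix.
#' @return Nonnegative matrix of identical dimensions.
#' @export
remove_gene_baseline <- function(X) {
  base <- apply(X, 1, min)
  out <- X - base
  attr(out, "baseline") <- base
  out
}

#' Consensus clustering over subsampled NMF restarts
#'
#' For each candidate rank `k`, runs `n_runs` NMF factorizations from
#' distinct seeds, each on a random `subsample` fraction of the samples
#' (the Monti-style perturbation that makes over-merged ranks reveal their
#' instability), labels the subsampled columns by argmax over `H`, and
#' records the consensus matrix: entry (i, j) is the fraction of runs
#' containing both samples in which they share a label. Rank stability is
#' summarized by the cophenetic correlation coefficient — the correlation
#' between the consensus dissimilarity (1 - consensus) and the cophenetic
#' distances of its average-linkage dendrogram — and by the dispersion
#' coefficient.
#'
#' @param X nonnegative genes x samples matrix (typically the regulator
#'   sub-matrix after [remove_gene_baseline()]).
#' @param k_range candidate ranks (integer vector, each >= 2).
#' @param n_runs restarts per rank (>= 10).
#' @param seed base seed; run seeds are derived deterministically.
#' @param subsample fraction of samples drawn per run, in (0, 1];
#'   `1` disables subsampling (all runs see every sample).
#' @param ... passed to [nmf_factorize()].
#' @return List of class `consensus_result`: per-k list with `consensus`,
#'   `cophenetic`, `dispersion`, `n_degenerate_runs`; plus `k_range`,
#'   `n_runs`, `subsample`, `seed`.
#' @export
consensus_cluster <- function(X, k_range = 2:5, n_runs = 30, seed = 1,
                              subsample = 0.8, ...) {
  if (n_runs < 10) .stopf("n_runs must be >= 10")
  if (subsample <= 0 || subsample > 1) .stopf("subsample must lie in (0, 1]")
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2)) .stopf("consensus ranks must be >= 2")
  n <- ncol(X)
  n_sub <- max(2L, round(subsample * n))
  per_k <- list()
  for (k in k_range) {
    counts <- matrix(0, n, n)
    totals <- matrix(0, n, n)
    degenerate <- 0L
    for (r in seq_len(n_runs)) {
      run_seed <- .derive_seed(seed, k, r)
      idx <- if (n_sub < n) {
        .with_seed(run_seed, sort(sample.int(n, n_sub)))
      } else seq_len(n)
      fit <- nmf_factorize(X[, idx, drop = FALSE], k, seed = run_seed, ...)
      lab <- apply(fit$H, 2, which.max)
      if (length(unique(lab)) < k) degenerate <- degenerate + 1L
      counts[idx, idx] <- counts[idx, idx] + outer(lab, lab, "==")
      totals[idx, idx] <- totals[idx, idx] + 1
    }
    # pairs never co-subsampled (vanishingly rare at n_runs >= 10) carry no
    # evidence; give them the uninformative midpoint
    C <- ifelse(totals > 0, counts / pmax(totals, 1), 0.5)
    diag(C) <- 1
    dimnames(C) <- list(colnames(X), colnames(X))
    coph <- if (degenerate == n_runs) NA_real_ else .cophenetic_coefficient(C)
    per_k[[as.character(k)]] <- list(
      consensus = C,
      cophenetic = coph,
      dispersion = mean(4 * (C - 0.5)^2),
      n_degenerate_runs = degenerate
    )
  }
  structure(list(per_k = per_k, k_range = k_range, n_runs = n_runs,
                 subsample = subsample, seed = seed),
            class = "consensus_result")
}

.cophenetic_coefficient <- function(C) {
  d <- as.dist(1 - C)
  hc <- hclust(d, method = "average")
  cd <- cophenetic(hc)
  if (sd(d) < 1e-12 || sd(cd) < 1e-12) {
    # perfectly stable (or perfectly flat) consensus: correlation undefined;
    # call it 1 when the dendrogram reproduces the distances exactly
    return(if (max(abs(d - cd)) < 1e-12) 1.0 else NA_real_)
  }
  cor(d, cd)
}

#' Select the factorization rank by cophenetic correlation
#'
#' Returns the candidate rank maximizing the cophenetic coefficient; ties
#' go to the smallest rank.
#'
#' @param cr a [consensus_cluster()] result.
#' @return Selected rank (integer).
#' @export
select_rank <- function(cr) {
  stopifnot(inherits(cr, "consensus_result"))
  coph <- vapply(cr$per_k, function(x) x$cophenetic, numeric(1))
  ok <- is.finite(coph)
  if (sum(ok) < 1) .stopf("no candidate rank has a finite cophenetic coefficient")
  ks <- cr$k_range[ok]
  coph <- coph[ok]
  ks[which.max(coph)]  # which.max takes the first (smallest k) on ties
}

#' Assign modification-pattern labels
#'
#' From a single NMF fit, labels are argmax over the `H` rows. From a
#' consensus result (the default pipeline path), samples are clustered by
#' average linkage on the consensus dissimilarity and the tree cut at `k`.
#' Clusters are renamed `A`, `B`, `C`, ... by descending size, ties broken
#' by first occurrence, so labels are deterministic.
#'
#' @param x an `nmf_result` or `consensus_result`.
#' @param k rank to cut at (required for consensus; defaults to
#'   [select_rank()]).
#' @param strict error (rather than warn) on an empty cluster.
#' @return data.frame with `sample_id` and `pattern` (factor).
#' @export
assign_patterns <- function(x, k = NULL, strict = FALSE) {
  if (inherits(x, "nmf_result")) {
    lab <- apply(x$H, 2, which.max)
    ids <- colnames(x$H) %||% sprintf("sample%d", seq_along(lab))
    k <- nrow(x$H)
  } else if (inherits(x, "consensus_result")) {
    k <- k %||% select_rank(x)
    entry <- x$per_k[[as.character(k)]]
    if (is.null(entry)) .stopf("rank %d not present in consensus result", k)
    hc <- hclust(as.dist(1 - entry$consensus), method = "average")
    lab <- cutree(hc, k = k)
    ids <- rownames(entry$consensus) %||% sprintf("sample%d", seq_along(lab))
  } else {
    .stopf("x must be an nmf_result or consensus_result")
  }
  if (length(unique(lab)) < k) {
    msg <- sprintf("degenerate solution: %d of %d clusters are empty",
                   k - length(unique(lab)), k)
    if (strict) .stopf("%s", msg) else .warnf("%s", msg)
  }
  sizes <- table(lab)
  firstocc <- vapply(names(sizes), function(l) which(lab == l)[1], numeric(1))
  ord <- names(sizes)[order(-as.numeric(sizes), firstocc)]
  newlab <- LETTERS[match(as.character(lab), ord)]
  data.frame(sample_id = ids,
             pattern = factor(newlab, levels = LETTERS[seq_along(ord)]),
             stringsAsFactors = FALSE)
}
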