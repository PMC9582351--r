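# Single-sample enrichment score for one sample's ranks and one set.
# r: per-gene expression ranks (ties averaged), ind: in-set indicator over
# genes ordered by decreasing rank; returns the integrated difference of
# the weighted in-set ECDF and the unweighted out-set ECDF.
.ssgsea_es <- function(r, in_set, alpha) {
  ord <- order(r, decreasing = TRUE)
  ind <- in_set[ord]
  w <- abs(r[ord])^alpha
  win <- w * ind
  pin <- cumsum(win) / sum(win)
  pout <- cumsum(!ind) / sum(!ind)
  sum(pin - pout)
}

#' Single-sample gene-set enrichment (ssGSEA)
#'
#' Per sample, genes are ranked by expression (ties averaged) and the
#' enrichment score of a set is the sum over the ranked list of the
#' difference between the weighted in-set empirical CDF (weight
#' `|rank|^alpha`) and the unweighted out-of-set empirical CDF. Scores are
#' rank-based, hence invariant to monotone within-sample transforms. By
#' default the full score matrix is range-normalized (divided by
#' `max - min`).
#'
#' @param expr genes x samples matrix.
#' @param sets named list of gene vectors (e.g. from [read_gene_sets()]).
#' @param alpha rank-weighting exponent (default 0.25, the classical
#'   ssGSEA weight).
#' @param min_set minimum number of set genes present in `expr`; smaller
#'   sets are dropped with a warning.
#' @param normalize range-normalize the score matrix (default TRUE).
#' @return gene-set x sample matrix with attributes `method = "ssgsea"`
#'   and `normalized`.
#' @export
ssgsea_scores <- function(expr, sets, alpha = 0.25, min_set = 3,
                          normalize = TRUE) {
  .assert_expression(expr)
  if (length(sets) == 0) .stopf("empty gene-set collection")
  present <- lapply(sets, function(g) intersect(unique(g), rownames(expr)))
  sizes <- lengths(present)
  if (any(sizes < min_set)) {
    .warnf("dropping %d set(s) with < %d genes present",
           sum(sizes < min_set), min_set)
    present <- present[sizes >= min_set]
  }
  if (length(present) == 0) .stopf("no gene set has >= min_set genes present")
  genes <- rownames(expr)
  indicators <- lapply(present, function(g) genes %in% g)
  ranks <- apply(expr, 2, rank, ties.method = "average")
  es <- matrix(NA_real_, length(present), ncol(expr),
               dimnames = list(names(present), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    r <- ranks[, j]
    ord <- order(r, decreasing = TRUE)
    w <- abs(r[ord])^alpha
    for (si in seq_along(indicators)) {
      ind <- indicators[[si]][ord]
      win <- w * ind
      pin <- cumsum(win) / sum(win)
      pout <- cumsum(!ind) / sum(!ind)
      es[si, j] <- sum(pin - pout)
    }
  }
  if (normalize) {
    rng <- max(es) - min(es)
    if (rng > 0) es <- es / rng
  }
  attr(es, "method") <- "ssgsea"
  attr(es, "normalized") <- normalize
  es
}

#' Stromal, immune and combined (ESTIMATE-style) scores
#'
#' ssGSEA scores of a stromal and an immune signature, plus their sum as
#' the combined estimate score — the ESTIMATE-style summary of
#' microenvironment content.
#'
#' @param expr genes x samples matrix.
#' @param stromal_set,immune_set character vectors of signature genes.
#' @param alpha ssGSEA weight.
#' @return data.frame with `sample_id`, `stromal`, `immune`, `estimate`.
#' @export
estimate_scores <- function(expr, stromal_set, immune_set, alpha = 0.25) {
  es <- ssgsea_scores(expr,
                      list(stromal = stromal_set, immune = immune_set),
                      alpha = alpha, normalize = FALSE)
  data.frame(sample_id = colnames(es),
             stromal = es["stromal", ], immune = es["immune", ],
             estimate = es["stromal", ] + es["immune", ],
             row.names = NULL, stringsAsFactors = FALSE)
}

# Weighted KS running-sum enrichment score for a preranked list.
# Returns ES (signed extremum) and the extremum position.
.gsea_running <- function(stat_sorted, hit, weight) {
  w <- abs(stat_sorted)^weight
  wh <- w * hit
  denom_hit <- sum(wh)
  n_miss <- sum(!hit)
  if (denom_hit == 0 || n_miss == 0) return(list(es = NA_real_, pos = NA_integer_))
  running <- cumsum(hit * wh / denom_hit - (!hit) / n_miss)
  pos <- which.max(abs(running))
  list(es = unname(running[pos]), pos = unname(pos), running = unname(running))
}

#' Preranked gene-set enrichment analysis
#'
#' Classical weighted Kolmogorov-Smirnov running-sum enrichment on a
#' sorted gene-level ranking statistic; significance by gene-label
#' permutation. `NES = ES / mean(|null ES| of matching sign)`; the
#' permutation p-value is two-sided with a +1 pseudocount, so it is always
#' at least `1 / (n_perm + 1)`.
#'
#' @param ranking named numeric vector of per-gene statistics (no NA).
#' @param set character vector of set genes (>= 3 in the ranking).
#' @param n_perm number of permutations (warning below 100).
#' @param weight running-sum weight exponent (default 1).
#' @param seed RNG seed.
#' @return List of class `gsea_result`: `ES`, `NES`, `p_value`,
#'   `leading_edge`, `n_perm`.
#' @export
preranked_gsea <- function(ranking, set, n_perm = 1000, weight = 1,
                           seed = NULL) {
  if (is.null(names(ranking)) || any(!is.finite(ranking)))
    .stopf("ranking must be a named, finite numeric vector")
  if (anyDuplicated(names(ranking))) .stopf("duplicated gene names in ranking")
  hitgenes <- intersect(names(ranking), unique(set))
  if (length(hitgenes) < 3) .stopf("fewer than 3 set genes in the ranking")
  if (length(hitgenes) == length(ranking))
    .stopf("set covers the whole ranking")
  if (n_perm < 100) .warnf("n_perm < 100 gives a coarse p-value grid")
  ord <- order(ranking, decreasing = TRUE)
  stat_sorted <- ranking[ord]
  hit <- names(stat_sorted) %in% hitgenes
  obs <- .gsea_running(stat_sorted, hit, weight)
  es <- obs$es
  leading <- if (es >= 0) {
    names(stat_sorted)[seq_len(obs$pos)][hit[seq_len(obs$pos)]]
  } else {
    tail_idx <- obs$pos:length(stat_sorted)
    names(stat_sorted)[tail_idx][hit[tail_idx]]
  }
  nh <- length(hitgenes)
  N <- length(ranking)
  null_es <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      h <- logical(N)
      h[sample.int(N, nh)] <- TRUE
      .gsea_running(stat_sorted, h, weight)$es
    }, numeric(1))
  })
  same_sign <- null_es[sign(null_es) == sign(es) | null_es == 0]
  nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
  p <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
  structure(list(ES = es, NES = nes, p_value = p,
                 leading_edge = leading, n_perm = n_perm, weight = weight),
            class = "gsea_result")
}

#' Compare enrichment scores between strata
#'
#' Operationalizes group-level "activated pathway" statements: for every
#' gene set, a rank test of its per-sample scores across groups (Wilcoxon
#' for 2 groups, Kruskal-Wallis otherwise), BH-adjusted over sets.
#'
#' @param scores gene-set x sample matrix (e.g. [ssgsea_scores()]).
#' @param groups group labels, one per sample.
#' @return data.frame: `gene_set`, per-group median columns, `statistic`,
#'   `p_value`, `adj_p`.
#' @export
enrichment_group_test <- function(scores, groups) {
  groups <- as.factor(groups)
  if (length(groups) != ncol(scores))
    .stopf("groups do not match score columns")
  res <- lapply(rownames(scores), function(gs) {
    rt <- rank_tests(scores[gs, ], groups)
    meds <- tapply(scores[gs, ], groups, median)
    out <- data.frame(gene_set = gs, stringsAsFactors = FALSE)
    for (g in levels(groups)) out[[paste0("median_", g)]] <- unname(meds[g])
    out$statistic <- rt$statistic
    out$p_value <- rt$p_value
    out
  })
  out <- do.call(rbind, res)
  out$adj_p <- bh_adjust(out$p_value)
  out
}
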