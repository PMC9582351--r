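#' Kaplan-Meier survival curve
#'
#' Product-limit estimate with Greenwood 95% confidence bands (via
#' `survival::survfit`, log CI). A censored-only tail leaves the curve
#' flat.
#'
#' @param times follow-up times (>= 0).
#' @param events event indicators (0 = censored, 1 = event).
#' @param conf_int include Greenwood CI columns.
#' @return data.frame of class `survival_curve`: `time`, `n_risk`,
#'   `n_event`, `surv`, and `lower`/`upper` when requested.
#' @export
km_estimate <- function(times, events, conf_int = TRUE) {
  .assert_survival(times, events)
  if (length(times) < 1) .stopf("need >= 1 subject")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = if (conf_int) "log" else "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv)
  if (conf_int) {
    out$lower <- fit$lower
    out$upper <- fit$upper
  }
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Log-rank test
#'
#' Observed-minus-expected over pooled event times with hypergeometric
#' variance (`survival::survdiff`), df = number of groups - 1.
#'
#' @param times,events survival data.
#' @param groups group labels (>= 2 non-empty groups).
#' @return List: `statistic` (chi-squared), `df`, `p_value`.
#' @export
logrank_test <- function(times, events, groups) {
  .assert_survival(times, events)
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) .stopf("need >= 2 non-empty groups")
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1
  list(statistic = unname(fit$chisq), df = df,
       p_value = pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Multivariable Cox regression (Newton-Raphson with step-halving, Efron
#' or Breslow ties, via `survival::coxph`) returning per-covariate hazard
#' ratios with 95% Wald intervals. Rank-deficient designs (e.g. duplicated
#' covariates) raise an error rather than silently dropping terms.
#'
#' @param design data.frame or matrix of covariates (no missing values;
#'   factors allowed in a data.frame).
#' @param times,events survival data aligned with the design rows.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return data.frame of class `cox_model`: `term`, `beta`, `HR`,
#'   `ci_low`, `ci_high`, `p_value`; attributes `converged`, `ties`,
#'   `loglik`.
#' @export
cox_fit <- function(design, times, events, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  .assert_survival(times, events)
  if (sum(events) < 1) .stopf("need >= 1 event")
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  if (nrow(design) != length(times)) .stopf("design rows do not match times")
  if (any(!complete.cases(design))) .stopf("design contains missing values")
  mm <- stats::model.matrix(~ ., data = design)
  if (qr(mm)$rank < ncol(mm))
    .stopf("rank-deficient design (collinear covariates)")
  dat <- cbind(design, .time = times, .event = events)
  fit <- survival::coxph(survival::Surv(.time, .event) ~ .,
                         data = dat[, c(names(design), ".time", ".event")],
                         ties = ties)
  beta <- coef(fit)
  se <- sqrt(diag(fit$var))
  out <- data.frame(term = names(beta), beta = unname(beta),
                    HR = exp(unname(beta)),
                    ci_low = exp(unname(beta) - 1.96 * se),
                    ci_high = exp(unname(beta) + 1.96 * se),
                    p_value = 2 * stats::pnorm(-abs(unname(beta) / se)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "converged") <- fit$iter < fit$control$iter.max &&
    all(is.finite(beta))
  attr(out, "ties") <- ties
  attr(out, "loglik") <- fit$loglik
  class(out) <- c("cox_model", "data.frame")
  out
}

#' Time-dependent AUC for a prognostic marker
#'
#' Cumulative/dynamic AUC at horizon `t` with inverse-probability-of-
#' censoring weights from the Kaplan-Meier estimate of the censoring
#' distribution: cases are subjects with an event by `t`, controls those
#' still under observation beyond `t`. Without censoring this reduces to
#' the empirical case/control rank (U) statistic.
#'
#' @param marker numeric risk marker (higher = higher risk).
#' @param times,events survival data.
#' @param horizon evaluation time `t` within observed follow-up.
#' @return AUC(t), a number in [0, 1].
#' @export
time_dependent_auc <- function(marker, times, events, horizon) {
  .assert_survival(times, events)
  if (length(marker) != length(times)) .stopf("marker length mismatch")
  if (any(!is.finite(marker))) .stopf("non-finite marker values")
  if (horizon <= 0 || horizon > max(times))
    .stopf("horizon must lie within observed follow-up (0, %g]", max(times))
  case <- times <= horizon & events == 1
  ctrl <- times > horizon
  if (!any(case)) .stopf("no cases by the horizon; AUC undefined")
  if (!any(ctrl)) .stopf("no controls beyond the horizon; AUC undefined")
  cens_fit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  G <- stats::stepfun(cens_fit$time, c(1, cens_fit$surv), right = FALSE)
  # left limit G(u-): survival just before u
  G_minus <- function(u) vapply(u, function(x) {
    idx <- cens_fit$time < x
    if (!any(idx)) 1 else cens_fit$surv[max(which(idx))]
  }, numeric(1))
  w_case <- 1 / G_minus(times[case])
  drop <- !is.finite(w_case)
  if (any(drop)) {
    .warnf("dropping %d case(s) with zero censoring-survival weight", sum(drop))
    w_case <- w_case[!drop]
  }
  m_case <- marker[case][if (any(drop)) !drop else TRUE]
  m_ctrl <- marker[ctrl]
  if (length(m_case) == 0) .stopf("no weighted cases remain")
  comp <- outer(m_case, m_ctrl, ">") + 0.5 * outer(m_case, m_ctrl, "==")
  sum(w_case * rowSums(comp)) / (sum(w_case) * length(m_ctrl))
}

#' Rank tests between groups
#'
#' Wilcoxon rank-sum for 2 groups, Kruskal-Wallis for 3 or more; average
#' ranks on ties with the usual tie-corrected approximations
#' (`stats::wilcox.test` / `stats::kruskal.test`).
#'
#' @param values numeric vector.
#' @param groups group labels (each non-empty).
#' @param ... passed to the underlying test (e.g. `alternative`, `exact`).
#' @return List: `statistic`, `p_value`, `method`.
#' @export
rank_tests <- function(values, groups, ...) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) .stopf("need >= 2 non-empty groups")
  if (length(values) != length(groups)) .stopf("values/groups length mismatch")
  if (nlevels(groups) == 2) {
    lv <- levels(groups)
    ht <- wilcox.test(values[groups == lv[1]], values[groups == lv[2]], ...)
  } else {
    ht <- kruskal.test(values, groups)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = ht$method)
}

#' Contingency-table tests
#'
#' Pearson chi-squared (no continuity correction by default; Yates by
#' flag) for any r x c table of counts; for 2 x 2 tables additionally the
#' Fisher exact two-sided p and the sample odds ratio (Haldane 0.5
#' correction when a cell is zero).
#'
#' @param tab matrix of nonnegative integer counts.
#' @param yates apply Yates continuity correction to the chi-squared test.
#' @return List: `chisq_statistic`, `chisq_df`, `chisq_p`, and for 2 x 2
#'   also `fisher_p`, `odds_ratio`.
#' @export
contingency_tests <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    .stopf("counts must be nonnegative integers")
  cs <- suppressWarnings(chisq.test(tab, correct = yates))
  out <- list(chisq_statistic = unname(cs$statistic),
              chisq_df = unname(cs$parameter), chisq_p = cs$p.value)
  if (all(dim(tab) == c(2, 2))) {
    out$fisher_p <- fisher.test(tab)$p.value
    t2 <- tab
    if (any(t2 == 0)) t2 <- t2 + 0.5
    out$odds_ratio <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  }
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks with the t-approximation p-value.
#'
#' @param x,y equal-length numeric vectors (n >= 3), neither constant.
#' @return List: `rho`, `p_value`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    .stopf("x and y must have equal length >= 3")
  if (sd(x) == 0 || sd(y) == 0) .stopf("constant vector; rho undefined")
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p_value = ht$p.value)
}

#' Mutation landscape summaries
#'
#' From a MAF-like call table: per-gene mutated-sample frequency
#' (non-silent calls over the provided sample universe), per-sample tumor
#' mutation burden (non-silent call count, optionally scaled), and
#' pairwise mutation co-occurrence Fisher exact tests, BH-adjusted over
#' pairs.
#'
#' @param mut data.frame with Hugo_Symbol, Tumor_Sample_Barcode,
#'   Variant_Classification.
#' @param samples the sample universe (frequency denominator).
#' @param genes genes for the frequency/co-occurrence summaries (default:
#'   all mutated genes).
#' @param nonsilent variant classes counted as non-silent.
#' @param unknown_class how to treat classes outside the known vocabulary.
#' @param tmb_scale multiplicative TMB scaling constant (e.g. 1/Mb);
#'   default 1 (raw counts).
#' @return List: `frequency` (gene, n_mutated, frequency), `tmb`
#'   (sample_id, tmb), `cooccurrence` (gene1, gene2, p_value, adj_p,
#'   odds_ratio, direction).
#' @export
mutation_summaries <- function(mut, samples, genes = NULL,
                               nonsilent = setdiff(.variant_classes(), "Silent"),
                               unknown_class = c("exclude", "include"),
                               tmb_scale = 1) {
  unknown_class <- match.arg(unknown_class)
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  if (!all(need %in% names(mut))) .stopf("mutation table lacks MAF columns")
  known <- c(.variant_classes(), nonsilent)
  unk <- !(mut$Variant_Classification %in% known)
  if (any(unk)) {
    .warnf("%d call(s) with unknown variant class (%s)", sum(unk), unknown_class)
    if (unknown_class == "exclude") mut <- mut[!unk, , drop = FALSE]
  }
  ns <- mut[mut$Variant_Classification %in% nonsilent |
              (unknown_class == "include" &
                 !(mut$Variant_Classification %in% .variant_classes())), ,
            drop = FALSE]
  ns <- ns[ns$Tumor_Sample_Barcode %in% samples, , drop = FALSE]
  if (is.null(genes)) genes <- sort(unique(ns$Hugo_Symbol))

  mut_by_gene <- lapply(setNames(genes, genes), function(g)
    unique(ns$Tumor_Sample_Barcode[ns$Hugo_Symbol == g]))
  n_mut <- vapply(mut_by_gene, length, integer(1))
  frequency <- data.frame(gene = genes, n_mutated = unname(n_mut),
                          frequency = unname(n_mut) / length(samples),
                          stringsAsFactors = FALSE)

  counts <- table(factor(ns$Tumor_Sample_Barcode, levels = samples))
  tmb <- data.frame(sample_id = samples, tmb = as.numeric(counts) * tmb_scale,
                    stringsAsFactors = FALSE)

  cooc <- NULL
  informative <- genes[n_mut > 0 & n_mut < length(samples)]
  if (length(informative) >= 2) {
    pairs <- utils::combn(informative, 2)
    rows <- apply(pairs, 2, function(pr) {
      a <- samples %in% mut_by_gene[[pr[1]]]
      b <- samples %in% mut_by_gene[[pr[2]]]
      tab <- table(factor(a, c(TRUE, FALSE)), factor(b, c(TRUE, FALSE)))
      ft <- fisher.test(tab)
      # fisher.test can return 1 + O(eps) from summing tail probabilities
      data.frame(gene1 = pr[1], gene2 = pr[2], p_value = min(ft$p.value, 1),
                 odds_ratio = unname(ft$estimate), stringsAsFactors = FALSE)
    })
    cooc <- do.call(rbind, rows)
    cooc$adj_p <- bh_adjust(cooc$p_value)
    cooc$direction <- ifelse(cooc$odds_ratio > 1, "co-occurrence",
                             "mutual exclusivity")
    cooc <- cooc[, c("gene1", "gene2", "p_value", "adj_p", "odds_ratio",
                     "direction")]
  }
  list(frequency = frequency, tmb = tmb, cooccurrence = cooc)
}

#' Copy-number gain/loss frequencies
#'
#' From discrete copy-number calls (GISTIC-style -2..2), the per-gene
#' fraction of samples with a gain (call above `gain_threshold`) or a loss
#' (below `loss_threshold`).
#'
#' @param calls samples x genes matrix with values in \{-2, -1, 0, 1, 2\}.
#' @param gain_threshold,loss_threshold call thresholds (defaults 0).
#' @return data.frame: `gene`, `gain_freq`, `loss_freq`.
#' @export
cnv_frequencies <- function(calls, gain_threshold = 0, loss_threshold = 0) {
  calls <- as.matrix(calls)
  if (!all(calls %in% -2:2))
    .stopf("copy-number calls must be integers in -2..2")
  data.frame(gene = colnames(calls) %||% sprintf("g%d", seq_len(ncol(calls))),
             gain_freq = colMeans(calls > gain_threshold),
             loss_freq = colMeans(calls < loss_threshold),
             row.names = NULL, stringsAsFactors = FALSE)
}
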