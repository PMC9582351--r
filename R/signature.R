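#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment: in sort order,
#' `adj_p_(i) = min_{j >= i} min(1, p_(j) * m / j)`, mapped back to the
#' input order. Thin validated wrapper over `stats::p.adjust(..., "BH")`.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    .stopf("p-values must be finite and within [0, 1]")
  p.adjust(p, method = "BH")
}

# Solve trigamma(y) = x by Newton iteration (monotone, convex in 1/y).
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

# Moment-match a scaled inverse-chi-square prior to observed log residual
# variances with equal residual df: returns prior df d0 (possibly Inf) and
# scale s0_sq. Standard empirical-Bayes estimate via digamma/trigamma
# moments of log s^2.
.fit_variance_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2) return(list(d0 = Inf, s0_sq = mean(s2)))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# Posterior (squeezed) variances given prior df/scale.
.squeeze_var <- function(s2, df, d0, s0_sq) {
  if (!is.finite(d0)) return(rep(s0_sq, length(s2)))
  (d0 * s0_sq + df * s2) / (d0 + df)
}

#' Moderated F-test for differential expression across groups
#'
#' Per-gene one-way ANOVA with empirical-Bayes variance moderation:
#' residual variances are shrunk toward a common prior whose df `d0` and
#' scale `s0^2` are moment-matched on the log residual variances
#' (digamma/trigamma equations); the moderated statistic is
#' `F = MS_between / s_tilde^2` on `(k - 1, d_g + d0)` degrees of freedom,
#' with `s_tilde^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`. Raw p-values are
#' BH-adjusted. This is the classical moderated statistic of empirical-
#' Bayes differential expression, computed directly on the group design.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param groups group labels, one per sample (>= 2 groups of >= 2).
#' @return data.frame of class `deg_table`: `gene`, per-group mean columns
#'   (`mean_<level>`), `F_statistic`, `p_value`, `adj_p`, `flagged`
#'   (all-constant genes: F undefined, p = 1). Attributes `d0`, `s0_sq`,
#'   `df_residual`.
#' @export
moderated_f_test <- function(expr, groups) {
  .assert_expression(expr)
  groups <- as.factor(groups)
  if (length(groups) != ncol(expr))
    .stopf("groups (%d) do not match samples (%d)", length(groups), ncol(expr))
  groups <- droplevels(groups)
  k <- nlevels(groups)
  if (k < 2) .stopf("need >= 2 groups")
  ng <- table(groups)
  if (any(ng < 2)) .stopf("every group needs >= 2 samples")
  n <- ncol(expr)
  df_res <- n - k

  means <- vapply(levels(groups),
                  function(g) rowMeans(expr[, groups == g, drop = FALSE]),
                  numeric(nrow(expr)))
  grand <- as.vector(means %*% (as.numeric(ng) / n))
  ssb <- as.vector(((means - grand)^2) %*% as.numeric(ng))
  total_ss <- rowSums((expr - grand)^2)
  rss <- pmax(total_ss - ssb, 0)
  s2 <- rss / df_res
  msb <- ssb / (k - 1)

  prior <- .fit_variance_prior(s2, df_res)
  s2_post <- .squeeze_var(s2, df_res, prior$d0, prior$s0_sq)

  flagged <- s2 <= .Machine$double.eps & ssb <= .Machine$double.eps
  Fstat <- msb / s2_post
  df2 <- if (is.finite(prior$d0)) df_res + prior$d0 else Inf
  pv <- pf(Fstat, k - 1, df2, lower.tail = FALSE)
  Fstat[flagged] <- NA_real_
  pv[flagged] <- 1

  out <- data.frame(gene = rownames(expr), stringsAsFactors = FALSE)
  for (g in levels(groups)) out[[paste0("mean_", g)]] <- means[, g]
  out$F_statistic <- Fstat
  out$p_value <- pv
  out$adj_p <- bh_adjust(pv)
  out$flagged <- flagged
  attr(out, "d0") <- prior$d0
  attr(out, "s0_sq") <- prior$s0_sq
  attr(out, "df_residual") <- df_res
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Univariate Cox screen over genes
#'
#' Fits a proportional-hazards model per gene on continuous expression
#' (Efron ties, Newton-Raphson, via `survival::coxph`) and returns the
#' hazard ratio per log2 unit, 95% Wald CI and Wald p. Constant or
#' non-converging genes are flagged and excluded from the table.
#'
#' @param expr genes x samples matrix.
#' @param clinical data.frame with `sample_id` and the survival columns.
#' @param genes genes to screen (default all rows).
#' @param time_col,event_col survival columns (default overall survival).
#' @return data.frame of class `cox_table`: `gene`, `beta`, `HR`,
#'   `ci_low`, `ci_high`, `p_value`; excluded gene ids in the `flagged`
#'   attribute.
#' @export
univariate_cox_screen <- function(expr, clinical, genes = rownames(expr),
                                  time_col = "os_time", event_col = "os_event") {
  .assert_expression(expr)
  ids <- intersect(colnames(expr), clinical$sample_id)
  if (length(ids) < 3) .stopf("fewer than 3 samples shared with clinical table")
  clin <- clinical[match(ids, clinical$sample_id), ]
  times <- clin[[time_col]]; events <- clin[[event_col]]
  if (is.null(times) || is.null(events))
    .stopf("clinical table lacks %s/%s", time_col, event_col)
  .assert_survival(times, events)
  if (sum(events) == 0) .stopf("no events; Cox screen impossible")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    .stopf("gene(s) absent from expression: %s", paste(head(missing, 3), collapse = ", "))
  surv <- survival::Surv(times, events)
  rows <- vector("list", length(genes))
  flagged <- character(0)
  for (i in seq_along(genes)) {
    x <- expr[genes[i], ids]
    if (sd(x) <= .Machine$double.eps) {
      flagged <- c(flagged, genes[i])
      next
    }
    fit <- tryCatch(
      withCallingHandlers(
        survival::coxph(surv ~ x, ties = "efron"),
        warning = function(w) {
          if (grepl("converge|infinite|beta", conditionMessage(w)))
            invokeRestart("muffleWarning") else invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    ok <- !is.null(fit) && is.finite(coef(fit)) &&
      is.finite(sqrt(diag(fit$var))[1]) && abs(coef(fit)) < 15
    if (!ok) {
      flagged <- c(flagged, genes[i])
      next
    }
    beta <- unname(coef(fit))
    se <- sqrt(fit$var[1, 1])
    rows[[i]] <- data.frame(
      gene = genes[i], beta = beta, HR = exp(beta),
      ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
      p_value = 2 * stats::pnorm(-abs(beta / se)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(gene = character(), beta = numeric(), HR = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "flagged") <- flagged
  class(out) <- c("cox_table", "data.frame")
  out
}

#' Derive the prognostic gene signature
#'
#' Intersection filter: genes differentially expressed across patterns
#' (`adj_p < deg_threshold`) that are also prognostic in the univariate Cox
#' screen (`p < cox_threshold`). Deterministic order: by DEG adjusted p,
#' then symbol.
#'
#' @param deg a [moderated_f_test()] table.
#' @param cox a [univariate_cox_screen()] table.
#' @param deg_threshold,cox_threshold filter thresholds (defaults 0.01,
#'   the published derivation thresholds).
#' @return List of class `gene_signature`: `genes`, `direction` (sign of
#'   the Cox beta per gene), `deg_threshold`, `cox_threshold`.
#' @export
derive_signature <- function(deg, cox, deg_threshold = 0.01,
                             cox_threshold = 0.01) {
  stopifnot(is.data.frame(deg), is.data.frame(cox))
  deg_hits <- deg[deg$adj_p < deg_threshold & !deg$flagged, , drop = FALSE]
  keep <- cox[cox$gene %in% deg_hits$gene & cox$p_value < cox_threshold, ,
              drop = FALSE]
  if (nrow(keep) == 0)
    .stopf("empty signature: no gene passes adj_p < %g and Cox p < %g",
           deg_threshold, cox_threshold)
  ord <- order(deg_hits$adj_p[match(keep$gene, deg_hits$gene)], keep$gene)
  keep <- keep[ord, ]
  structure(list(genes = keep$gene,
                 direction = setNames(sign(keep$beta), keep$gene),
                 deg_threshold = deg_threshold,
                 cox_threshold = cox_threshold),
            class = "gene_signature")
}
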