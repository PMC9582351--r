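#' Fit the DNA methylation score (DMS) model
#'
#' Principal component analysis on the signature-gene expression (samples x
#' genes, each gene centered and by default unit-variance scaled). The DMS
#' of a sample is the sum of its first and second principal-component
#' projections. Each component's sign is oriented so that its sample scores
#' carry a positive univariate Cox log hazard ratio for overall survival —
#' high DMS means worse prognosis, which is otherwise unidentifiable from
#' the PCA alone.
#'
#' @param expr genes x samples matrix containing the signature genes.
#' @param clinical data.frame with `sample_id`, `os_time`, `os_event`
#'   (needed for orientation).
#' @param signature a [derive_signature()] object or character vector of
#'   gene ids.
#' @param scale. scale genes to unit variance before PCA (default TRUE).
#' @param orient orient PC signs by Cox log-HR positivity (default TRUE).
#' @return List of class `dms_model`: `genes`, `center`, `scale`, `v1`,
#'   `v2` (unit, orthogonal loadings), `scaled`, `cutpoint` (NULL until
#'   [optimal_cutpoint()] is run), plus the training `scores`.
#' @export
fit_dms <- function(expr, clinical, signature, scale. = TRUE, orient = TRUE) {
  .assert_expression(expr)
  genes <- if (inherits(signature, "gene_signature")) signature$genes else signature
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    .stopf("signature gene(s) missing from expression: %s",
           paste(head(missing, 5), collapse = ", "))
  if (ncol(expr) < 3) .stopf("need >= 3 samples")
  X <- t(expr[genes, , drop = FALSE])
  sds <- apply(X, 2, sd)
  drop <- sds <= .Machine$double.eps
  if (any(drop)) {
    .warnf("dropping %d zero-variance signature gene(s)", sum(drop))
    X <- X[, !drop, drop = FALSE]
    genes <- genes[!drop]
  }
  if (length(genes) < 2) .stopf("fewer than 2 usable signature genes")
  center <- colMeans(X)
  scl <- if (scale.) apply(X, 2, sd) else rep(1, ncol(X))
  Xs <- sweep(sweep(X, 2, center), 2, scl, "/")
  sv <- svd(Xs, nu = 0, nv = 2)
  v1 <- sv$v[, 1]; v2 <- sv$v[, 2]
  s1 <- drop(Xs %*% v1); s2 <- drop(Xs %*% v2)
  signs <- c(1, 1)
  if (orient) {
    ids <- intersect(rownames(X), clinical$sample_id)
    if (length(ids) < 3 || sum(clinical$os_event[match(ids, clinical$sample_id)]) < 1)
      .stopf("orientation requires overall survival with >= 1 event")
    clin <- clinical[match(ids, clinical$sample_id), ]
    surv <- survival::Surv(clin$os_time, clin$os_event)
    for (j in 1:2) {
      sc <- (if (j == 1) s1 else s2)[match(ids, rownames(X))]
      b <- tryCatch(unname(coef(survival::coxph(surv ~ sc, ties = "efron"))),
                    error = function(e) 0)
      if (is.finite(b) && b < 0) signs[j] <- -1
    }
    v1 <- v1 * signs[1]; s1 <- s1 * signs[1]
    v2 <- v2 * signs[2]; s2 <- s2 * signs[2]
  }
  names(v1) <- names(v2) <- genes
  structure(list(genes = genes, center = center, scale = scl,
                 v1 = v1, v2 = v2, signs = signs, scaled = scale.,
                 cutpoint = NULL, minprop = NULL,
                 scores = setNames(s1 + s2, rownames(X))),
            class = "dms_model")
}

#' Score samples with a fitted DMS model
#'
#' Frozen-model scoring: applies the training centering means, scaling SDs
#' and loadings to a (possibly new) cohort. `DMS = x' v1 + x' v2` per
#' sample over the signature genes.
#'
#' @param model a [fit_dms()] model.
#' @param expr genes x samples matrix containing all model genes.
#' @return Named numeric vector of scores (one per sample).
#' @export
score_dms <- function(model, expr) {
  stopifnot(inherits(model, "dms_model"))
  .assert_expression(expr)
  missing <- setdiff(model$genes, rownames(expr))
  if (length(missing))
    .stopf("model gene(s) missing from expression: %s",
           paste(missing, collapse = ", "))
  X <- t(expr[model$genes, , drop = FALSE])
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  setNames(drop(Xs %*% model$v1) + drop(Xs %*% model$v2), colnames(expr))
}

# Standardized log-rank statistic for a binary split. Returns
# (O1 - E1) / sqrt(V1) computed over pooled event times.
.logrank_z <- function(times, events, high) {
  ord <- order(times)
  t <- times[ord]; e <- events[ord]; g <- high[ord]
  ut <- unique(t[e == 1])
  n <- length(t)
  o1 <- e1 <- v <- 0
  for (tt in ut) {
    at_risk <- t >= tt
    N <- sum(at_risk)
    N1 <- sum(at_risk & g)
    d <- sum(t == tt & e == 1)
    d1 <- sum(t == tt & e == 1 & g)
    o1 <- o1 + d1
    e1 <- e1 + d * N1 / N
    if (N > 1) v <- v + d * (N1 / N) * (1 - N1 / N) * (N - d) / (N - 1)
  }
  if (v <= 0) return(0)
  (o1 - e1) / sqrt(v)
}

#' Optimal survival cutpoint by maximally selected rank statistics
#'
#' Enumerates every admissible threshold on the score — those with a low-
#' group proportion in `[minprop, 1 - minprop)` — and returns the one
#' maximizing the absolute standardized log-rank statistic of the high-vs-
#' low split. The maximally selected statistic is kept for reference but is
#' NOT a calibrated test statistic: selection inflates it, so downstream
#' log-rank tests on the chosen split are exploratory.
#'
#' @param scores named numeric vector (e.g. from [score_dms()]).
#' @param clinical data.frame with `sample_id` and survival columns.
#' @param minprop minimum group proportion, in (0, 0.5).
#' @param time_col,event_col survival columns.
#' @return List of class `dms_cutpoint`: `cutpoint`, `statistic` (the
#'   maximal |Z|), `groups` (factor low/high named by sample), and the
#'   `candidates` data.frame of all evaluated splits.
#' @export
optimal_cutpoint <- function(scores, clinical, minprop = 0.1,
                             time_col = "os_time", event_col = "os_event") {
  if (minprop <= 0 || minprop >= 0.5) .stopf("minprop must be in (0, 0.5)")
  ids <- intersect(names(scores), clinical$sample_id)
  if (length(ids) < 4) .stopf("need >= 4 scored samples with clinical data")
  s <- scores[ids]
  if (any(!is.finite(s))) .stopf("non-finite scores")
  clin <- clinical[match(ids, clinical$sample_id), ]
  times <- clin[[time_col]]; events <- clin[[event_col]]
  .assert_survival(times, events)
  if (sum(events) < 2) .stopf("need >= 2 events")
  n <- length(s)
  sorted <- sort(unname(s))
  if (sorted[1] == sorted[n]) .stopf("all scores tied; no cutpoint exists")
  lo <- ceiling(minprop * n)
  hi <- ceiling((1 - minprop) * n) - 1L
  idx <- seq.int(lo, hi)
  idx <- idx[sorted[idx] < sorted[idx + 1L]]  # skip ties (same split)
  if (length(idx) < 2) .stopf("fewer than 2 admissible cutpoints under minprop")
  cand <- (sorted[idx] + sorted[idx + 1L]) / 2
  z <- vapply(cand, function(c) .logrank_z(times, events, s > c), numeric(1))
  best <- which.max(abs(z))
  cutpoint <- cand[best]
  groups <- factor(ifelse(s > cutpoint, "high", "low"),
                   levels = c("low", "high"))
  names(groups) <- ids
  structure(list(cutpoint = cutpoint, statistic = abs(z[best]),
                 groups = groups,
                 candidates = data.frame(cutpoint = cand, z = z),
                 minprop = minprop),
            class = "dms_cutpoint")
}

#' Serialize a DMS model to JSON
#'
#' @param model a [fit_dms()] model (optionally with a cutpoint attached).
#' @param path output path.
#' @export
write_dms_model <- function(model, path) {
  stopifnot(inherits(model, "dms_model"))
  payload <- list(genes = model$genes, center = unname(model$center),
                  scale = unname(model$scale), v1 = unname(model$v1),
                  v2 = unname(model$v2), signs = model$signs,
                  scaled = model$scaled, cutpoint = model$cutpoint,
                  minprop = model$minprop)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a DMS model from JSON
#'
#' @param path path written by [write_dms_model()].
#' @return A `dms_model`.
#' @export
read_dms_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(genes = p$genes,
                center = setNames(p$center, p$genes),
                scale = setNames(p$scale, p$genes),
                v1 = setNames(p$v1, p$genes), v2 = setNames(p$v2, p$genes),
                signs = p$signs, scaled = p$scaled,
                cutpoint = p$cutpoint, minprop = p$minprop, scores = NULL)
  class(model) <- "dms_model"
  model
}
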