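#' @keywords internal
"_PACKAGE"

#' @importFrom stats cutree hclust as.dist cophenetic cor rexp rnorm runif
#'   rbinom rpois pf pchisq var sd median quantile prcomp plogis p.adjust
#'   complete.cases setNames aggregate chisq.test fisher.test kruskal.test
#'   wilcox.test cor.test qnorm digamma trigamma psigamma coef
#' @importFrom utils read.delim write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.assert_expression <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    .stopf("%s must be a numeric matrix", what)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    .stopf("%s must carry gene row names and sample column names", what)
  if (anyDuplicated(rownames(x)))
    .stopf("%s has duplicated gene ids", what)
  if (anyDuplicated(colnames(x)))
    .stopf("%s has duplicated sample ids", what)
  if (any(!is.finite(x)))
    .stopf("%s contains non-finite values", what)
  invisible(x)
}

.assert_survival <- function(times, events) {
  if (any(!is.finite(times)) || any(times < 0))
    .stopf("survival times must be finite and >= 0")
  if (!all(events %in% c(0, 1)))
    .stopf("event indicators must be 0/1")
  invisible(NULL)
}

# Run code under a local RNG state so generators are reproducible without
# clobbering the caller's stream.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

# Deterministic per-stage seed fan-out from one root seed (kept < 2^31).
.derive_seed <- function(seed, stage, extra = 0L) {
  (as.double(seed) * 2654435761 + stage * 97003 + extra * 613) %% 2147483629
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same samples,
#' used throughout to compare recovered cluster labels with planted truth.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A number in [-1, 1]; 1 means identical partitions up to renaming.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) .stopf("label vectors differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# md5 of an arbitrary R object via its serialization (manifest hashing).
.object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
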