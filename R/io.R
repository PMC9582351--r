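#' Read an expression matrix from TSV or GCT
#'
#' Expression is assumed already log2-transformed/normalized (microarray
#' series matrices or log2 FPKM). Duplicate gene symbols are collapsed by
#' keeping the row with the highest mean expression, the common microarray
#' probe-collapse convention.
#'
#' @param path file path.
#' @param dialect `"tsv"` (first column = gene id, header = sample ids) or
#'   `"gct"` (`#1.2` header, dimensions line, `Name`/`Description` columns).
#' @return Numeric matrix, genes x samples, with unique row/column names.
#' @export
read_expression <- function(path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (dialect == "gct") {
    header <- readLines(path, n = 2)
    if (!grepl("^#1\\.2", header[1]))
      .stopf("not a GCT file (missing #1.2 header): %s", path)
    df <- read.delim(path, skip = 2, check.names = FALSE,
                     stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    df <- df[, -c(1, 2), drop = FALSE]  # drop Name, Description
  } else {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  if (nrow(df) == 0 || ncol(df) == 0)
    .stopf("empty expression matrix in %s", path)
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))[1]
      if (!is.na(bad))
        .stopf("non-numeric value %s at gene '%s', sample '%s'",
               deparse(col[bad]), genes[bad], colnames(df)[j])
      df[[j]] <- num
    }
  }
  values <- as.matrix(df)
  rownames(values) <- genes
  .collapse_duplicate_genes(values)
}

.collapse_duplicate_genes <- function(values) {
  if (anyDuplicated(rownames(values))) {
    means <- rowMeans(values)
    keep <- tapply(seq_len(nrow(values)), rownames(values),
                   function(i) i[which.max(means[i])])
    values <- values[sort(unlist(keep)), , drop = FALSE]
  }
  .assert_expression(values)
  values
}

#' Write an expression matrix as TSV
#'
#' @param expr genes x samples numeric matrix.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  .assert_expression(expr)
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Each GMT line is `name<TAB>description<TAB>gene1<TAB>gene2...`. The
#' description is dropped and duplicate genes within a set deduplicated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors with a `provenance` attribute.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      .stopf("GMT line %d has %d field(s); need name, description, genes",
             i, length(fields))
    genes <- unique(fields[-c(1, 2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0)
      .stopf("GMT line %d ('%s') lists no genes", i, fields[1])
    if (fields[1] %in% names(sets))
      .stopf("duplicated gene-set name '%s' (line %d)", fields[1], i)
    sets[[fields[1]]] <- genes
  }
  attr(sets, "provenance") <- path
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description single description string recycled per set.
#' @export
write_gene_sets <- function(sets, path, description = "na") {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    .stopf("gene sets must be named")
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, unique(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' Requires a `sample_id` column; validates survival columns when present
#' (times >= 0, events in 0/1, unique sample ids).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) .stopf("clinical table lacks sample_id")
  if (anyDuplicated(df$sample_id)) .stopf("duplicated sample_id in clinical table")
  for (pref in c("os", "rfs")) {
    tc <- paste0(pref, "_time"); ec <- paste0(pref, "_event")
    if (tc %in% names(df) && ec %in% names(df)) {
      ok <- !is.na(df[[tc]]) & !is.na(df[[ec]])
      .assert_survival(df[[tc]][ok], df[[ec]][ok])
    }
  }
  df
}

#' Read a MAF-like mutation table from TSV
#'
#' @param path TSV with at least Hugo_Symbol, Tumor_Sample_Barcode,
#'   Variant_Classification columns.
#' @return data.frame of single calls.
#' @export
read_mutations <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification")
  missing <- setdiff(need, names(df))
  if (length(missing))
    .stopf("mutation table lacks column(s): %s", paste(missing, collapse = ", "))
  df
}

#' Merge expression cohorts on shared genes
#'
#' Restricts every cohort to the intersection of gene sets (in the first
#' cohort's row order) and concatenates samples, recording the source
#' cohort of each sample as its batch label — the construction of a
#' meta-cohort from multiple series profiled on the same platform.
#'
#' @param cohorts list of >= 2 expression matrices with disjoint sample ids.
#' @return list with `expression` (merged matrix) and `batch` (factor of
#'   source cohort index per sample).
#' @export
merge_cohorts <- function(cohorts) {
  if (!is.list(cohorts) || length(cohorts) < 2)
    .stopf("need a list of >= 2 cohorts")
  for (x in cohorts) .assert_expression(x)
  ids <- unlist(lapply(cohorts, colnames))
  if (anyDuplicated(ids))
    .stopf("duplicate sample id(s) across cohorts: %s",
           paste(unique(ids[duplicated(ids)])[1:min(3, sum(duplicated(ids)))],
                 collapse = ", "))
  genes <- Reduce(intersect, lapply(cohorts, rownames))
  if (length(genes) == 0) .stopf("empty gene intersection across cohorts")
  genes <- rownames(cohorts[[1]])[rownames(cohorts[[1]]) %in% genes]
  merged <- do.call(cbind, lapply(cohorts, function(x) x[genes, , drop = FALSE]))
  batch <- factor(rep(seq_along(cohorts),
                      times = vapply(cohorts, ncol, integer(1))))
  names(batch) <- colnames(merged)
  list(expression = merged, batch = batch)
}

#' Remove additive batch effects with ComBat
#'
#' Empirical-Bayes location/scale batch adjustment (parametric priors,
#' intercept-only model), delegated to `sva::ComBat`. Genes with zero
#' variance across all samples have no defined scale and are passed through
#' unadjusted; their ids are attached as the `unadjusted_genes` attribute.
#'
#' @param expr genes x samples matrix.
#' @param batch batch labels, one per sample (>= 2 batches, each >= 2
#'   samples).
#' @return Adjusted matrix of identical dimensions.
#' @export
combat_adjust <- function(expr, batch) {
  .assert_expression(expr)
  batch <- as.factor(batch)
  if (length(batch) != ncol(expr))
    .stopf("batch labels (%d) do not match samples (%d)", length(batch), ncol(expr))
  if (nlevels(batch) < 2) .stopf("need >= 2 batches")
  if (any(table(batch) < 2)) .stopf("every batch needs >= 2 samples")
  v <- apply(expr, 1, var)
  flat <- v <= .Machine$double.eps
  out <- expr
  if (all(flat)) .stopf("all genes have zero variance")
  adj <- suppressMessages(
    sva::ComBat(dat = expr[!flat, , drop = FALSE], batch = batch,
                mod = NULL, par.prior = TRUE, prior.plots = FALSE)
  )
  out[!flat, ] <- adj
  if (any(flat))
    message(sum(flat), " zero-variance gene(s) passed through unadjusted")
  attr(out, "unadjusted_genes") <- rownames(expr)[flat]
  out
}
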