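#' Cramér's V association between two categorical labelings
#'
#' @param a,b equal-length label vectors.
#' @return V in [0, 1].
#' @export
cramers_v <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  chi <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
  sqrt(unname(chi) / (n * (min(dim(tab)) - 1)))
}

#' Pipeline configuration
#'
#' Collects every input and tuning knob of the end-to-end analysis. Either
#' provide file paths (expression cohorts as TSV, clinical TSV, gene sets
#' GMT, mutations MAF-like TSV) or a [synthetic_config()] to run on a
#' generated cohort.
#'
#' @param expression_paths character vector of >= 2 cohort TSV paths.
#' @param clinical_path clinical TSV path.
#' @param gene_sets_path optional GMT path.
#' @param mutations_path optional MAF-like TSV path.
#' @param synthetic optional [synthetic_config()]; replaces the paths.
#' @param regulators regulator gene symbols (default the 24-gene panel).
#' @param k_range candidate NMF ranks.
#' @param n_runs NMF restarts per rank.
#' @param k_fixed optional fixed rank (skips rank selection).
#' @param deg_threshold,cox_threshold signature derivation thresholds in
#'   (0, 1].
#' @param dms_scale unit-variance scale genes before PCA.
#' @param minprop minimum group proportion for the survival cutpoint.
#' @param auc_horizons horizons (months) for time-dependent AUC.
#' @param seed root seed; per-stage seeds are derived deterministically.
#' @param output_dir optional directory for all intermediate tables.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(expression_paths = NULL, clinical_path = NULL,
                            gene_sets_path = NULL, mutations_path = NULL,
                            synthetic = NULL,
                            regulators = regulator_set()$symbol,
                            k_range = 2:5, n_runs = 30, k_fixed = NULL,
                            deg_threshold = 0.01, cox_threshold = 0.01,
                            dms_scale = TRUE, minprop = 0.1,
                            auc_horizons = c(12, 36, 60),
                            seed = 1, output_dir = NULL) {
  if (is.null(synthetic)) {
    if (is.null(expression_paths) || length(expression_paths) < 2 ||
        is.null(clinical_path))
      .stopf("provide >= 2 expression_paths and clinical_path, or synthetic")
    for (p in c(expression_paths, clinical_path, gene_sets_path,
                mutations_path)) {
      if (!is.null(p) && !file.exists(p)) .stopf("input not found: %s", p)
    }
  } else if (!inherits(synthetic, "synthetic_config")) {
    .stopf("synthetic must be a synthetic_config")
  }
  for (thr in c(deg_threshold, cox_threshold))
    if (thr <= 0 || thr > 1) .stopf("thresholds must lie in (0, 1]")
  structure(list(expression_paths = expression_paths,
                 clinical_path = clinical_path,
                 gene_sets_path = gene_sets_path,
                 mutations_path = mutations_path,
                 synthetic = synthetic, regulators = regulators,
                 k_range = k_range, n_runs = n_runs, k_fixed = k_fixed,
                 deg_threshold = deg_threshold,
                 cox_threshold = cox_threshold, dms_scale = dms_scale,
                 minprop = minprop, auc_horizons = auc_horizons,
                 seed = seed, output_dir = output_dir),
            class = "pipeline_config")
}

.stage <- function(name) message("[methpattern] stage: ", name)

#' Run the end-to-end analysis
#'
#' Executes the full workflow: merge cohorts, ComBat batch adjustment,
#' consensus NMF on the regulator sub-matrix with cophenetic rank
#' selection, moderated-F differential expression across patterns,
#' univariate Cox screening, a second consensus NMF on the signature genes
#' (the gene clusters), DMS fitting/scoring and survival cutpoint,
#' single-sample enrichment of any provided gene sets, survival and
#' mutation summaries, and a reproducibility manifest.
#'
#' @param config a [pipeline_config()].
#' @return List of class `report_bundle` with elements `patterns`,
#'   `consensus`, `selected_k`, `deg`, `cox_screen`, `signature`,
#'   `gene_clusters`, `dms_model`, `scores`, `cutpoint`, `enrichment`,
#'   `survival`, `mutation`, `truth` (synthetic runs only), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  truth <- NULL

  .stage("inputs")
  if (!is.null(cfg$synthetic)) {
    batches <- generate_batched_cohorts(cfg$synthetic)
    exprs <- lapply(batches$cohorts, `[[`, "expression")
    clinical <- do.call(rbind, lapply(batches$cohorts, `[[`, "clinical"))
    mutations <- do.call(rbind, lapply(batches$cohorts, `[[`, "mutations"))
    gene_sets <- batches$cohorts[[1]]$gene_sets
    truth <- batches$truth
  } else {
    exprs <- lapply(cfg$expression_paths, read_expression)
    clinical <- read_clinical(cfg$clinical_path)
    mutations <- if (!is.null(cfg$mutations_path))
      read_mutations(cfg$mutations_path) else NULL
    gene_sets <- if (!is.null(cfg$gene_sets_path))
      read_gene_sets(cfg$gene_sets_path) else list()
  }

  .stage("merge + batch adjustment")
  merged <- merge_cohorts(exprs)
  adjusted <- combat_adjust(merged$expression, merged$batch)

  .stage("pattern discovery (consensus NMF on regulators)")
  reg <- intersect(cfg$regulators, rownames(adjusted))
  if (length(reg) < 4) .stopf("fewer than 4 regulator genes present")
  sub <- remove_gene_baseline(adjusted[reg, , drop = FALSE])
  consensus <- consensus_cluster(sub, k_range = cfg$k_range,
                                 n_runs = cfg$n_runs,
                                 seed = .derive_seed(cfg$seed, 10L))
  k <- cfg$k_fixed %||% select_rank(consensus)
  patterns <- assign_patterns(consensus, k = k)
  pat <- patterns$pattern[match(colnames(adjusted), patterns$sample_id)]

  .stage("differential expression + Cox screen")
  deg <- moderated_f_test(adjusted, pat)
  deg_hits <- deg$gene[deg$adj_p < cfg$deg_threshold & !deg$flagged]
  cox_screen <- univariate_cox_screen(adjusted, clinical, genes = deg_hits)
  signature <- derive_signature(deg, cox_screen,
                                deg_threshold = cfg$deg_threshold,
                                cox_threshold = cfg$cox_threshold)

  .stage("gene clusters (second consensus NMF on signature genes)")
  sub2 <- remove_gene_baseline(adjusted[signature$genes, , drop = FALSE])
  consensus2 <- consensus_cluster(sub2, k_range = cfg$k_range,
                                  n_runs = cfg$n_runs,
                                  seed = .derive_seed(cfg$seed, 11L))
  k2 <- cfg$k_fixed %||% select_rank(consensus2)
  gene_clusters <- assign_patterns(consensus2, k = k2)

  .stage("DMS")
  dms_model <- fit_dms(adjusted, clinical, signature, scale. = cfg$dms_scale)
  scores <- dms_model$scores
  cutpoint <- optimal_cutpoint(scores, clinical, minprop = cfg$minprop)
  dms_model$cutpoint <- cutpoint$cutpoint
  dms_model$minprop <- cfg$minprop

  .stage("enrichment")
  enrichment <- NULL
  if (length(gene_sets) > 0) {
    score_mat <- ssgsea_scores(adjusted, gene_sets)
    by_pattern <- enrichment_group_test(score_mat, pat)
    est <- NULL
    if (all(c("StromalSignature", "ImmuneSignature") %in% names(gene_sets)))
      est <- estimate_scores(adjusted, gene_sets$StromalSignature,
                             gene_sets$ImmuneSignature)
    enrichment <- list(scores = score_mat, by_pattern = by_pattern,
                       estimate = est)
  }

  .stage("survival statistics")
  ids <- colnames(adjusted)
  clin <- clinical[match(ids, clinical$sample_id), ]
  dms_group <- cutpoint$groups[ids]
  survres <- list(
    km_by_dms = lapply(split(seq_along(ids), dms_group), function(i)
      km_estimate(clin$os_time[i], clin$os_event[i])),
    logrank_pattern = logrank_test(clin$os_time, clin$os_event, pat),
    logrank_gene_cluster = logrank_test(
      clin$os_time, clin$os_event,
      gene_clusters$pattern[match(ids, gene_clusters$sample_id)]),
    logrank_dms = logrank_test(clin$os_time, clin$os_event, dms_group),
    cox_dms = cox_fit(data.frame(DMS = as.numeric(scale(scores[ids]))),
                      clin$os_time, clin$os_event),
    cox_multivariate = cox_fit(
      data.frame(DMS = as.numeric(scale(scores[ids])), stage = clin$stage),
      clin$os_time, clin$os_event),
    auc = vapply(cfg$auc_horizons, function(h) {
      tryCatch(time_dependent_auc(scores[ids], clin$os_time, clin$os_event, h),
               error = function(e) NA_real_)
    }, numeric(1))
  )
  names(survres$auc) <- paste0("t", cfg$auc_horizons)

  .stage("mutation summaries")
  mutation <- NULL
  if (!is.null(mutations) && nrow(mutations) > 0) {
    mutation <- mutation_summaries(mutations, samples = ids,
                                   genes = reg)
    tmb <- mutation$tmb$tmb[match(ids, mutation$tmb$sample_id)]
    mutation$tmb_vs_dms <- if (sd(tmb) > 0)
      spearman_corr(tmb, scores[ids]) else NULL
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("methpattern")),
    seed = cfg$seed, selected_k = k, gene_cluster_k = k2,
    n_samples = ncol(adjusted), n_genes = nrow(adjusted),
    input_hash = .object_hash(exprs),
    expression_hash = .object_hash(adjusted),
    labels_hash = .object_hash(list(patterns, gene_clusters, dms_group)),
    signature_hash = .object_hash(signature$genes)
  )

  bundle <- structure(list(
    patterns = patterns, consensus = consensus, selected_k = k,
    deg = deg, cox_screen = cox_screen, signature = signature,
    gene_clusters = gene_clusters, dms_model = dms_model,
    scores = scores, cutpoint = cutpoint, enrichment = enrichment,
    survival = survres, mutation = mutation, truth = truth,
    clinical = clinical, expression = adjusted, pattern_labels = pat,
    manifest = manifest
  ), class = "report_bundle")

  if (!is.null(cfg$output_dir)) .write_bundle(bundle, cfg$output_dir)
  bundle
}

.write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(bundle$patterns, "patterns.tsv")
  wt(bundle$gene_clusters, "gene_clusters.tsv")
  wt(as.data.frame(bundle$deg), "deg_table.tsv")
  wt(as.data.frame(bundle$cox_screen), "cox_screen.tsv")
  writeLines(bundle$signature$genes, file.path(dir, "signature_genes.txt"))
  wt(data.frame(sample_id = names(bundle$scores), DMS = bundle$scores,
                group = as.character(bundle$cutpoint$groups[names(bundle$scores)])),
     "dms_scores.tsv")
  write_dms_model(bundle$dms_model, file.path(dir, "dms_model.json"))
  if (!is.null(bundle$enrichment)) {
    wt(data.frame(gene_set = rownames(bundle$enrichment$scores),
                  bundle$enrichment$scores, check.names = FALSE),
       "enrichment_scores.tsv")
    wt(bundle$enrichment$by_pattern, "enrichment_by_pattern.tsv")
  }
  if (!is.null(bundle$mutation)) {
    wt(bundle$mutation$frequency, "mutation_frequency.tsv")
    wt(bundle$mutation$tmb, "tmb.tsv")
    if (!is.null(bundle$mutation$cooccurrence))
      wt(bundle$mutation$cooccurrence, "mutation_cooccurrence.tsv")
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
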