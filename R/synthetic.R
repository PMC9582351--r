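#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated colon-cancer-like
#' expression cohort: `k_patterns` latent modification patterns driven by
#' mean shifts in disjoint regulator-gene blocks, a block of planted
#' differentially expressed genes (the signature truth), pattern-dependent
#' exponential survival with independent censoring, additive per-cohort
#' batch offsets, immune/stromal signature co-expression correlated with
#' pattern, and pattern-dependent Poisson mutation counts.
#'
#' Defaults describe the reference simulation used throughout the test
#' suite: 600 samples, 2,000 genes, 24 regulators split into three blocks of
#' eight, pattern proportions matching the published meta-cohort pattern
#' sizes (306/227/221 of 754), a one log2-unit pattern effect over residual
#' noise SD 0.5, and a clearly favorable hazard for the immune-inflamed
#' second pattern.
#'
#' @param n_samples number of samples.
#' @param n_genes number of genes (>= n_regulators + n_sig_genes).
#' @param n_regulators size of the regulator panel placed at the top rows;
#'   24 uses the real regulator symbols.
#' @param k_patterns number of latent patterns.
#' @param pattern_props simplex weights of the patterns (sums to 1).
#' @param effect_size mean log2 shift of a pattern-defining gene in its
#'   pattern.
#' @param noise_sd residual log2 SD.
#' @param n_batches number of cohorts for [generate_batched_cohorts()].
#' @param batch_shift_sd SD of the per-gene additive batch offsets.
#' @param surv_hazards per-pattern exponential hazard rates (events/month).
#' @param censor_rate hazard of the independent exponential censoring.
#' @param n_sig_genes number of planted pattern-tracking (DEG-truth) genes.
#' @param mut_rates per-pattern mean somatic mutation count.
#' @param seed integer RNG seed.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 600, n_genes = 2000,
                             n_regulators = 24, k_patterns = 3,
                             pattern_props = c(306, 227, 221) / 754,
                             effect_size = 1.0, noise_sd = 0.5,
                             n_batches = 3, batch_shift_sd = 1.0,
                             surv_hazards = c(0.060, 0.010, 0.110),
                             censor_rate = 0.015, n_sig_genes = 150,
                             mut_rates = c(10, 30, 8), seed = 1) {
  cfg <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
              n_regulators = as.integer(n_regulators),
              k_patterns = as.integer(k_patterns),
              pattern_props = as.numeric(pattern_props),
              effect_size = effect_size, noise_sd = noise_sd,
              n_batches = as.integer(n_batches),
              batch_shift_sd = batch_shift_sd,
              surv_hazards = as.numeric(surv_hazards),
              censor_rate = censor_rate,
              n_sig_genes = as.integer(n_sig_genes),
              mut_rates = as.numeric(mut_rates), seed = as.integer(seed))
  k <- cfg$k_patterns
  if (length(cfg$pattern_props) != k)
    .stopf("pattern_props must have k_patterns = %d entries", k)
  if (abs(sum(cfg$pattern_props) - 1) > 1e-12)
    .stopf("pattern_props must sum to 1 (got %.15g)", sum(cfg$pattern_props))
  if (any(cfg$pattern_props < 0))
    .stopf("pattern_props must be nonnegative")
  if (length(cfg$surv_hazards) != k || any(cfg$surv_hazards <= 0))
    .stopf("surv_hazards must be %d positive rates", k)
  if (cfg$censor_rate <= 0) .stopf("censor_rate must be > 0")
  if (length(cfg$mut_rates) != k || any(cfg$mut_rates < 0))
    .stopf("mut_rates must be %d nonnegative means", k)
  if (cfg$n_sig_genes > cfg$n_genes)
    .stopf("n_sig_genes (%d) exceeds n_genes (%d)", cfg$n_sig_genes, cfg$n_genes)
  if (cfg$n_regulators + cfg$n_sig_genes > cfg$n_genes)
    .stopf("n_genes too small for disjoint regulator and signal blocks")
  if (cfg$noise_sd < 0 || cfg$effect_size < 0)
    .stopf("effect_size and noise_sd must be >= 0")
  class(cfg) <- "synthetic_config"
  cfg
}

.variant_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Del",
    "Frame_Shift_Ins", "Splice_Site", "In_Frame_Del", "Silent")
}

# Split idx into k contiguous blocks of near-equal size.
.even_blocks <- function(idx, k) {
  sizes <- rep(length(idx) %/% k, k)
  extra <- length(idx) %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  split(idx, rep(seq_len(k), times = sizes))
}

# Layout of planted gene-set signature blocks after regulators and signal
# genes; returns list(name -> gene row indices, affinity -> pattern index or
# 0) or NULL when n_genes leaves no room.
.signature_layout <- function(cfg, first_row) {
  cell_types <- tme_cell_types()
  procs <- process_signature_names()
  sizes <- c(rep(8L, length(cell_types)), 12L, 12L, rep(6L, length(procs)))
  names(sizes) <- c(cell_types, "StromalSignature", "ImmuneSignature", procs)
  if (first_row + sum(sizes) - 1L > cfg$n_genes) return(NULL)
  ends <- first_row - 1L + cumsum(sizes)
  starts <- ends - sizes + 1L
  rows <- mapply(function(s, e) s:e, starts, ends, SIMPLIFY = FALSE)
  k <- cfg$k_patterns
  aff <- integer(length(sizes))
  names(aff) <- names(sizes)
  aff[.adaptive_cell_types()] <- min(2L, k)
  aff[.innate_cell_types()] <- 1L
  aff[setdiff(cell_types, c(.adaptive_cell_types(), .innate_cell_types()))] <- 0L
  aff["StromalSignature"] <- 1L
  aff["ImmuneSignature"] <- min(2L, k)
  stromal_like <- c("Pan-F-TBRS", "EMT1", "EMT2", "EMT3", "WNT targets",
                    "FGFR3 related")
  aff[procs] <- ifelse(procs %in% stromal_like, 1L, min(2L, k))
  list(rows = rows, affinity = aff)
}

#' Generate one synthetic cohort
#'
#' Draws a cohort with the structure described in [synthetic_config()]:
#' `expression = baseline + pattern shifts + signature co-expression +
#' N(0, noise_sd)` on log2 scale, exponential pattern-dependent survival
#' with independent exponential censoring, and per-sample Poisson mutation
#' counts. Fully reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return A list of class `synthetic_cohort` with elements `expression`
#'   (genes x samples matrix), `clinical` (data.frame), `mutations`
#'   (MAF-like data.frame), `gene_sets` (planted signature blocks, a named
#'   list of gene vectors; empty if `n_genes` leaves no room), `truth`
#'   (planted pattern labels, DEG gene list, per-gene log-hazard betas,
#'   prognostic score), and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  cfg <- config
  .with_seed(cfg$seed, {
    n <- cfg$n_samples; m <- cfg$n_genes; k <- cfg$k_patterns
    nreg <- cfg$n_regulators
    sample_ids <- sprintf("S%04d", seq_len(n))
    gene_ids <- sprintf("G%06d", seq_len(m))
    if (nreg == 24L) {
      gene_ids[seq_len(24)] <- regulator_set()$symbol
    } else {
      gene_ids[seq_len(nreg)] <- sprintf("REG%03d", seq_len(nreg))
    }

    pattern <- sample.int(k, n, replace = TRUE, prob = cfg$pattern_props)
    names(pattern) <- sample_ids

    baseline <- runif(m, 4, 9)
    expr <- matrix(rnorm(m * n, sd = cfg$noise_sd), m, n,
                   dimnames = list(gene_ids, sample_ids)) + baseline

    reg_blocks <- .even_blocks(seq_len(nreg), k)
    sig_rows <- nreg + seq_len(cfg$n_sig_genes)
    sig_blocks <- .even_blocks(sig_rows, k)
    for (p in seq_len(k)) {
      cols <- pattern == p
      if (!any(cols)) next
      expr[reg_blocks[[p]], cols] <- expr[reg_blocks[[p]], cols] + cfg$effect_size
      expr[sig_blocks[[p]], cols] <- expr[sig_blocks[[p]], cols] + cfg$effect_size
    }

    layout <- .signature_layout(cfg, first_row = nreg + cfg$n_sig_genes + 1L)
    gene_sets <- list()
    affine_rows <- integer(0)
    if (!is.null(layout)) {
      for (nm in names(layout$rows)) {
        rows <- layout$rows[[nm]]
        p <- layout$affinity[[nm]]
        activity <- rnorm(n, sd = 0.3)
        if (p > 0) {
          activity <- activity + cfg$effect_size * (pattern == p)
          affine_rows <- c(affine_rows, rows)
        }
        expr[rows, ] <- expr[rows, ] + rep(activity, each = length(rows))
        gene_sets[[nm]] <- gene_ids[rows]
      }
      attr(gene_sets, "provenance") <- "synthetic planted signature blocks"
    }

    log_h <- log(cfg$surv_hazards)
    prognostic <- log_h[pattern] - mean(log_h)
    names(prognostic) <- sample_ids

    t_event <- rexp(n, rate = cfg$surv_hazards[pattern])
    t_cens <- rexp(n, rate = cfg$censor_rate)
    os_time <- pmin(t_event, t_cens)
    os_event <- as.integer(t_event <= t_cens)
    r_event <- rexp(n, rate = 1.3 * cfg$surv_hazards[pattern])
    r_cens <- rexp(n, rate = cfg$censor_rate)
    clinical <- data.frame(
      sample_id = sample_ids,
      os_time = os_time, os_event = os_event,
      rfs_time = pmin(r_event, r_cens),
      rfs_event = as.integer(r_event <= r_cens),
      stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                     prob = c(0.15, 0.3, 0.35, 0.2)),
      msi = ifelse(rbinom(n, 1, ifelse(pattern == min(2L, k), 0.25, 0.10)) == 1,
                   "MSI", "MSS"),
      stringsAsFactors = FALSE
    )

    counts <- rpois(n, cfg$mut_rates[pattern])
    # regulators get a fifth of the calls so regulator-level mutation
    # summaries are exercised at realistic frequencies
    mut <- NULL
    if (sum(counts) > 0) {
      sample_col <- rep(sample_ids, counts)
      total <- sum(counts)
      from_reg <- rbinom(total, 1, 0.2) == 1
      genes_mut <- character(total)
      genes_mut[from_reg] <- sample(gene_ids[seq_len(nreg)], sum(from_reg),
                                    replace = TRUE)
      genes_mut[!from_reg] <- sample(gene_ids[-seq_len(nreg)], sum(!from_reg),
                                     replace = TRUE)
      mut <- data.frame(
        Hugo_Symbol = genes_mut,
        Tumor_Sample_Barcode = sample_col,
        Variant_Classification = sample(.variant_classes(), total, replace = TRUE),
        stringsAsFactors = FALSE
      )
    } else {
      mut <- data.frame(Hugo_Symbol = character(), Tumor_Sample_Barcode = character(),
                        Variant_Classification = character(), stringsAsFactors = FALSE)
    }

    gene_beta <- setNames(numeric(m), gene_ids)
    if (cfg$effect_size > 0) {
      centered_log_h <- log_h - mean(log_h)
      for (p in seq_len(k)) {
        planted <- gene_ids[c(reg_blocks[[p]], sig_blocks[[p]])]
        gene_beta[planted] <- centered_log_h[p] / cfg$effect_size
      }
    }

    truth <- list(
      pattern = pattern,
      deg_genes = gene_ids[sig_rows],
      # every gene with a planted pattern-dependent mean (regulators, the
      # DEG block, and pattern-affine signature-set genes)
      pattern_genes = if (cfg$effect_size > 0)
        gene_ids[sort(unique(c(seq_len(nreg), sig_rows, affine_rows)))]
        else character(0),
      regulator_blocks = lapply(reg_blocks, function(i) gene_ids[i]),
      gene_beta = gene_beta,
      prognostic_score = prognostic,
      batch = NULL, batch_offsets = NULL
    )
    structure(list(expression = expr, clinical = clinical, mutations = mut,
                   gene_sets = gene_sets, truth = truth, config = cfg),
              class = "synthetic_cohort")
  })
}

#' Generate batched cohorts sharing one pattern structure
#'
#' Draws one cohort with [generate_cohort()], randomly partitions its
#' samples into `config$n_batches` cohorts, and adds an independent
#' per-gene additive offset `N(0, batch_shift_sd^2)` to each cohort,
#' emulating platform/site batch effects across merged series. Pattern
#' composition is shared across batches by construction.
#'
#' @param config a [synthetic_config()] with `n_batches >= 2`.
#' @param batch_sizes optional integer vector of cohort sizes summing to
#'   `n_samples` (default near-even split).
#' @return A list of class `synthetic_batches`: `cohorts` (list of
#'   `synthetic_cohort`, one per batch), `truth` (the shared truth plus
#'   `batch` labels and the `batch_offsets` gene x batch matrix), `config`.
#' @export
generate_batched_cohorts <- function(config, batch_sizes = NULL) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  if (config$n_batches < 2) .stopf("n_batches must be >= 2")
  base <- generate_cohort(config)
  cfg <- config
  .with_seed(.derive_seed(cfg$seed, 2L), {
    n <- cfg$n_samples
    b <- cfg$n_batches
    if (is.null(batch_sizes)) {
      batch_sizes <- rep(n %/% b, b)
      extra <- n %% b
      if (extra > 0) batch_sizes[seq_len(extra)] <- batch_sizes[seq_len(extra)] + 1
    }
    if (sum(batch_sizes) != n || length(batch_sizes) != b)
      .stopf("batch_sizes must be %d sizes summing to n_samples", b)
    batch <- sample(rep(seq_len(b), times = batch_sizes))
    names(batch) <- colnames(base$expression)
    offsets <- matrix(rnorm(cfg$n_genes * b, sd = cfg$batch_shift_sd),
                      cfg$n_genes, b,
                      dimnames = list(rownames(base$expression),
                                      paste0("batch", seq_len(b))))
    cohorts <- lapply(seq_len(b), function(bi) {
      ids <- names(batch)[batch == bi]
      expr <- base$expression[, ids, drop = FALSE] + offsets[, bi]
      truth <- base$truth
      truth$pattern <- truth$pattern[ids]
      truth$prognostic_score <- truth$prognostic_score[ids]
      truth$batch <- setNames(rep(bi, length(ids)), ids)
      truth$batch_offsets <- offsets[, bi]
      structure(list(
        expression = expr,
        clinical = base$clinical[match(ids, base$clinical$sample_id), , drop = FALSE],
        mutations = base$mutations[base$mutations$Tumor_Sample_Barcode %in% ids, ,
                                   drop = FALSE],
        gene_sets = base$gene_sets, truth = truth, config = cfg
      ), class = "synthetic_cohort")
    })
    truth <- base$truth
    truth$batch <- batch
    truth$batch_offsets <- offsets
    structure(list(cohorts = cohorts, truth = truth, config = cfg),
              class = "synthetic_batches")
  })
}

#' Append simulated immunotherapy response labels
#'
#' Draws a binary responder (CR/PR) vs non-responder (SD/PD) label whose
#' logit is linear in the standardized planted prognostic score, emulating
#' response analyses of checkpoint-blockade cohorts. A positive slope makes
#' high-risk samples more likely to respond; use a negative slope for the
#' usual "low score responds better" direction.
#'
#' @param cohort a `synthetic_cohort`.
#' @param response_logit_slope slope on the standardized prognostic score.
#' @param intercept logit intercept (default 0, ~50% overall response).
#' @param seed RNG seed (default derived from the cohort seed).
#' @return The cohort's clinical table with added `response` (CR/PR/SD/PD)
#'   and `responder` (0/1) columns.
#' @export
generate_immunotherapy_labels <- function(cohort, response_logit_slope,
                                          intercept = 0,
                                          seed = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  seed <- seed %||% .derive_seed(cohort$config$seed, 3L)
  .with_seed(seed, {
    z <- cohort$truth$prognostic_score
    if (sd(z) > 0) z <- (z - mean(z)) / sd(z)
    p <- plogis(intercept + response_logit_slope * z)
    responder <- rbinom(length(z), 1, p)
    fine <- ifelse(responder == 1,
                   sample(c("CR", "PR"), length(z), replace = TRUE),
                   sample(c("SD", "PD"), length(z), replace = TRUE))
    clin <- cohort$clinical
    clin$response <- fine
    clin$responder <- responder
    clin
  })
}
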