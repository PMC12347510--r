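#' Specification for the synthetic expression-data generator
#'
#' Describes the study design the generator emulates: two conditions
#' (regenerative wound healing WH vs fibrosis F) sampled on three days
#' with three biological replicates each — 18 samples — over a few
#' thousand genes, a minority of which carry planted condition effects on
#' the log2 scale.
#'
#' @param n_genes total genes (default 2000).
#' @param n_planted_f genes up-shifted in F samples (default 20).
#' @param n_planted_wh genes up-shifted in WH samples (default 10).
#' @param effect_size planted shift in log2 units (default 3).
#' @param noise_sd per-observation Gaussian SD in log2 units (default 1).
#' @param baseline_log2_mean_range range of per-gene baseline log2 means
#'   (default c(0, 10)).
#' @param day_effect_sd SD of mean-zero per-gene-per-day nuisance shifts
#'   shared by both conditions (default 0.25).
#' @param library_size_cv coefficient of variation of per-sample
#'   log-normal library-size factors (default 0.1).
#' @param n_days,n_reps design dimensions (defaults 3 and 3).
#' @param seed integer seed.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(n_genes = 2000, n_planted_f = 20, n_planted_wh = 10,
                     effect_size = 3, noise_sd = 1,
                     baseline_log2_mean_range = c(0, 10),
                     day_effect_sd = 0.25, library_size_cv = 0.1,
                     n_days = 3, n_reps = 3, seed = 1) {
  stopifnot(n_genes >= 1, n_planted_f >= 0, n_planted_wh >= 0,
            n_planted_f + n_planted_wh < n_genes,
            effect_size >= 0, noise_sd >= 0, day_effect_sd >= 0,
            library_size_cv >= 0, n_days >= 1, n_reps >= 1,
            length(baseline_log2_mean_range) == 2)
  structure(list(n_genes = n_genes, n_planted_f = n_planted_f,
                 n_planted_wh = n_planted_wh, effect_size = effect_size,
                 noise_sd = noise_sd,
                 baseline_log2_mean_range = baseline_log2_mean_range,
                 day_effect_sd = day_effect_sd,
                 library_size_cv = library_size_cv,
                 n_days = n_days, n_reps = n_reps, seed = seed),
            class = "sim_spec")
}

#' Generate a synthetic FPKM-like expression matrix with planted effects
#'
#' Per gene, a baseline log2 mean is drawn uniformly from the configured
#' range; planted genes add `effect_size` in their associated condition;
#' per-gene-per-day nuisance shifts and per-observation Gaussian noise
#' (both log2-scale) are added; values are back-transformed to the linear
#' scale and each sample column is multiplied by a log-normal library
#' factor. The result mimics an FPKM table before any normalization.
#'
#' @param spec a [sim_spec].
#' @return list: `matrix` (an [expr_matrix], unit FPKM) and `truth`
#'   (data.frame `gene_id`, `class` ("F"/"WH"), `log2_effect` signed as
#'   F-versus-WH, so WH-planted genes are negative).
#' @export
generate_expression <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  n_samp <- 2 * spec$n_days * spec$n_reps
  gene_ids <- sprintf("G%05d", seq_len(spec$n_genes))
  cond <- rep(c("WH", "F"), each = spec$n_days * spec$n_reps)
  day <- rep(rep(seq_len(spec$n_days), each = spec$n_reps), 2)
  repl <- rep(seq_len(spec$n_reps), 2 * spec$n_days)
  samples <- data.frame(
    sample_id = paste0(cond, "_D", day, "_R", repl),
    condition = cond, day = day, replicate = repl,
    stringsAsFactors = FALSE)
  planted_f <- if (spec$n_planted_f > 0) seq_len(spec$n_planted_f)
               else integer(0)
  planted_wh <- if (spec$n_planted_wh > 0)
    spec$n_planted_f + seq_len(spec$n_planted_wh) else integer(0)
  base <- runif(spec$n_genes, spec$baseline_log2_mean_range[1],
                spec$baseline_log2_mean_range[2])
  log2m <- matrix(base, spec$n_genes, n_samp)
  log2m[planted_f, cond == "F"] <- log2m[planted_f, cond == "F"] +
    spec$effect_size
  log2m[planted_wh, cond == "WH"] <- log2m[planted_wh, cond == "WH"] +
    spec$effect_size
  if (spec$day_effect_sd > 0) {
    day_shift <- matrix(rnorm(spec$n_genes * spec$n_days, 0,
                              spec$day_effect_sd),
                        spec$n_genes, spec$n_days)
    log2m <- log2m + day_shift[, day]
  }
  log2m <- log2m + matrix(rnorm(spec$n_genes * n_samp, 0, spec$noise_sd),
                          spec$n_genes, n_samp)
  vals <- 2^log2m
  if (spec$library_size_cv > 0) {
    sdlog <- sqrt(log(1 + spec$library_size_cv^2))
    lib <- exp(rnorm(n_samp, -sdlog^2 / 2, sdlog))
    vals <- sweep(vals, 2, lib, "*")
  }
  dimnames(vals) <- list(gene_ids, samples$sample_id)
  planted <- c(planted_f, planted_wh)
  truth <- data.frame(
    gene_id = gene_ids[planted],
    class = c(rep("F", length(planted_f)), rep("WH", length(planted_wh))),
    log2_effect = c(rep(spec$effect_size, length(planted_f)),
                    rep(-spec$effect_size, length(planted_wh))),
    stringsAsFactors = FALSE)
  list(matrix = expr_matrix(vals, samples, unit = "FPKM"), truth = truth)
}

#' Generate gene-set fixtures matched to a simulation truth table
#'
#' Emits one "enriched" set holding the planted fibrosis genes padded
#' with random unplanted genes, plus size-matched random sets, for
#' exercising the enrichment module.
#'
#' @param truth truth table from [generate_expression].
#' @param spec the [sim_spec] used.
#' @param set_size total size of each set (default 30).
#' @param n_random_sets number of random comparison sets (default 10).
#' @param seed integer seed (default `spec$seed + 1`).
#' @return named list of gene-id vectors; the planted set is
#'   `"planted_F_set"`.
#' @export
generate_gene_sets <- function(truth, spec, set_size = 30,
                               n_random_sets = 10, seed = spec$seed + 1) {
  set.seed(seed)
  all_genes <- sprintf("G%05d", seq_len(spec$n_genes))
  planted_f <- truth$gene_id[truth$class == "F"]
  pool <- setdiff(all_genes, truth$gene_id)
  pad <- sample(pool, max(0, set_size - length(planted_f)))
  sets <- list(planted_F_set = c(planted_f, pad))
  for (i in seq_len(n_random_sets))
    sets[[sprintf("random_set_%02d", i)]] <- sample(pool, set_size)
  sets
}

#' Generate a synthetic qPCR Ct fixture from known expression ratios
#'
#' For each chosen gene, the per-condition true log2 expression (baseline
#' plus any planted effect) is converted to a Ct value as
#' `Ct = a - log2(expression) + N(0, noise_sd)`; the reference gene is
#' held constant across conditions. Three experiments of three technical
#' replicates are produced by default, matching a typical validation
#' design.
#'
#' @param truth truth table from [generate_expression].
#' @param spec the [sim_spec] used.
#' @param genes genes to include (default: first three truth genes).
#' @param reference_gene reference id (default `"GAPDH"`).
#' @param a Ct intercept in cycles (default 30).
#' @param ct_noise_sd replicate noise in cycles (default 0.1).
#' @param n_experiments,n_technical design (defaults 3 and 3).
#' @param seed integer seed (default `spec$seed + 2`).
#' @return data.frame Ct table (see [read_ct_table]); attribute
#'   `planted_folds` gives each gene's true F-vs-WH fold change.
#' @export
generate_ct_fixture <- function(truth, spec, genes = head(truth$gene_id, 3),
                                reference_gene = "GAPDH", a = 30,
                                ct_noise_sd = 0.1, n_experiments = 3,
                                n_technical = 3, seed = spec$seed + 2) {
  set.seed(seed)
  base_range <- spec$baseline_log2_mean_range
  rows <- list()
  planted_folds <- setNames(numeric(length(genes)), genes)
  for (g in genes) {
    b <- runif(1, base_range[1] + 2, base_range[2])  # keep Ct < a
    eff <- truth$log2_effect[match(g, truth$gene_id)]
    if (is.na(eff)) eff <- 0
    lwh <- b; lf <- b + eff
    planted_folds[g] <- 2^eff
    for (e in seq_len(n_experiments)) {
      for (cond in c("WH", "F")) {
        mu <- a - (if (cond == "F") lf else lwh)
        rows[[length(rows) + 1]] <- data.frame(
          experiment = e, condition = cond, gene = g,
          technical_rep = seq_len(n_technical),
          ct = mu + rnorm(n_technical, 0, ct_noise_sd))
      }
    }
  }
  ref_level <- a - mean(base_range)
  for (e in seq_len(n_experiments)) {
    for (cond in c("WH", "F")) {
      rows[[length(rows) + 1]] <- data.frame(
        experiment = e, condition = cond, gene = reference_gene,
        technical_rep = seq_len(n_technical),
        ct = ref_level + rnorm(n_technical, 0, ct_noise_sd))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "planted_folds") <- planted_folds
  out
}
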