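#' Run the full signature-discovery pipeline
#'
#' Orchestrates the stages in order: FPKM-to-TPM normalization, log2
#' transform, class-stratified holdout split, univariate Welch screen on
#' the training samples only, the three feature-selection tracks
#' (bootstrap-LASSO stability selection + cross-validated refit;
#' linear-SVM ranking + permutation pruning + calibrated RBF classifier;
#' random-forest Gini ranking + permutation confirmation), held-out
#' evaluation per track, per-gene ROC on the holdout, pooled log2 fold
#' changes on the FPKM matrix, and optionally per-candidate gene-set
#' enrichment and delta-delta-Ct quantification. All feature selection
#' sees training data only; the holdout enters at evaluation time.
#'
#' The consensus table labels every selected gene as wound-healing- or
#' fibrosis-associated by the sign of its training WH-minus-F mean log2
#' difference (positive = WH-associated).
#'
#' @param m an [expr_matrix] of FPKM values (all samples).
#' @param gene_sets optional named list of gene sets for enrichment of
#'   the selected genes.
#' @param ct_table optional qPCR Ct table for delta-delta-Ct validation.
#' @param n_holdout_per_class holdout size per class (default 5).
#' @param screen,lasso,svm,rf,gsea parameter objects (defaults as
#'   documented in each constructor).
#' @param offset log2 pseudo-count (default 1).
#' @param seed global seed; stage seeds are derived from it.
#' @param output_dir if non-NULL, artifacts (TSVs plus a JSON parameter
#'   sidecar) are written there.
#' @return list of class `fibrosig_run` with elements `split`, `screen`,
#'   `tracks` (per-track selection results, holdout predictions and
#'   [confusion_and_pr] reports), `per_gene_auc`, `pooled_log2fc`,
#'   `consensus`, `pca`, and optionally `gsea`, `ddct`.
#' @export
run_pipeline <- function(m, gene_sets = NULL, ct_table = NULL,
                         n_holdout_per_class = 5,
                         screen = screen_params(),
                         lasso = stability_params(),
                         svm = svm_params(),
                         rf = rf_params(),
                         gsea = gsea_params(),
                         offset = 1, seed = 1, output_dir = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  stage <- function(...) message(sprintf("[fibrosig] %s", sprintf(...)))
  lasso$seed <- seed + 101; svm$seed <- seed + 202
  rf$seed <- seed + 303; gsea$seed <- seed + 404

  tpm <- fpkm_to_tpm(m)
  log2tpm <- log_transform(tpm, offset = offset)
  split <- make_holdout_split(tpm, n_holdout_per_class, seed = seed)
  train_tpm <- split$train
  holdout_log2 <- log_transform(split$holdout, offset = offset)
  train_log2 <- log_transform(train_tpm, offset = offset)
  stage("split: %d train / %d holdout samples",
        ncol(train_tpm$values), ncol(split$holdout$values))

  scr <- screen_genes(train_tpm, screen)
  kept <- scr$gene_id[scr$kept]
  stage("screen: %d of %d genes kept", length(kept), nrow(scr))
  if (length(kept) == 0)
    stop("screen kept no genes; nothing to model", call. = FALSE)
  train_sel <- train_log2[kept, ]
  holdout_sel <- holdout_log2[kept, ]
  y_hold <- class_labels(split$holdout)

  tracks <- list()

  # --- LASSO track -----------------------------------------------------
  stab <- stability_select(train_sel, lasso)
  stage("lasso: %d stable genes (freq >= %.2f)",
        length(stab$stable_genes), lasso$freq_threshold)
  lasso_track <- list(stability = stab, model = NULL, panel = character(),
                      predictions = NULL, evaluation = NULL)
  if (length(stab$stable_genes) > 0) {
    fit <- cv_refit(train_sel, stab$stable_genes, lasso)
    pred <- predict_lasso(fit, holdout_sel)
    lasso_track$model <- fit
    lasso_track$panel <- fit$selected_genes
    lasso_track$predictions <- pred
    lasso_track$evaluation <- confusion_and_pr(
      y_hold, as.integer(pred$predicted == "F"), pred$score)
    stage("lasso: %d-gene panel, holdout AUC %.3f",
          length(fit$selected_genes), lasso_track$evaluation$auc)
  } else {
    stage("lasso: empty stable set, no panel reported")
  }
  tracks$lasso <- lasso_track

  # --- SVM track -------------------------------------------------------
  ranking <- rank_linear_svm(train_sel, svm)
  top <- head(ranking$gene_id, svm$top_k)
  imp <- svm_permutation_importance(train_sel, top, svm)
  panel <- imp$gene_id[imp$retained]
  svm_track <- list(ranking = ranking, importance = imp, panel = panel,
                    predictions = NULL, evaluation = NULL)
  if (length(panel) > 0) {
    rbf <- fit_calibrated_rbf(train_sel, panel, svm)
    pred <- predict_rbf(rbf, holdout_sel)
    svm_track$model <- rbf
    svm_track$predictions <- pred
    svm_track$evaluation <- confusion_and_pr(
      y_hold, as.integer(pred$predicted == "F"), pred$score)
    stage("svm: %d/%d genes retained, holdout AUC %.3f", length(panel),
          svm$top_k, svm_track$evaluation$auc)
  } else {
    stage("svm: no genes survived permutation pruning")
  }
  tracks$svm <- svm_track

  # --- RF track --------------------------------------------------------
  forest <- fit_rf(train_sel, rf)
  panelobj <- confirm_and_reduce(forest, train_sel, rf)
  rf_track <- list(gini = forest$gini, importance = panelobj$importance,
                   panel = panelobj$panel, predictions = NULL,
                   evaluation = NULL)
  if (length(panelobj$panel) > 0) {
    pred <- predict_rf(panelobj, holdout_sel)
    rf_track$model <- panelobj
    rf_track$predictions <- pred
    rf_track$evaluation <- confusion_and_pr(
      y_hold, as.integer(pred$predicted == "F"), pred$score)
    stage("rf: %d-gene panel, holdout AUC %.3f", length(panelobj$panel),
          rf_track$evaluation$auc)
  } else {
    stage("rf: no genes with positive permutation importance")
  }
  tracks$rf <- rf_track

  selected <- unique(c(tracks$lasso$panel, tracks$svm$panel,
                       tracks$rf$panel))

  # --- per-gene ROC on holdout, pooled log2FC on full FPKM -------------
  per_gene <- lapply(selected, function(g) {
    r <- per_gene_roc(holdout_sel, g)
    data.frame(gene_id = g, auc = r$auc, direction = r$direction,
               stringsAsFactors = FALSE)
  })
  per_gene <- if (length(per_gene)) do.call(rbind, per_gene) else
    data.frame(gene_id = character(), auc = numeric(),
               direction = character())
  fc <- lapply(selected, function(g) {
    r <- pooled_log2fc(m, g, offset = offset)
    data.frame(gene_id = g, mean_F = r$mean_F, mean_WH = r$mean_WH,
               log2fc = r$log2fc, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  fc <- if (length(fc)) do.call(rbind, fc) else
    data.frame(gene_id = character(), mean_F = numeric(),
               mean_WH = numeric(), log2fc = numeric(),
               p_value = numeric())

  # consensus association from training means only
  consensus <- do.call(rbind, lapply(names(tracks), function(tr) {
    p <- tracks[[tr]]$panel
    if (length(p) == 0) return(NULL)
    data.frame(gene_id = p, track = tr, stringsAsFactors = FALSE)
  }))
  if (!is.null(consensus)) {
    tr_log2 <- train_log2$values[consensus$gene_id, , drop = FALSE]
    trc <- train_log2$samples$condition
    diffs <- rowMeans(tr_log2[, trc == "WH", drop = FALSE]) -
      rowMeans(tr_log2[, trc == "F", drop = FALSE])
    consensus$wh_minus_f <- unname(diffs)
    consensus$association <- ifelse(diffs > 0, "WH", "F")
  } else {
    consensus <- data.frame(gene_id = character(), track = character(),
                            wh_minus_f = numeric(),
                            association = character())
  }

  result <- list(split = list(train = train_tpm$samples$sample_id,
                              holdout = split$holdout$samples$sample_id),
                 screen = scr, tracks = tracks, per_gene_auc = per_gene,
                 pooled_log2fc = fc, consensus = consensus,
                 pca = pca_projection(log2tpm),
                 seed = seed)

  if (!is.null(gene_sets) && length(selected) > 0) {
    result$gsea <- lapply(setNames(selected, selected), function(g) {
      ranked <- rank_for_candidate(log2tpm, g, gsea)
      nes_and_fdr(ranked, gene_sets, gsea)
    })
    stage("gsea: %d candidate genes scored against %d sets",
          length(selected), length(gene_sets))
  }
  if (!is.null(ct_table)) {
    result$ddct <- ddct_analysis(ct_table)
    stage("ddct: %d genes quantified", nrow(result$ddct))
  }
  class(result) <- "fibrosig_run"
  if (!is.null(output_dir)) write_run_artifacts(result, output_dir)
  result
}

#' @export
print.fibrosig_run <- function(x, ...) {
  cat(sprintf("fibrosig pipeline run (seed %d)\n", x$seed))
  cat(sprintf("  screen: %d/%d genes kept\n", sum(x$screen$kept),
              nrow(x$screen)))
  for (tr in names(x$tracks)) {
    t <- x$tracks[[tr]]
    auc <- if (is.null(t$evaluation)) NA else t$evaluation$auc
    cat(sprintf("  %-5s panel: %-40s holdout AUC %s\n", tr,
                paste(t$panel, collapse = ","),
                ifelse(is.na(auc), "-", sprintf("%.2f", auc))))
  }
  invisible(x)
}

# Write the run's tabular artifacts plus a JSON parameter sidecar.
write_run_artifacts <- function(run, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    write.table(df, file.path(output_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  wt(run$screen, "screen_result.tsv")
  wt(run$tracks$lasso$stability$frequencies, "lasso_frequencies.tsv")
  wt(run$tracks$svm$ranking, "svm_ranking.tsv")
  wt(run$tracks$svm$importance, "svm_importance.tsv")
  wt(run$tracks$rf$gini, "rf_gini.tsv")
  wt(run$tracks$rf$importance, "rf_permutation.tsv")
  if (!is.null(run$tracks$svm$predictions))
    wt(run$tracks$svm$predictions, "svm_decision_values.tsv")
  if (!is.null(run$tracks$rf$predictions))
    wt(run$tracks$rf$predictions, "rf_holdout_predictions.tsv")
  wt(run$per_gene_auc, "per_gene_auc.tsv")
  wt(run$pooled_log2fc, "pooled_log2fc.tsv")
  wt(run$consensus, "consensus_panel.tsv")
  wt(run$pca, "pca_coords.tsv")
  if (!is.null(run$ddct)) wt(run$ddct, "ddct_results.tsv")
  if (!is.null(run$tracks$lasso$model)) {
    mod <- run$tracks$lasso$model
    jsonlite::write_json(
      list(lambda = mod$lambda, intercept = mod$intercept,
           coefficients = as.list(mod$coefficients),
           selected_genes = mod$selected_genes),
      file.path(output_dir, "lasso_final_model.json"),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(
    list(seed = run$seed, train_samples = run$split$train,
         holdout_samples = run$split$holdout),
    file.path(output_dir, "run_params.json"), auto_unbox = TRUE)
  invisible(output_dir)
}
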