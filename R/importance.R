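# Shared helpers for the supervised tracks.

# samples x genes model matrix on the modeling (log2) scale
model_matrix <- function(m) t(m$values)

# z-score columns; zero-sd columns get scale 1 so they map to 0
standardize_fit <- function(x) {
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  sdev[sdev == 0] <- 1
  list(center = mu, scale = sdev)
}
standardize_apply <- function(x, std) {
  sweep(sweep(x, 2, std$center, "-"), 2, std$scale, "/")
}

# Stratified fold assignment: per class, samples are shuffled and fold
# ids recycled, so every fold keeps both classes whenever possible.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Permutation importance by out-of-fold AUC drop
#'
#' The shared importance engine for the SVM and random-forest tracks.
#' Models are fit per stratified training fold; baseline performance is
#' the AUC of the assembled out-of-fold scores. For each listed gene and
#' each of `n_permutations` seeded shuffles, the gene's values are
#' permuted across all samples, the fold models re-score their held-in
#' folds (no refit), and the importance is baseline AUC minus the mean
#' permuted AUC. Only training data is used — the holdout set plays no
#' part in feature selection.
#'
#' @param x samples x genes numeric matrix (already standardized if the
#'   fitter expects it).
#' @param y binary labels (1 = F).
#' @param genes character vector of genes (columns of `x`) to score.
#'   Genes not among the model's features have importance exactly 0.
#' @param fit_fun `function(x_train, y_train)` returning a fitted model.
#' @param score_fun `function(model, x_new)` returning scores oriented
#'   toward the positive class.
#' @param n_folds number of stratified folds (default 3).
#' @param n_permutations shuffles per gene (default 100).
#' @param seed integer seed.
#' @return data.frame: `gene_id`, `mean_auc_drop`, `sd_auc_drop`,
#'   `retained` (strictly positive mean drop); attribute `baseline_auc`.
#' @export
permutation_importance <- function(x, y, genes, fit_fun, score_fun,
                                   n_folds = 3, n_permutations = 100,
                                   seed = 1) {
  stopifnot(is.matrix(x), length(y) == nrow(x))
  set.seed(seed)
  fold <- stratified_folds(y, n_folds)
  models <- lapply(seq_len(n_folds), function(k) {
    fit_fun(x[fold != k, , drop = FALSE], y[fold != k])
  })
  oof_scores <- function(xm) {
    sc <- numeric(nrow(xm))
    for (k in seq_len(n_folds)) {
      idx <- which(fold == k)
      sc[idx] <- score_fun(models[[k]], xm[idx, , drop = FALSE])
    }
    sc
  }
  baseline <- auc_score(y, oof_scores(x))
  res <- lapply(genes, function(g) {
    if (!g %in% colnames(x))
      return(data.frame(gene_id = g, mean_auc_drop = 0, sd_auc_drop = 0,
                        retained = FALSE))
    if (sd(x[, g]) == 0)
      return(data.frame(gene_id = g, mean_auc_drop = 0, sd_auc_drop = 0,
                        retained = FALSE))
    drops <- vapply(seq_len(n_permutations), function(i) {
      xp <- x
      xp[, g] <- x[sample(nrow(x)), g]
      baseline - auc_score(y, oof_scores(xp))
    }, numeric(1))
    data.frame(gene_id = g, mean_auc_drop = mean(drops),
               sd_auc_drop = sd(drops), retained = mean(drops) > 0)
  })
  out <- do.call(rbind, res)
  attr(out, "baseline_auc") <- baseline
  out
}
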