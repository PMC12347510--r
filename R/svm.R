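#' Parameters for the SVM selection track
#'
#' @param top_k number of top-ranked genes carried into permutation
#'   pruning (default 5).
#' @param cost soft-margin cost C, fixed rather than tuned (default 1).
#' @param rbf_gamma RBF kernel width; `"auto_scale"` (default) uses
#'   1 / (n_features * mean feature variance), or give a positive number.
#' @param n_permutations shuffles per gene for permutation importance
#'   (default 100).
#' @param calibration_folds folds for Platt sigmoid calibration
#'   (default 3).
#' @param seed integer seed.
#' @return an `svm_params` list.
#' @export
svm_params <- function(top_k = 5, cost = 1, rbf_gamma = "auto_scale",
                       n_permutations = 100, calibration_folds = 3,
                       seed = 1) {
  stopifnot(top_k >= 1, cost > 0, n_permutations >= 1,
            calibration_folds >= 2)
  if (is.numeric(rbf_gamma)) stopifnot(rbf_gamma > 0)
  structure(list(top_k = top_k, cost = cost, rbf_gamma = rbf_gamma,
                 n_permutations = n_permutations,
                 calibration_folds = calibration_folds, seed = seed),
            class = "svm_params")
}

# Fit an e1071 SVM with F as the positive class and return a score
# function giving decision values oriented so positive = WH, negative = F
# (matching the convention that fibrosis sits on the negative side of the
# decision boundary).
svm_fit_raw <- function(x, y, kernel, cost, gamma = NULL) {
  yf <- factor(ifelse(y == 1, "F", "WH"), levels = c("WH", "F"))
  args <- list(x = x, y = yf, kernel = kernel, cost = cost, scale = FALSE)
  if (!is.null(gamma)) args$gamma <- gamma
  do.call(e1071::svm, args)
}

svm_decision_wh <- function(model, x) {
  pred <- predict(model, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # e1071 labels the column "<first>/<second>"; positive means the first.
  pos <- strsplit(colnames(dv)[1], "/")[[1]][1]
  d <- drop(dv[, 1])
  if (pos == "WH") d else -d
}

#' Rank genes by absolute linear-SVM coefficient
#'
#' One linear soft-margin SVM is fit on the standardized training matrix;
#' genes are ranked by the absolute magnitude of their weight-vector
#' entries (descending, ties broken by gene id).
#'
#' @param train an [expr_matrix] (log2 modeling scale, screened genes).
#' @param params an [svm_params] object.
#' @return data.frame: `gene_id`, `weight`, `abs_weight`, ranked.
#' @export
rank_linear_svm <- function(train, params = svm_params()) {
  stopifnot(inherits(train, "expr_matrix"))
  x <- model_matrix(train)
  y <- class_labels(train)
  if (length(unique(y)) < 2)
    stop("training data must contain both classes", call. = FALSE)
  std <- standardize_fit(x)
  xs <- standardize_apply(x, std)
  set.seed(params$seed)
  model <- svm_fit_raw(xs, y, kernel = "linear", cost = params$cost)
  w <- drop(crossprod(model$coefs, model$SV))
  # orient w toward the F class score; magnitude is what ranks genes
  full_w <- setNames(numeric(ncol(xs)), colnames(xs))
  full_w[colnames(model$SV)] <- w
  ord <- order(-abs(full_w), names(full_w))
  data.frame(gene_id = names(full_w)[ord], weight = unname(full_w[ord]),
             abs_weight = abs(unname(full_w[ord])),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Permutation-importance pruning of the top linear-SVM genes
#'
#' Computes out-of-fold AUC-drop permutation importance (see
#' [permutation_importance]) for the given genes using a linear SVM on the
#' training data only; genes with non-positive mean AUC drop are flagged
#' for exclusion from the final panel.
#'
#' @param train an [expr_matrix] (log2 modeling scale).
#' @param genes genes to score (typically the top `top_k` from
#'   [rank_linear_svm]).
#' @param params an [svm_params] object.
#' @return data.frame from [permutation_importance].
#' @export
svm_permutation_importance <- function(train, genes,
                                       params = svm_params()) {
  x <- model_matrix(train)[, genes, drop = FALSE]
  y <- class_labels(train)
  std <- standardize_fit(x)
  xs <- standardize_apply(x, std)
  permutation_importance(
    xs, y, genes,
    fit_fun = function(xt, yt) svm_fit_raw(xt, yt, "linear", params$cost),
    score_fun = function(mod, xn) -svm_decision_wh(mod, xn),
    n_folds = params$calibration_folds,
    n_permutations = params$n_permutations, seed = params$seed)
}

#' Fit a calibrated RBF-kernel SVM on a gene panel
#'
#' Fits a radial-basis-function SVM on the retained panel (standardized on
#' training data) and calibrates probabilities by Platt scaling: decision
#' values are collected out-of-fold over `calibration_folds` stratified
#' folds of the training data and a sigmoid (binomial GLM) maps decision
#' value to class probability. Decision values follow the convention
#' positive = WH, negative = F.
#'
#' @param train an [expr_matrix] (log2 modeling scale).
#' @param genes non-empty character vector, the final panel.
#' @param params an [svm_params] object.
#' @return list of class `rbf_model`: the fitted svm, calibration
#'   coefficients, `genes`, `std`, `gamma`.
#' @export
fit_calibrated_rbf <- function(train, genes, params = svm_params()) {
  stopifnot(inherits(train, "expr_matrix"), length(genes) >= 1)
  x <- model_matrix(train)[, genes, drop = FALSE]
  y <- class_labels(train)
  std <- standardize_fit(x)
  xs <- standardize_apply(x, std)
  gamma <- if (identical(params$rbf_gamma, "auto_scale")) {
    1 / (ncol(xs) * mean(apply(xs, 2, var)))
  } else params$rbf_gamma
  set.seed(params$seed)
  folds <- params$calibration_folds
  dv <- rep(NA_real_, length(y))
  repeat {
    fold <- stratified_folds(y, folds)
    ok <- all(vapply(seq_len(folds), function(k)
      length(unique(y[fold != k])) == 2, logical(1)))
    if (ok) break
    folds <- folds - 1
    warning("calibration fold collapsed to one class; reducing folds to ",
            folds)
    if (folds < 2) stop("cannot build two-class calibration folds",
                        call. = FALSE)
  }
  for (k in seq_len(folds)) {
    mk <- svm_fit_raw(xs[fold != k, , drop = FALSE], y[fold != k],
                      "radial", params$cost, gamma)
    dv[fold == k] <- svm_decision_wh(mk, xs[fold == k, , drop = FALSE])
  }
  is_wh <- as.integer(y == 0)
  calib <- suppressWarnings(glm(is_wh ~ dv, family = binomial()))
  model <- svm_fit_raw(xs, y, "radial", params$cost, gamma)
  structure(list(svm = model, calib = coef(calib), genes = genes,
                 std = std, gamma = gamma),
            class = "rbf_model")
}

#' Apply a calibrated RBF-SVM to new samples
#'
#' @param model an `rbf_model` from [fit_calibrated_rbf].
#' @param m an [expr_matrix] on the training (log2) scale.
#' @return data.frame: `sample_id`, `decision_value` (positive = WH),
#'   `prob_WH`, `score` (probability of F), `predicted`, `truth`.
#' @export
predict_rbf <- function(model, m) {
  stopifnot(inherits(model, "rbf_model"), inherits(m, "expr_matrix"))
  x <- model_matrix(m)[, model$genes, drop = FALSE]
  xs <- standardize_apply(x, model$std)
  d <- svm_decision_wh(model$svm, xs)
  prob_wh <- plogis(model$calib[1] + model$calib[2] * d)
  data.frame(sample_id = m$samples$sample_id, decision_value = d,
             prob_WH = prob_wh, score = 1 - prob_wh,
             predicted = ifelse(prob_wh >= 0.5, "WH", "F"),
             truth = m$samples$condition,
             stringsAsFactors = FALSE, row.names = NULL)
}
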