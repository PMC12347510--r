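#' Parameters for bootstrap-LASSO stability selection
#'
#' @param n_bootstrap number of bootstrap iterations (default 200).
#' @param subsample_fraction fraction of training samples drawn without
#'   replacement per iteration, stratified by class (default 0.75).
#' @param freq_threshold selection-frequency cutoff defining the stable
#'   set (default 0.5).
#' @param cv_folds stratified folds for penalty selection (default 3).
#' @param lambda_min_ratio smallest grid penalty as a fraction of the
#'   empty-support penalty lambda_max (default 1e-3).
#' @param n_lambda grid length (default 100).
#' @param seed integer seed.
#' @return a `stability_params` list.
#' @export
stability_params <- function(n_bootstrap = 200, subsample_fraction = 0.75,
                             freq_threshold = 0.5, cv_folds = 3,
                             lambda_min_ratio = 1e-3, n_lambda = 100,
                             seed = 1) {
  stopifnot(n_bootstrap >= 1,
            subsample_fraction > 0, subsample_fraction < 1,
            freq_threshold > 0, freq_threshold <= 1,
            cv_folds >= 2, lambda_min_ratio > 0, lambda_min_ratio < 1)
  structure(list(n_bootstrap = n_bootstrap,
                 subsample_fraction = subsample_fraction,
                 freq_threshold = freq_threshold, cv_folds = cv_folds,
                 lambda_min_ratio = lambda_min_ratio, n_lambda = n_lambda,
                 seed = seed),
            class = "stability_params")
}

# Shared penalty grid: n_lambda log-spaced values from lambda_max (the
# smallest penalty with empty support on the training data, taken from
# the head of glmnet's path) down to lambda_max * lambda_min_ratio.
lambda_grid <- function(x, y, params) {
  # small-n class-size warnings are inherent to this design; silenced
  fit <- suppressWarnings(
    glmnet::glmnet(x, y, family = "binomial", standardize = FALSE,
                   nlambda = 5))
  lam_max <- max(fit$lambda)
  exp(seq(log(lam_max), log(lam_max * params$lambda_min_ratio),
          length.out = params$n_lambda))
}

# One bootstrap iteration: stratified subsample, per-subsample z-scoring,
# penalty by stratified CV over the shared grid (fixed lambda_max/10 when
# CV degenerates), returns the nonzero support as gene names.
bootstrap_support <- function(x, y, grid, params) {
  idx <- unlist(lapply(unique(y), function(cl) {
    cls <- which(y == cl)
    sample(cls, ceiling(params$subsample_fraction * length(cls)))
  }))
  ys <- y[idx]
  if (length(unique(ys)) < 2) return(NULL)  # caller retries
  xs <- x[idx, , drop = FALSE]
  std <- standardize_fit(xs)
  keep <- apply(xs, 2, sd) > 0
  xs <- standardize_apply(xs, std)[, keep, drop = FALSE]
  lam <- tryCatch({
    fold <- stratified_folds(ys, params$cv_folds)
    cvf <- suppressWarnings(
      glmnet::cv.glmnet(xs, ys, family = "binomial", lambda = grid,
                        foldid = fold, standardize = FALSE,
                        type.measure = "deviance"))
    cvf$lambda.min
  }, error = function(e) max(grid) / 10)
  fit <- suppressWarnings(
    glmnet::glmnet(xs, ys, family = "binomial", lambda = grid,
                   standardize = FALSE))
  beta <- as.matrix(predict(fit, type = "coefficients",
                            s = lam, exact = FALSE))[-1, 1]
  names(beta)[beta != 0]
}

#' Bootstrap-LASSO stability selection
#'
#' Runs `n_bootstrap` L1-penalized logistic fits on stratified 75%
#' subsamples of the training data (drawn without replacement), records
#' which genes receive nonzero coefficients in each, and retains genes
#' selected in at least `freq_threshold` of the iterations as the stable
#' set.
#'
#' @param train an [expr_matrix] on the log2 modeling scale, restricted to
#'   screened genes.
#' @param params a [stability_params] object.
#' @return list of class `stability_result`: `frequencies` (data.frame
#'   `gene_id`, `frequency`, sorted by frequency then gene id),
#'   `stable_genes` (character), `params`.
#' @export
stability_select <- function(train, params = stability_params()) {
  stopifnot(inherits(train, "expr_matrix"))
  x <- model_matrix(train)
  y <- class_labels(train)
  if (length(unique(y)) < 2)
    stop("training data must contain both classes", call. = FALSE)
  set.seed(params$seed)
  grid <- lambda_grid(standardize_apply(x, standardize_fit(x)), y, params)
  counts <- setNames(numeric(ncol(x)), colnames(x))
  b <- 0; tries <- 0
  while (b < params$n_bootstrap && tries < 10 * params$n_bootstrap) {
    tries <- tries + 1
    sel <- bootstrap_support(x, y, grid, params)
    if (is.null(sel)) next
    b <- b + 1
    counts[sel] <- counts[sel] + 1
  }
  if (b < params$n_bootstrap)
    stop("could not draw enough two-class subsamples", call. = FALSE)
  freq <- counts / params$n_bootstrap
  ord <- order(-freq, names(freq))
  frequencies <- data.frame(gene_id = names(freq)[ord],
                            frequency = unname(freq[ord]),
                            stringsAsFactors = FALSE)
  stable <- frequencies$gene_id[frequencies$frequency >= params$freq_threshold]
  structure(list(frequencies = frequencies, stable_genes = stable,
                 params = params),
            class = "stability_result")
}

#' Cross-validated sparse refit on the stable gene set
#'
#' Selects the penalty by K-fold stratified cross-validated binomial
#' deviance over the stable genes only, refits on all training samples at
#' that penalty, and reports the genes that retain nonzero coefficients —
#' the final LASSO panel.
#'
#' @param train an [expr_matrix] (log2 modeling scale).
#' @param stable_genes non-empty character vector of gene ids.
#' @param params a [stability_params] object.
#' @return list of class `lasso_model`: `lambda`, `intercept`,
#'   `coefficients` (named, standardized scale), `selected_genes`,
#'   `std` (training centers/scales), `genes`.
#' @export
cv_refit <- function(train, stable_genes, params = stability_params()) {
  stopifnot(inherits(train, "expr_matrix"))
  if (length(stable_genes) == 0)
    stop("stable gene set is empty; no LASSO panel", call. = FALSE)
  x <- model_matrix(train)[, stable_genes, drop = FALSE]
  y <- class_labels(train)
  std <- standardize_fit(x)
  xs <- standardize_apply(x, std)
  padded <- FALSE
  if (ncol(xs) == 1) {           # glmnet needs >= 2 columns
    xs <- cbind(xs, `..pad` = 0)
    padded <- TRUE
  }
  set.seed(params$seed)
  fold <- stratified_folds(y, params$cv_folds)
  grid <- lambda_grid(xs, y, params)
  cvf <- suppressWarnings(
    glmnet::cv.glmnet(xs, y, family = "binomial", foldid = fold,
                      standardize = FALSE, type.measure = "deviance",
                      lambda = grid))
  lam <- cvf$lambda.min
  fit <- suppressWarnings(
    glmnet::glmnet(xs, y, family = "binomial", standardize = FALSE,
                   lambda = cvf$lambda))
  coefs <- as.matrix(predict(fit, type = "coefficients", s = lam))[, 1]
  intercept <- coefs[1]
  beta <- coefs[-1]
  if (padded) beta <- beta[names(beta) != "..pad"]
  structure(list(lambda = lam, intercept = unname(intercept),
                 coefficients = beta,
                 selected_genes = names(beta)[beta != 0],
                 std = std, genes = stable_genes),
            class = "lasso_model")
}

#' Predict fibrosis scores from a fitted sparse logistic model
#'
#' @param model a `lasso_model` from [cv_refit].
#' @param m an [expr_matrix] on the same (log2) scale as training.
#' @return data.frame: `sample_id`, `score` (probability of F),
#'   `predicted` ("WH"/"F" at 0.5), `truth`.
#' @export
predict_lasso <- function(model, m) {
  stopifnot(inherits(model, "lasso_model"), inherits(m, "expr_matrix"))
  x <- model_matrix(m)[, model$genes, drop = FALSE]
  xs <- standardize_apply(x, model$std)
  eta <- model$intercept + drop(xs %*% model$coefficients)
  prob <- plogis(eta)
  data.frame(sample_id = m$samples$sample_id, score = prob,
             predicted = ifelse(prob >= 0.5, "F", "WH"),
             truth = m$samples$condition,
             stringsAsFactors = FALSE, row.names = NULL)
}
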