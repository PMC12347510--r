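#' Parameters for the random-forest selection track
#'
#' @param n_trees number of trees (default 500).
#' @param max_features_fraction fraction of genes sampled at each split
#'   (default 0.5).
#' @param max_nodes optional cap on terminal nodes per tree (default
#'   `NULL` = unlimited depth).
#' @param top_k_examine genes taken forward by Gini rank for permutation
#'   confirmation (default 10).
#' @param top_k_final size of the final panel (default 3).
#' @param n_permutations shuffles per gene for permutation importance
#'   (default 100).
#' @param seed integer seed.
#' @return an `rf_params` list.
#' @export
rf_params <- function(n_trees = 500, max_features_fraction = 0.5,
                      max_nodes = NULL, top_k_examine = 10,
                      top_k_final = 3, n_permutations = 100, seed = 1) {
  stopifnot(n_trees >= 1, max_features_fraction > 0,
            max_features_fraction <= 1, top_k_examine >= 1,
            top_k_final >= 1, top_k_final <= top_k_examine)
  structure(list(n_trees = n_trees,
                 max_features_fraction = max_features_fraction,
                 max_nodes = max_nodes, top_k_examine = top_k_examine,
                 top_k_final = top_k_final,
                 n_permutations = n_permutations, seed = seed),
            class = "rf_params")
}

rf_fit_raw <- function(x, y, params) {
  yf <- factor(ifelse(y == 1, "F", "WH"), levels = c("WH", "F"))
  mtry <- max(1, round(params$max_features_fraction * ncol(x)))
  args <- list(x = x, y = yf, ntree = params$n_trees, mtry = mtry,
               importance = FALSE)
  if (!is.null(params$max_nodes)) args$maxnodes <- params$max_nodes
  do.call(randomForest::randomForest, args)
}

rf_prob_f <- function(model, x) predict(model, x, type = "prob")[, "F"]

#' Fit a random forest and rank genes by mean decrease in Gini impurity
#'
#' Classification forest with half of the genes sampled at each split;
#' Gini importances are normalized to sum to one over genes with nonzero
#' importance.
#'
#' @param train an [expr_matrix] (log2 modeling scale, screened genes).
#' @param params an [rf_params] object.
#' @return list of class `rf_fit`: `forest`, `gini` (data.frame `gene_id`,
#'   `gini_importance`, ranked descending with gene-id tie-break),
#'   `params`.
#' @export
fit_rf <- function(train, params = rf_params()) {
  stopifnot(inherits(train, "expr_matrix"))
  x <- model_matrix(train)
  y <- class_labels(train)
  if (length(unique(y)) < 2)
    stop("training data must contain both classes", call. = FALSE)
  set.seed(params$seed)
  forest <- rf_fit_raw(x, y, params)
  imp <- forest$importance[, "MeanDecreaseGini"]
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  ord <- order(-imp, names(imp))
  gini <- data.frame(gene_id = names(imp)[ord],
                     gini_importance = unname(imp[ord]),
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(forest = forest, gini = gini, params = params),
            class = "rf_fit")
}

#' Confirm top random-forest genes by permutation importance and refit
#'
#' Permutation AUC-drop importance (same engine as the SVM track) is
#' computed for the `top_k_examine` genes by Gini rank on training data;
#' the final panel is the `top_k_final` genes by Gini among those with
#' strictly positive permutation importance (shrinking with a warning if
#' fewer qualify). A reduced forest is refit on the panel.
#'
#' @param rf an `rf_fit` from [fit_rf].
#' @param train the training [expr_matrix] used for the fit.
#' @param params an [rf_params] object.
#' @return list of class `rf_panel`: `panel` (character), `importance`
#'   (permutation importance data.frame), `forest` (reduced), `std`,
#'   `gini`.
#' @export
confirm_and_reduce <- function(rf, train, params = rf_params()) {
  stopifnot(inherits(rf, "rf_fit"), inherits(train, "expr_matrix"))
  examine <- head(rf$gini$gene_id, params$top_k_examine)
  x <- model_matrix(train)[, examine, drop = FALSE]
  y <- class_labels(train)
  imp <- permutation_importance(
    x, y, examine,
    fit_fun = function(xt, yt) rf_fit_raw(xt, yt, params),
    score_fun = rf_prob_f,
    n_permutations = params$n_permutations, seed = params$seed)
  positive <- imp$gene_id[imp$retained]
  panel <- head(rf$gini$gene_id[rf$gini$gene_id %in% positive],
                params$top_k_final)
  if (length(panel) < params$top_k_final)
    warning("only ", length(panel),
            " gene(s) with positive permutation importance; panel shrunk")
  reduced <- NULL
  if (length(panel) >= 1) {
    set.seed(params$seed)
    reduced <- rf_fit_raw(model_matrix(train)[, panel, drop = FALSE], y,
                          params)
  }
  structure(list(panel = panel, importance = imp, forest = reduced,
                 gini = rf$gini),
            class = "rf_panel")
}

#' Predict fibrosis probabilities from a reduced random forest
#'
#' The score is the fraction of trees voting for the fibrosis class.
#'
#' @param model an `rf_panel` from [confirm_and_reduce].
#' @param m an [expr_matrix] on the training (log2) scale.
#' @return data.frame: `sample_id`, `score` (probability of F),
#'   `predicted`, `truth`.
#' @export
predict_rf <- function(model, m) {
  stopifnot(inherits(model, "rf_panel"), inherits(m, "expr_matrix"))
  if (is.null(model$forest))
    stop("empty panel: no reduced forest to predict from", call. = FALSE)
  x <- model_matrix(m)[, model$panel, drop = FALSE]
  prob <- rf_prob_f(model$forest, x)
  data.frame(sample_id = m$samples$sample_id, score = unname(prob),
             predicted = ifelse(prob >= 0.5, "F", "WH"),
             truth = m$samples$condition,
             stringsAsFactors = FALSE, row.names = NULL)
}
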