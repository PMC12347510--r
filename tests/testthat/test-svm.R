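test_that("linear SVM ranking puts a separating gene first", {
  sim <- generate_expression(sim_spec(n_genes = 200, n_planted_f = 1,
                                      n_planted_wh = 0, effect_size = 4,
                                      seed = 7))
  m <- prep_screened(sim)
  rk <- rank_linear_svm(m, svm_params(seed = 7))
  expect_equal(rk$gene_id[1], sim$truth$gene_id)
  # agreement with a univariate AUC oracle on the winner
  y <- class_labels(m)
  auc_by_gene <- apply(m$values, 1, function(v) max(auc_score(y, v),
                                                    1 - auc_score(y, v)))
  expect_equal(rk$gene_id[1], names(which.max(auc_by_gene)))
})

test_that("duplicated genes share relevance and ties break by id", {
  set.seed(3)
  base <- c(rnorm(9, 0), rnorm(9, 3))
  vals <- rbind(dupA = base, dupB = base,
                noise1 = rnorm(18), noise2 = rnorm(18))
  m <- toy_matrix(vals, unit = "log2(TPM+1)",
                  condition = rep(c("WH", "F"), each = 9))
  rk <- rank_linear_svm(m, svm_params(seed = 1))
  wA <- rk$abs_weight[rk$gene_id == "dupA"]
  wB <- rk$abs_weight[rk$gene_id == "dupB"]
  expect_equal(wA, wB, tolerance = 1e-6)
  expect_equal(rk$gene_id[1:2], c("dupA", "dupB"))  # id tie-break
})

test_that("ranking is invariant to sample order", {
  sim <- generate_expression(sim_spec(n_genes = 80, n_planted_f = 2,
                                      n_planted_wh = 0, seed = 4))
  m <- prep_screened(sim)
  perm <- sample(ncol(m$values))
  mp <- m[, perm]
  r1 <- rank_linear_svm(m, svm_params(seed = 1))
  r2 <- rank_linear_svm(mp, svm_params(seed = 1))
  expect_equal(setNames(r1$abs_weight, r1$gene_id)[sort(r1$gene_id)],
               setNames(r2$abs_weight, r2$gene_id)[sort(r1$gene_id)],
               tolerance = 1e-2)
})

test_that("permutation importance behaves at its analytic anchors", {
  set.seed(5)
  n <- 18
  y <- rep(c(0, 1), each = 9)
  strong <- c(rnorm(9, 0, 0.5), rnorm(9, 6, 0.5))
  x <- cbind(strong = strong, null = rnorm(n))
  fit_fun <- function(xt, yt) fibrosig:::svm_fit_raw(xt, yt, "linear", 1)
  score_fun <- function(mod, xn) -fibrosig:::svm_decision_wh(mod, xn)

  # gene absent from the model's features scores exactly 0
  imp <- permutation_importance(x, y, c("strong", "null", "ghost"),
                                fit_fun, score_fun,
                                n_permutations = 30, seed = 2)
  expect_equal(imp$mean_auc_drop[imp$gene_id == "ghost"], 0)
  expect_false(imp$retained[imp$gene_id == "ghost"])

  # a lone perfectly separating gene loses about baseline - 0.5
  x1 <- cbind(strong = strong)
  imp1 <- permutation_importance(x1, y, "strong", fit_fun, score_fun,
                                 n_permutations = 60, seed = 3)
  base <- attr(imp1, "baseline_auc")
  expect_equal(base, 1)
  expect_equal(imp1$mean_auc_drop[1], 0.5, tolerance = 0.1)

  # a label-independent gene hovers near zero importance
  drops <- sapply(1:10, function(s) {
    set.seed(100 + s)
    xn <- cbind(strong = strong, null = rnorm(n))
    imp <- permutation_importance(xn, y, "null", fit_fun, score_fun,
                                  n_permutations = 40, seed = s)
    imp$mean_auc_drop[1]
  })
  expect_lt(abs(mean(drops)), 0.05)
})

test_that("calibrated RBF-SVM separates a planted panel on holdout", {
  sim <- generate_expression(sim_spec(n_genes = 100, n_planted_f = 3,
                                      n_planted_wh = 0, effect_size = 4,
                                      seed = 9))
  tpm <- fpkm_to_tpm(sim$matrix)
  sp <- make_holdout_split(tpm, 5, seed = 9)
  tr <- log_transform(sp$train)
  ho <- log_transform(sp$holdout)
  panel <- sim$truth$gene_id
  model <- fit_calibrated_rbf(tr, panel, svm_params(seed = 9))
  pred <- predict_rbf(model, ho)
  y <- class_labels(sp$holdout)
  expect_equal(auc_score(y, pred$score), 1)
  # probabilities land on the correct side of 0.5 for every sample
  expect_true(all(pred$predicted == pred$truth))
  # decision values: positive side is WH
  expect_true(all(pred$decision_value[pred$truth == "WH"] >
                    min(pred$decision_value[pred$truth == "F"])))
  # calibrated probabilities are monotone in the decision value
  expect_true(all(diff(pred$prob_WH[order(pred$decision_value)]) >=
                    -1e-12))
})

test_that("permuted labels give chance-level holdout performance", {
  aucs <- sapply(1:6, function(s) {
    sim <- generate_expression(sim_spec(n_genes = 100, n_planted_f = 3,
                                        n_planted_wh = 0, effect_size = 4,
                                        seed = s))
    tpm <- fpkm_to_tpm(sim$matrix)
    sp <- make_holdout_split(tpm, 5, seed = s)
    tr <- log_transform(sp$train)
    set.seed(1000 + s)
    tr$samples$condition <- sample(tr$samples$condition)
    model <- suppressWarnings(
      fit_calibrated_rbf(tr, sim$truth$gene_id, svm_params(seed = s)))
    pred <- predict_rbf(model, log_transform(sp$holdout))
    auc_score(class_labels(sp$holdout), pred$score)
  })
  expect_gt(mean(aucs), 0.2)
  expect_lt(mean(aucs), 0.8)
})
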