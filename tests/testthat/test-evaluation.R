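test_that("auc_score equals the all-pairs brute-force value", {
  expect_equal(auc_score(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.2)), 0.75)
  expect_equal(auc_score(c(0, 0, 1, 1), c(1, 2, 3, 4)), 1)
  expect_equal(auc_score(c(0, 1, 0, 1), rep(0.3, 4)), 0.5)
  set.seed(21)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(rnorm(n), sample(0:2, 1))  # induce ties
    expect_identical(auc_score(labels, scores),
                     auc_bruteforce(labels, scores))
  }
  expect_error(auc_score(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("auc_score agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(8)
  for (i in 1:5) {
    labels <- rbinom(20, 1, 0.5); labels[1:2] <- c(0, 1)
    scores <- rnorm(20)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_score(labels, scores), ref)
  }
})

test_that("confusion matrix, accuracy and curves are consistent", {
  # all correct on a 5 + 5 holdout
  lab <- rep(c(0, 1), each = 5)
  sc <- c(runif(5, 0, 0.4), runif(5, 0.6, 1))
  rep1 <- confusion_and_pr(lab, scores = sc)
  expect_equal(rep1$auc, 1)
  expect_equal(rep1$accuracy, 1)
  expect_equal(unname(diag(rep1$confusion)), c(5, 5))

  # one WH sample misclassified as F
  pred <- c(1, 0, 0, 0, 0, 1, 1, 1, 1, 1)
  rep2 <- confusion_and_pr(lab, pred, sc)
  expect_equal(unname(rep2$confusion["WH", ]), c(4, 1))
  expect_equal(rep2$accuracy, 0.9)
  expect_equal(rep2$accuracy,
               sum(diag(rep2$confusion)) / sum(rep2$confusion))

  # degenerate: everything called F
  rep3 <- confusion_and_pr(lab, rep(1, 10), rep(0.9, 10))
  expect_equal(unname(rep3$confusion[, "WH"]), c(0, 0))
  expect_equal(rep3$accuracy, 0.5)

  # ROC endpoints
  expect_equal(unlist(rep1$roc_points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(rep1$roc_points[nrow(rep1$roc_points), ]),
               c(fpr = 1, tpr = 1))
})

test_that("per-gene ROC reports orientation-corrected AUC", {
  set.seed(4)
  vals <- rbind(up = c(rnorm(5, 0), rnorm(5, 6)),
                down = c(rnorm(5, 6), rnorm(5, 0)),
                flat = rep(2, 10),
                noisy = rnorm(10))
  m <- toy_matrix(vals, unit = "log2(TPM+1)",
                  condition = rep(c("WH", "F"), each = 5))
  up <- per_gene_roc(m, "up")
  expect_equal(up$auc, 1)
  expect_equal(up$direction, "F-high")
  down <- per_gene_roc(m, "down")
  expect_equal(down$auc, 1)
  expect_true(down$flipped)
  expect_equal(per_gene_roc(m, "flat")$auc, 0.5)
  # orientation identity auc(x) = 1 - auc(-x)
  y <- class_labels(m)
  expect_equal(auc_score(y, vals["noisy", ]),
               1 - auc_score(y, -vals["noisy", ]))
})

test_that("pooled log2 fold change follows the pooled-mean ratio", {
  vals <- rbind(g1 = c(rep(2, 9), rep(8, 9)),    # WH mean 2, F mean 8
                g2 = rep(5, 18),
                g3 = c(rep(0, 9), rep(7, 9)))
  m <- toy_matrix(vals, unit = "FPKM",
                  condition = rep(c("WH", "F"), each = 9))
  r1 <- pooled_log2fc(m, "g1")
  expect_equal(r1$log2fc, 2)
  expect_equal(r1$mean_F, 8)
  r2 <- pooled_log2fc(m, "g2")
  expect_equal(r2$log2fc, 0)
  # swapping the classes negates the fold change
  sw <- m; sw$samples$condition <- rev(sw$samples$condition)
  expect_equal(pooled_log2fc(sw, "g1")$log2fc, -2)
  # zero pooled mean triggers the offset guard instead of -Inf
  r3 <- pooled_log2fc(m, "g3")
  expect_true(r3$offset_used)
  expect_true(is.finite(r3$log2fc))
})

test_that("PCA projection separates planted classes and is well-formed", {
  sim <- generate_expression(sim_spec(n_genes = 300, effect_size = 4,
                                      seed = 6))
  lg <- log_transform(fpkm_to_tpm(sim$matrix))
  pca <- pca_projection(lg)
  ve <- attr(pca, "var_explained")
  expect_true(all(ve >= 0) && sum(ve) <= 100)
  # PC1 should separate the two conditions given strong planted effects
  m1 <- mean(pca$PC1[pca$condition == "F"])
  m2 <- mean(pca$PC1[pca$condition == "WH"])
  expect_true(abs(m1 - m2) >
                2 * max(sd(pca$PC1[pca$condition == "F"]),
                        sd(pca$PC1[pca$condition == "WH"])))
  # duplicated samples get identical coordinates
  dvals <- lg$values[, c(1, 1, 2, 10, 11, 12)]
  colnames(dvals) <- paste0("s", 1:6)
  dup <- toy_matrix(dvals, unit = lg$unit,
                    condition = rep(c("WH", "F"), each = 3))
  pd <- pca_projection(dup)
  expect_equal(pd$PC1[1], pd$PC1[2])
  expect_equal(pd$PC2[1], pd$PC2[2])
})
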