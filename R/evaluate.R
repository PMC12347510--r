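#' Area under the ROC curve
#'
#' Probability that a positive sample scores above a negative one, with
#' ties counted half — computed from midranks (the Mann-Whitney identity),
#' which equals the trapezoidal area under the ROC curve.
#'
#' @param labels binary vector (1/TRUE = positive class; fibrosis in this
#'   package's convention).
#' @param scores numeric scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(labels, scores) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC curve as (FPR, TPR) points from (0,0) to (1,1), thresholds swept
# over the distinct score values in decreasing order.
roc_points <- function(labels, scores) {
  labels <- as.integer(as.logical(labels))
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  tp <- cumsum(lab); fp <- cumsum(1 - lab)
  last <- !duplicated(sc, fromLast = TRUE)  # one point per threshold
  data.frame(fpr = c(0, fp[last] / sum(labels == 0)),
             tpr = c(0, tp[last] / sum(labels == 1)))
}

# Precision-recall points over decreasing score thresholds.
pr_points <- function(labels, scores) {
  labels <- as.integer(as.logical(labels))
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  rec <- tp / sum(labels == 1)
  last <- !duplicated(sc, fromLast = TRUE)
  data.frame(recall = rec[last], precision = prec[last])
}

#' Held-out evaluation report: ROC, PR, AUC, confusion matrix
#'
#' @param labels binary truth (1 = F).
#' @param predicted predicted class as binary (1 = F); if `NULL`, derived
#'   from `scores >= threshold`.
#' @param scores numeric scores oriented toward the positive class
#'   (e.g. probability of F).
#' @param threshold classification threshold on `scores` (default 0.5).
#' @return list of class `eval_report`: `roc_points`, `auc`, `pr_points`,
#'   `confusion` (2x2, rows = truth WH/F, cols = prediction), `accuracy`.
#' @export
confusion_and_pr <- function(labels, predicted = NULL, scores,
                             threshold = 0.5) {
  labels <- as.integer(as.logical(labels))
  if (is.null(predicted)) predicted <- as.integer(scores >= threshold)
  predicted <- as.integer(as.logical(predicted))
  lv <- c("WH", "F")
  conf <- table(truth = factor(lv[labels + 1], levels = lv),
                prediction = factor(lv[predicted + 1], levels = lv))
  conf <- unclass(conf)
  structure(list(roc_points = roc_points(labels, scores),
                 auc = auc_score(labels, scores),
                 pr_points = pr_points(labels, scores),
                 confusion = conf,
                 accuracy = sum(diag(conf)) / sum(conf)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: AUC = %.3f, accuracy = %.3f\n", x$auc,
              x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Single-gene ROC analysis on a held-out set
#'
#' Uses a gene's expression directly as the classifier score. Orientation
#' is resolved so the reported AUC is at least 0.5, with a flag giving the
#' direction (`"F-high"` when fibrosis samples express more).
#'
#' @param holdout an [expr_matrix] containing the gene and both classes.
#' @param gene gene id.
#' @return list: `gene_id`, `auc` (>= 0.5), `direction`, `flipped`.
#' @export
per_gene_roc <- function(holdout, gene) {
  stopifnot(inherits(holdout, "expr_matrix"))
  if (!gene %in% rownames(holdout$values))
    stop("gene not found: ", gene, call. = FALSE)
  x <- holdout$values[gene, ]
  y <- class_labels(holdout)
  if (sd(x) == 0)
    return(list(gene_id = gene, auc = 0.5, direction = "constant",
                flipped = FALSE))
  a <- auc_score(y, x)
  flipped <- a < 0.5
  list(gene_id = gene, auc = max(a, 1 - a),
       direction = if (flipped) "WH-high" else "F-high", flipped = flipped)
}

#' Pooled log2 fold change of one gene (F relative to WH)
#'
#' Means are pooled over all samples of each condition (all days); the
#' fold change is `log2(mean_F / mean_WH)`. When one pooled mean is zero
#' the configured offset is added inside the ratio (to both means) and the
#' record is flagged. A Welch test on per-sample `log2(value + offset)`
#' accompanies the estimate, as do 95% t confidence intervals of the
#' per-condition log2 means.
#'
#' @param m an [expr_matrix] on a linear scale (typically FPKM).
#' @param gene gene id.
#' @param offset pseudo-count used for the zero-mean guard, the Welch test
#'   scale and the CIs (default 1).
#' @return list: `gene_id`, `mean_F`, `mean_WH`, `log2fc`, `p_value`,
#'   `ci_F`, `ci_WH` (95% CI on log2 scale), `offset_used`.
#' @export
pooled_log2fc <- function(m, gene, offset = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!m$unit %in% c("FPKM", "TPM"))
    stop("pooled_log2fc expects a linear-scale matrix", call. = FALSE)
  if (!gene %in% rownames(m$values))
    stop("gene not found: ", gene, call. = FALSE)
  x <- m$values[gene, ]
  cond <- m$samples$condition
  mF <- mean(x[cond == "F"]); mWH <- mean(x[cond == "WH"])
  offset_used <- mF == 0 || mWH == 0
  log2fc <- if (offset_used) log2((mF + offset) / (mWH + offset))
            else log2(mF / mWH)
  lx <- log2(x + offset)
  wt <- welch_t(lx[cond == "F"], lx[cond == "WH"])
  ci <- function(v) {
    n <- length(v)
    half <- qt(0.975, n - 1) * sd(v) / sqrt(n)
    c(mean(v) - half, mean(v) + half)
  }
  list(gene_id = gene, mean_F = mF, mean_WH = mWH, log2fc = log2fc,
       p_value = wt$p, ci_F = ci(lx[cond == "F"]),
       ci_WH = ci(lx[cond == "WH"]), offset_used = offset_used)
}

#' PCA projection of samples for quality control
#'
#' Gene-wise mean-centered principal component analysis of the (log-scale)
#' expression matrix; returns per-sample coordinates on the first two
#' components and the percent variance each explains.
#'
#' @param m an [expr_matrix] (log2 scale recommended).
#' @return data.frame with `sample_id`, `condition`, `day`, `PC1`, `PC2`;
#'   attribute `var_explained` holds the two percentages.
#' @export
pca_projection <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (ncol(m$values) < 3)
    stop("PCA needs at least 3 samples", call. = FALSE)
  pc <- prcomp(t(m$values), center = TRUE, scale. = FALSE)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  out <- data.frame(sample_id = m$samples$sample_id,
                    condition = m$samples$condition,
                    day = m$samples$day,
                    PC1 = pc$x[, 1], PC2 = pc$x[, 2],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "var_explained") <- ve[1:2]
  out
}
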