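#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value. Kept as a plain function of two
#' vectors so the gene screen and the qPCR module share one definition.
#'
#' @param x,y numeric vectors with at least two values each.
#' @return list with `t`, `df`, `p`. When both sample variances are zero
#'   the statistic is undefined and all three are `NaN`.
#' @export
welch_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2)
    stop("welch_t needs at least two observations per group", call. = FALSE)
  v1 <- var(x); v2 <- var(y)
  if (v1 == 0 && v2 == 0)
    return(list(t = NaN, df = NaN, p = NaN))
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Row-wise Welch test: mat is genes x samples, idx1/idx2 column indices.
# Vectorized over genes; rows where both group variances are 0 get NaN.
row_welch <- function(mat, idx1, idx2) {
  x <- mat[, idx1, drop = FALSE]
  y <- mat[, idx2, drop = FALSE]
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  degen <- v1 == 0 & v2 == 0
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  t[degen] <- NaN; df[degen] <- NaN
  p <- 2 * pt(-abs(t), df)
  data.frame(mean1 = m1, mean2 = m2, t = t, df = df, p = p,
             degenerate = degen, row.names = rownames(mat))
}

#' Parameters for the univariate gene screen
#'
#' @param diff_threshold minimum absolute WH-F mean difference a gene must
#'   show to be kept (default 1, on the scale chosen by `diff_scale`).
#' @param alpha Welch p-value cutoff (default 0.05). No multiplicity
#'   correction is applied at this stage.
#' @param diff_scale scale on which the mean difference is computed:
#'   `"tpm"` (literal TPM units, the default) or `"log2tpm"`.
#' @param test_scale scale on which the Welch test runs: `"log2tpm"`
#'   (variance-stabilized, the default) or `"tpm"`.
#' @param offset pseudo-count for the log2 scale (default 1).
#' @return a `screen_params` list.
#' @export
screen_params <- function(diff_threshold = 1, alpha = 0.05,
                          diff_scale = c("tpm", "log2tpm"),
                          test_scale = c("log2tpm", "tpm"),
                          offset = 1) {
  diff_scale <- match.arg(diff_scale)
  test_scale <- match.arg(test_scale)
  stopifnot(diff_threshold >= 0, alpha > 0, alpha <= 1, offset > 0)
  structure(list(diff_threshold = diff_threshold, alpha = alpha,
                 diff_scale = diff_scale, test_scale = test_scale,
                 offset = offset),
            class = "screen_params")
}

#' Univariate Welch + mean-difference gene screen
#'
#' Reduces the transcriptome to candidate features: a gene is kept when
#' its absolute WH-F mean difference reaches `diff_threshold` AND its
#' two-sided Welch p-value is at most `alpha`. Genes with zero variance
#' in both conditions are degenerate (p undefined) and dropped with a
#' warning.
#'
#' @param m an [expr_matrix] with `unit = "TPM"`, at least two samples per
#'   condition.
#' @param params a [screen_params] object.
#' @return data.frame (one row per gene): `gene_id`, `mean_WH`, `mean_F`,
#'   `mean_diff` (signed, WH - F, on `diff_scale`), `t`, `df`, `p`
#'   (on `test_scale`), `kept`.
#' @export
screen_genes <- function(m, params = screen_params()) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$unit != "TPM")
    stop("screen_genes expects a TPM matrix (run fpkm_to_tpm first)",
         call. = FALSE)
  cond <- m$samples$condition
  if (sum(cond == "WH") < 2 || sum(cond == "F") < 2)
    stop("need at least 2 samples per condition to screen", call. = FALSE)
  iwh <- which(cond == "WH"); ifb <- which(cond == "F")
  log2m <- log2(m$values + params$offset)
  diff_mat <- if (params$diff_scale == "tpm") m$values else log2m
  test_mat <- if (params$test_scale == "log2tpm") log2m else m$values
  mean_WH <- rowMeans(diff_mat[, iwh, drop = FALSE])
  mean_F <- rowMeans(diff_mat[, ifb, drop = FALSE])
  wt <- row_welch(test_mat, iwh, ifb)
  mean_diff <- mean_WH - mean_F
  kept <- !wt$degenerate &
    abs(mean_diff) >= params$diff_threshold &
    wt$p <= params$alpha
  kept[is.na(kept)] <- FALSE
  if (any(wt$degenerate))
    warning(sum(wt$degenerate),
            " gene(s) with zero variance in both conditions dropped")
  res <- data.frame(gene_id = rownames(m$values),
                    mean_WH = mean_WH, mean_F = mean_F,
                    mean_diff = mean_diff,
                    t = wt$t, df = wt$df, p = wt$p, kept = kept,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "n_input") <- nrow(res)
  attr(res, "n_kept") <- sum(res$kept)
  res
}
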