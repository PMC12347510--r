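#' Read a long-format qPCR Ct table
#'
#' @param path CSV with columns `experiment,condition,gene,technical_rep,ct`.
#' @return validated data.frame.
#' @export
read_ct_table <- function(path) {
  ct <- read.csv(path, stringsAsFactors = FALSE)
  validate_ct_table(ct)
}

validate_ct_table <- function(ct) {
  req <- c("experiment", "condition", "gene", "technical_rep", "ct")
  if (!all(req %in% names(ct)))
    stop("Ct table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (!all(ct$condition %in% c("WH", "F")))
    stop("Ct table conditions must be WH or F", call. = FALSE)
  if (any(ct$ct <= 0)) stop("Ct values must be positive", call. = FALSE)
  ct
}

#' Relative quantification by the delta-delta-Ct method
#'
#' Technical replicates are averaged to one Ct per (experiment,
#' condition, gene). Delta Ct is target minus reference (GAPDH by
#' default); the second delta is taken within experiment against the
#' baseline condition, so the baseline's fold change is exactly 1 and
#' plate-wide Ct shifts cancel. Fold changes are `2^-ddCt` (amplification
#' efficiency fixed at 2). Per gene, the mean fold and SEM over the
#' biological replicates (experiments) are reported with a two-sided
#' Welch test comparing the conditions' delta-Ct values.
#'
#' @param ct a Ct table (see [read_ct_table]).
#' @param target_genes genes to quantify (default: all non-reference
#'   genes present).
#' @param reference_gene housekeeping gene (default `"GAPDH"`).
#' @param baseline_condition condition folds are expressed against
#'   (default `"WH"`).
#' @return data.frame (one row per gene): `gene`, `mean_fold` (comparison
#'   condition vs baseline), `sem`, `p_value`, plus `fold_exp<k>`
#'   per-experiment folds.
#' @export
ddct_analysis <- function(ct, target_genes = NULL,
                          reference_gene = "GAPDH",
                          baseline_condition = "WH") {
  ct <- validate_ct_table(ct)
  other <- setdiff(unique(ct$condition), baseline_condition)
  if (length(other) != 1)
    stop("expected exactly one non-baseline condition", call. = FALSE)
  if (is.null(target_genes))
    target_genes <- setdiff(unique(ct$gene), reference_gene)
  # mean over technical replicates
  agg <- aggregate(ct ~ experiment + condition + gene, data = ct,
                   FUN = mean)
  ref <- agg[agg$gene == reference_gene, ]
  if (nrow(ref) == 0)
    stop("reference gene ", reference_gene, " not in table", call. = FALSE)
  exps <- sort(unique(agg$experiment))
  combos <- expand.grid(experiment = exps,
                        condition = c(baseline_condition, other))
  missing_ref <- combos[!paste(combos$experiment, combos$condition) %in%
                          paste(ref$experiment, ref$condition), ]
  if (nrow(missing_ref) > 0)
    stop("reference gene missing for experiment(s): ",
         paste(unique(missing_ref$experiment), collapse = ", "),
         call. = FALSE)
  ref_ct <- function(e, cond)
    ref$ct[ref$experiment == e & ref$condition == cond]
  res <- lapply(target_genes, function(g) {
    sub <- agg[agg$gene == g, ]
    dct <- sapply(exps, function(e) {
      sapply(c(baseline_condition, other), function(cond) {
        v <- sub$ct[sub$experiment == e & sub$condition == cond]
        if (length(v) != 1) NA_real_ else v - ref_ct(e, cond)
      })
    })  # 2 x n_exp matrix: row 1 baseline, row 2 comparison
    ddct <- dct[2, ] - dct[1, ]
    folds <- 2^(-ddct)
    wt <- welch_t(dct[2, ], dct[1, ])
    # constant, identical delta-Ct in both conditions: no evidence at all
    if (is.nan(wt$p) && isTRUE(all.equal(dct[2, ], dct[1, ])))
      wt$p <- 1
    out <- data.frame(gene = g, mean_fold = mean(folds),
                      sem = sd(folds) / sqrt(length(folds)),
                      p_value = wt$p, stringsAsFactors = FALSE)
    for (k in seq_along(exps))
      out[[paste0("fold_exp", exps[k])]] <- folds[k]
    out
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
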