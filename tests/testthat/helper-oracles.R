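# Independent oracles and fixture builders shared by the tests.

# AUC by exhaustive enumeration of positive-negative pairs.
auc_bruteforce <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# Weighted-KS running sum by an explicit position-by-position loop,
# independent of the package's vectorized implementation.
es_bruteforce <- function(metric, hit, p_w) {
  n <- length(metric)
  w <- abs(metric)^p_w
  hit_sum <- sum(w[hit])
  n_miss <- sum(!hit)
  run <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- if (hit[i]) acc + w[i] / hit_sum else acc - 1 / n_miss
    run[i] <- acc
  }
  run[which.max(abs(run))]
}

# Build a small expr_matrix from a plain matrix; condition split in half.
toy_matrix <- function(vals, unit = "TPM",
                       condition = rep(c("WH", "F"),
                                       each = ncol(vals) / 2)) {
  if (is.null(rownames(vals)))
    rownames(vals) <- sprintf("g%02d", seq_len(nrow(vals)))
  if (is.null(colnames(vals)))
    colnames(vals) <- sprintf("s%02d", seq_len(ncol(vals)))
  samples <- data.frame(sample_id = colnames(vals), condition = condition,
                        day = rep_len(1:3, ncol(vals)),
                        replicate = seq_len(ncol(vals)))
  expr_matrix(vals, samples, unit = unit)
}

# Screened log2 modeling matrix from a simulated dataset, full design.
prep_screened <- function(sim, params = screen_params()) {
  tpm <- fpkm_to_tpm(sim$matrix)
  scr <- suppressWarnings(screen_genes(tpm, params))
  log_transform(tpm)[scr$gene_id[scr$kept], ]
}
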