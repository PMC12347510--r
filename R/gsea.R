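#' Parameters for per-candidate-gene set enrichment
#'
#' @param weight_exponent exponent applied to |ranking metric| in the
#'   weighted Kolmogorov-Smirnov running sum (default 1; 0 gives the
#'   classic unweighted KS statistic).
#' @param n_permutations random same-size gene sets drawn for the NES/FDR
#'   null (default 1000). Gene-set permutation is used rather than
#'   phenotype permutation, which is infeasible at n = 18.
#' @param min_set_size,max_set_size set-size limits after intersecting
#'   with the ranked list (defaults 5 / 500).
#' @param seed integer seed.
#' @return a `gsea_params` list.
#' @export
gsea_params <- function(weight_exponent = 1, n_permutations = 1000,
                        min_set_size = 5, max_set_size = 500, seed = 1) {
  stopifnot(weight_exponent >= 0, n_permutations >= 1,
            min_set_size >= 1, min_set_size <= max_set_size)
  structure(list(weight_exponent = weight_exponent,
                 n_permutations = n_permutations,
                 min_set_size = min_set_size, max_set_size = max_set_size,
                 seed = seed),
            class = "gsea_params")
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (`set<TAB>description<TAB>gene1<TAB>gene2...`).
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) fgsea::gmtPathways(path)

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Rank the transcriptome by correlation with a candidate gene
#'
#' Every other gene is scored by the Pearson correlation of its expression
#' with the candidate's across all samples, and ranked in descending
#' order (ties broken by gene id). Genes with zero variance are
#' uninformative and scored 0.
#'
#' @param m an [expr_matrix] on the log2 scale with at least 3 samples.
#' @param candidate gene id present in `m`.
#' @param params a [gsea_params] object (unused fields ignored).
#' @return data.frame: `gene_id`, `metric`, ranked.
#' @export
rank_for_candidate <- function(m, candidate, params = gsea_params()) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!candidate %in% rownames(m$values))
    stop("candidate gene not found: ", candidate, call. = FALSE)
  if (ncol(m$values) < 3)
    stop("need at least 3 samples to rank by correlation", call. = FALSE)
  cand <- m$values[candidate, ]
  if (sd(cand) == 0)
    stop("candidate gene has zero variance", call. = FALSE)
  others <- m$values[rownames(m$values) != candidate, , drop = FALSE]
  metric <- suppressWarnings(drop(cor(t(others), cand)))
  metric[is.na(metric)] <- 0
  ord <- order(-metric, names(metric))
  data.frame(gene_id = names(metric)[ord], metric = unname(metric[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Core weighted-KS running sum. ranked_metric: named metric vector in
# rank order; hit: logical of the same length. Returns the running sum.
gsea_running_sum <- function(ranked_metric, hit, weight_exponent) {
  w <- abs(ranked_metric)^weight_exponent
  hit_sum <- sum(w[hit])
  n_miss <- sum(!hit)
  inc <- numeric(length(ranked_metric))
  if (hit_sum > 0) inc[hit] <- w[hit] / hit_sum
  else inc[hit] <- 1 / sum(hit)       # all-zero weights: fall back to KS
  if (n_miss > 0) inc[!hit] <- -1 / n_miss
  cumsum(inc)
}

#' Weighted-KS enrichment score for one gene set
#'
#' Walks the ranked list accumulating |metric|^p / (sum over set hits)
#' at set members and -1/(N - N_hits) elsewhere; the enrichment score is
#' the signed extremum of largest magnitude, and the leading edge is the
#' set members at or before the extremum (at or after it for negative
#' scores).
#'
#' @param ranked data.frame from [rank_for_candidate] (`gene_id`,
#'   `metric`, in rank order).
#' @param gene_set character vector of gene ids.
#' @param params a [gsea_params] object.
#' @return list of class `enrichment_result`: `es`, `running_sum`,
#'   `leading_edge`, `size` (set members in the ranked list), or `NULL`
#'   if the intersected set violates the size limits.
#' @export
enrichment_score <- function(ranked, gene_set, params = gsea_params()) {
  hit <- ranked$gene_id %in% gene_set
  n_hit <- sum(hit)
  if (n_hit < params$min_set_size || n_hit > params$max_set_size)
    return(NULL)
  if (n_hit == length(hit)) return(NULL)  # no misses: score undefined
  rs <- gsea_running_sum(setNames(ranked$metric, ranked$gene_id), hit,
                         params$weight_exponent)
  i_ext <- which.max(abs(rs))
  es <- rs[i_ext]
  le <- if (es >= 0) ranked$gene_id[seq_len(i_ext)][hit[seq_len(i_ext)]]
        else ranked$gene_id[i_ext:length(rs)][hit[i_ext:length(rs)]]
  structure(list(es = es, running_sum = rs, leading_edge = le,
                 size = n_hit),
            class = "enrichment_result")
}

#' Normalized enrichment scores and FDR over a gene-set collection
#'
#' For each eligible set, a null ES distribution is built from
#' `n_permutations` random gene sets of the same size drawn from the
#' ranked list. NES is the ES divided by the mean |null ES| of the same
#' sign, null NES values are normalized the same way, and the FDR for a
#' positively enriched set is the pooled-null tail fraction at its NES
#' divided by the observed tail fraction (capped to \[0, 1\]). Results
#' are filtered to NES > 0 and ordered by FDR — the positive-enrichment
#' report used for candidate-gene interpretation.
#'
#' @param ranked data.frame from [rank_for_candidate].
#' @param gene_sets named list of character vectors.
#' @param params a [gsea_params] object.
#' @return data.frame: `set_name`, `size`, `es`, `nes`, `fdr`,
#'   `leading_edge` (comma-separated); attribute `all_results` holds the
#'   unfiltered table including negative NES.
#' @export
nes_and_fdr <- function(ranked, gene_sets, params = gsea_params()) {
  set.seed(params$seed)
  scored <- lapply(gene_sets, enrichment_score, ranked = ranked,
                   params = params)
  keep <- !vapply(scored, is.null, logical(1))
  if (!any(keep))
    return(data.frame(set_name = character(), size = integer(),
                      es = numeric(), nes = numeric(), fdr = numeric(),
                      leading_edge = character()))
  scored <- scored[keep]
  metric <- setNames(ranked$metric, ranked$gene_id)
  n_genes <- nrow(ranked)
  null_es_for_size <- function(size) {
    vapply(seq_len(params$n_permutations), function(i) {
      hit <- logical(n_genes)
      hit[sample(n_genes, size)] <- TRUE
      rs <- gsea_running_sum(metric, hit, params$weight_exponent)
      rs[which.max(abs(rs))]
    }, numeric(1))
  }
  sizes <- vapply(scored, `[[`, integer(1), "size")
  null_by_size <- lapply(unique(sizes), null_es_for_size)
  names(null_by_size) <- as.character(unique(sizes))
  normalize <- function(es, null) {
    pos_mean <- mean(null[null > 0]); neg_mean <- mean(abs(null[null < 0]))
    nes <- ifelse(es >= 0, es / pos_mean, es / neg_mean)
    null_nes <- ifelse(null >= 0, null / pos_mean, null / neg_mean)
    list(nes = nes, null_nes = null_nes)
  }
  norm <- Map(function(sc, sz) {
    nl <- normalize(sc$es, null_by_size[[as.character(sz)]])
    if (!is.finite(nl$nes)) {
      warning("degenerate null for set size ", sz, "; FDR set to 1")
      nl$nes <- 0
    }
    nl
  }, scored, sizes)
  obs_nes <- vapply(norm, function(z) z$nes, numeric(1))
  pooled_null <- unlist(lapply(norm, function(z)
    z$null_nes[is.finite(z$null_nes)]))
  fdr <- vapply(obs_nes, function(nes) {
    if (nes > 0) {
      num <- mean(pooled_null >= nes)
      den <- mean(obs_nes >= nes)
    } else {
      num <- mean(pooled_null <= nes)
      den <- mean(obs_nes <= nes)
    }
    min(1, max(0, if (den == 0) 1 else num / den))
  }, numeric(1))
  out <- data.frame(
    set_name = names(scored), size = sizes,
    es = vapply(scored, `[[`, numeric(1), "es"),
    nes = obs_nes, fdr = fdr,
    leading_edge = vapply(scored, function(s)
      paste(s$leading_edge, collapse = ","), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  pos <- out[out$nes > 0, , drop = FALSE]
  pos <- pos[order(pos$fdr, pos$set_name), , drop = FALSE]
  rownames(pos) <- NULL
  attr(pos, "all_results") <- out
  pos
}
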