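#' Expression matrix container
#'
#' A light container for a gene-by-sample expression matrix together with
#' per-sample labels and a unit tag. Values are carried in `FPKM`, `TPM`,
#' or a log2-transformed unit (e.g. `"log2(TPM+1)"`); several downstream
#' operations check the tag so that, say, TPM conversion is not applied
#' twice.
#'
#' @param values numeric gene x sample matrix with rownames (gene ids) and
#'   colnames (sample ids). Must be non-negative for linear-scale units.
#' @param samples data.frame with one row per column of `values`, containing
#'   at least `sample_id`, `condition` (`"WH"` or `"F"`) and `day`
#'   (integer). Row order must match the column order of `values`.
#' @param unit character scalar, e.g. `"FPKM"`, `"TPM"`, `"log2(TPM+1)"`.
#'
#' @return an object of class `expr_matrix`: a list with elements `values`,
#'   `samples`, `unit`.
#' @export
expr_matrix <- function(values, samples, unit = "FPKM") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix", call. = FALSE)
  if (anyNA(values))
    stop("expression matrix contains missing values", call. = FALSE)
  samples <- as.data.frame(samples)
  req <- c("sample_id", "condition", "day")
  if (!all(req %in% names(samples)))
    stop("`samples` must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (nrow(samples) != ncol(values))
    stop("`samples` rows (", nrow(samples), ") != matrix columns (",
         ncol(values), ")", call. = FALSE)
  if (!identical(as.character(samples$sample_id), colnames(values)))
    stop("sample_id order must match matrix column order", call. = FALSE)
  if (!all(samples$condition %in% c("WH", "F")))
    stop("condition labels must be \"WH\" or \"F\"", call. = FALSE)
  if (unit %in% c("FPKM", "TPM") && any(values < 0))
    stop("negative values not allowed for unit ", unit, call. = FALSE)
  samples$condition <- as.character(samples$condition)
  samples$day <- as.integer(samples$day)
  structure(list(values = values, samples = samples, unit = unit),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  tab <- table(x$samples$condition)
  cat("  conditions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by genes and/or samples
#'
#' @param x an [expr_matrix].
#' @param i gene selector (indices, logical, or gene ids).
#' @param j sample selector (indices, logical, or sample ids).
#' @param ... ignored.
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(i) && !all(i %in% rownames(x$values)))
    stop("unknown gene id(s): ",
         paste(setdiff(i, rownames(x$values)), collapse = ", "), call. = FALSE)
  if (is.character(j)) j <- match(j, colnames(x$values))
  vals <- x$values[i, j, drop = FALSE]
  expr_matrix(vals, x$samples[j, , drop = FALSE], unit = x$unit)
}

#' Binary class labels for an expression matrix
#'
#' Fibrosis (`"F"`) is the positive class throughout the package.
#'
#' @param m an [expr_matrix].
#' @return integer vector, 1 for F samples, 0 for WH.
#' @export
class_labels <- function(m) as.integer(m$samples$condition == "F")

#' Load an expression matrix and its sample metadata from TSV files
#'
#' The matrix file is tab-separated with gene identifiers in the first
#' column and sample identifiers in the header; the metadata file maps
#' `sample_id` to `condition` (WH/F) and `day`. Samples are reordered to
#' the metadata order.
#'
#' @param matrix_path path to the expression TSV (FPKM values).
#' @param metadata_path path to the metadata TSV with header
#'   `sample_id  condition  day  replicate`.
#' @return an [expr_matrix] with `unit = "FPKM"`.
#' @export
load_expression <- function(matrix_path, metadata_path) {
  raw <- read.delim(matrix_path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
  meta <- read.delim(metadata_path, header = TRUE, sep = "\t",
                     check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(raw[[1]])
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids in ", matrix_path, call. = FALSE)
  vals <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- gene_ids
  if (!setequal(meta$sample_id, colnames(vals)))
    stop("metadata samples do not match matrix samples", call. = FALSE)
  vals <- vals[, as.character(meta$sample_id), drop = FALSE]
  if (anyNA(vals))
    stop("missing values in expression matrix", call. = FALSE)
  if (any(vals < 0))
    stop("negative FPKM values in ", matrix_path, call. = FALSE)
  expr_matrix(vals, meta, unit = "FPKM")
}

#' Convert FPKM to TPM
#'
#' Per sample, TPM is the FPKM value divided by the sample's FPKM column
#' sum, times 1e6, so every sample column sums to one million. This
#' normalizes simultaneously for gene length (inherited from FPKM) and
#' sequencing depth.
#'
#' @param m an [expr_matrix] with `unit = "FPKM"`.
#' @return an [expr_matrix] with `unit = "TPM"`.
#' @export
fpkm_to_tpm <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$unit != "FPKM")
    stop("fpkm_to_tpm expects unit FPKM, got ", m$unit, call. = FALSE)
  cs <- colSums(m$values)
  if (any(cs <= 0))
    stop("all-zero sample column(s): ",
         paste(colnames(m$values)[cs <= 0], collapse = ", "), call. = FALSE)
  vals <- sweep(m$values, 2, cs, "/") * 1e6
  expr_matrix(vals, m$samples, unit = "TPM")
}

#' Log2-transform expression values with a small offset
#'
#' @param m an [expr_matrix] on a linear scale (FPKM or TPM).
#' @param offset positive pseudo-count added before taking log2; the
#'   default 1 keeps zeros at zero.
#' @return an [expr_matrix] with unit `"log2(<unit>+<offset>)"`.
#' @export
log_transform <- function(m, offset = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!m$unit %in% c("FPKM", "TPM"))
    stop("log_transform expects a linear-scale unit, got ", m$unit,
         call. = FALSE)
  if (!is.numeric(offset) || length(offset) != 1 || offset <= 0)
    stop("`offset` must be a positive scalar", call. = FALSE)
  out <- expr_matrix(log2(m$values + offset), m$samples,
                     unit = sprintf("log2(%s+%g)", m$unit, offset))
  out
}

#' Split samples into a training set and a class-stratified holdout set
#'
#' Draws `n_holdout_per_class` samples from each condition at random
#' (stratified by condition only; with five per class the draw cannot be
#' balanced over three days of three replicates). The two returned
#' matrices partition the samples.
#'
#' @param m an [expr_matrix].
#' @param n_holdout_per_class samples per class to hold out (default 5).
#' @param seed integer seed making the draw reproducible.
#' @return list with elements `train` and `holdout`, both [expr_matrix].
#' @export
make_holdout_split <- function(m, n_holdout_per_class = 5, seed = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  cond <- m$samples$condition
  n_by <- table(cond)
  if (any(n_by <= n_holdout_per_class))
    stop("each class needs more than ", n_holdout_per_class,
         " samples to split", call. = FALSE)
  if (any(n_by - n_holdout_per_class < 2))
    stop("each class must retain at least 2 training samples", call. = FALSE)
  set.seed(seed)
  hold <- unlist(lapply(c("WH", "F"), function(cl) {
    sample(which(cond == cl), n_holdout_per_class)
  }))
  hold <- sort(hold)
  train <- setdiff(seq_along(cond), hold)
  list(train = m[, train], holdout = m[, hold])
}
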