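test_that("load_expression parses matrix + metadata and validates them", {
  mdir <- withr::local_tempdir()
  mpath <- file.path(mdir, "expr.tsv")
  dpath <- file.path(mdir, "meta.tsv")
  writeLines(c("gene_id\tsampA\tsampB",
               "g1\t1.5\t2.0", "g2\t0\t4.0", "g3\t7\t0.5"), mpath)
  writeLines(c("sample_id\tcondition\tday\treplicate",
               "sampA\tWH\t1\t1", "sampB\tF\t1\t1"), dpath)
  m <- load_expression(mpath, dpath)
  expect_s3_class(m, "expr_matrix")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m$unit, "FPKM")
  expect_equal(m$samples$condition, c("WH", "F"))
  expect_equal(m$values["g3", "sampB"], 0.5)

  # duplicated gene row
  writeLines(c("gene_id\tsampA\tsampB",
               "ID1\t1\t2", "ID1\t3\t4"), mpath)
  expect_error(load_expression(mpath, dpath), "duplicate gene")

  # metadata sample set mismatch
  writeLines(c("gene_id\tsampA\tsampB", "g1\t1\t2"), mpath)
  writeLines(c("sample_id\tcondition\tday\treplicate",
               "sampA\tWH\t1\t1", "sampX\tF\t1\t1"), dpath)
  expect_error(load_expression(mpath, dpath), "do not match")

  # negative value
  writeLines(c("gene_id\tsampA\tsampB", "g1\t-1\t2"), mpath)
  writeLines(c("sample_id\tcondition\tday\treplicate",
               "sampA\tWH\t1\t1", "sampB\tF\t1\t1"), dpath)
  expect_error(load_expression(mpath, dpath), "negative")
})

test_that("fpkm_to_tpm rescales columns to one million", {
  m <- toy_matrix(matrix(c(5, 10, 85, 7.3, 1, 1.7), 3, 2), unit = "FPKM")
  tpm <- fpkm_to_tpm(m)
  expect_equal(tpm$values[, 1], c(g01 = 50000, g02 = 100000, g03 = 850000))
  expect_equal(tpm$unit, "TPM")

  # single-gene matrix: normalization forces 1e6
  m1 <- toy_matrix(matrix(7.3, 1, 2), unit = "FPKM")
  expect_equal(unname(fpkm_to_tpm(m1)$values[1, ]), c(1e6, 1e6))

  # property over random matrices, against direct summation
  set.seed(42)
  for (i in 1:10) {
    vals <- matrix(runif(300, 0, 50), 50, 6)
    tpm <- fpkm_to_tpm(toy_matrix(vals, unit = "FPKM"))
    expect_equal(unname(colSums(tpm$values)), rep(1e6, 6),
                 tolerance = 1e-6)
    # within-sample rank order of genes preserved
    expect_equal(unname(apply(tpm$values, 2, order)),
                 apply(vals, 2, order))
  }

  # idempotent up to rescaling: reapplying to already-normalized values
  once <- fpkm_to_tpm(m)
  again <- fpkm_to_tpm(expr_matrix(once$values, once$samples, "FPKM"))
  expect_equal(again$values, once$values)

  # degenerate all-zero sample
  bad <- toy_matrix(matrix(c(1, 2, 0, 0), 2, 2), unit = "FPKM")
  expect_error(fpkm_to_tpm(bad), "all-zero")
})

test_that("log_transform is log2(x + offset) and preserves ordering", {
  m <- toy_matrix(matrix(c(0, 3, 1, 7), 2, 2), unit = "TPM")
  lt <- log_transform(m, offset = 1)
  expect_equal(unname(lt$values[1, 1]), 0)   # log2(0 + 1)
  expect_equal(unname(lt$values[2, 1]), 2)   # log2(3 + 1)
  expect_equal(lt$unit, "log2(TPM+1)")
  expect_error(log_transform(m, offset = 0), "positive")

  set.seed(1)
  v <- runif(100, 0, 1000)
  mv <- toy_matrix(matrix(v, 100, 2), unit = "TPM")
  expect_equal(order(log_transform(mv)$values[, 1]), order(v))
})

test_that("holdout split is stratified, partitioning, and seeded", {
  sim <- generate_expression(sim_spec(n_genes = 50, seed = 3))
  sp <- make_holdout_split(sim$matrix, 5, seed = 9)
  expect_equal(as.vector(table(sp$holdout$samples$condition)), c(5L, 5L))
  expect_equal(as.vector(table(sp$train$samples$condition)), c(4L, 4L))
  # partition on sample ids
  expect_setequal(c(sp$train$samples$sample_id,
                    sp$holdout$samples$sample_id),
                  sim$matrix$samples$sample_id)
  expect_length(intersect(sp$train$samples$sample_id,
                          sp$holdout$samples$sample_id), 0)
  # determinism under seed
  sp2 <- make_holdout_split(sim$matrix, 5, seed = 9)
  expect_identical(sp$holdout$samples$sample_id,
                   sp2$holdout$samples$sample_id)
  # too-small class
  small <- sim$matrix[, c(1:3, 10:12)]
  expect_error(make_holdout_split(small, 5), "more than")
})

test_that("expr_matrix rejects malformed inputs", {
  vals <- matrix(1:4, 2, 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  samples <- data.frame(sample_id = c("s1", "s2"),
                        condition = c("WH", "F"), day = c(1, 1))
  expect_s3_class(expr_matrix(vals + 0, samples), "expr_matrix")
  expect_error(expr_matrix(vals + 0, samples[1, ]), "rows")
  bad <- samples; bad$condition <- c("WH", "fibrosis")
  expect_error(expr_matrix(vals + 0, bad), "WH")
  neg <- vals; neg[1] <- -1
  expect_error(expr_matrix(neg + 0, samples, unit = "TPM"), "negative")
})
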