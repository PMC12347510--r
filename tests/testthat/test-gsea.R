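test_that("candidate ranking is correlation-ordered with sane bounds", {
  set.seed(6)
  cand <- rnorm(12)
  vals <- rbind(cand = cand, same = cand * 2 + 1, anti = -cand,
                matrix(rnorm(12 * 20), 20, 12,
                       dimnames = list(sprintf("n%02d", 1:20), NULL)))
  m <- toy_matrix(vals, unit = "log2(TPM+1)",
                  condition = rep(c("WH", "F"), each = 6))
  rk <- rank_for_candidate(m, "cand")
  expect_false("cand" %in% rk$gene_id)
  expect_equal(rk$gene_id[1], "same")
  expect_equal(rk$metric[1], 1)
  expect_equal(rk$gene_id[nrow(rk)], "anti")
  expect_equal(rk$metric[nrow(rk)], -1)
  expect_true(all(rk$metric >= -1 & rk$metric <= 1))
  # zero-variance candidate is an error
  flat <- toy_matrix(rbind(vals, flat = rep(1, 12)),
                     unit = "log2(TPM+1)",
                     condition = rep(c("WH", "F"), each = 6))
  expect_error(rank_for_candidate(flat, "flat"), "zero variance")
})

test_that("enrichment score matches the hand-worked running sum", {
  ranked <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                       metric = c(0.9, 0.5, 0.1, -0.4, -0.8))
  p <- gsea_params(weight_exponent = 1, min_set_size = 2)
  res <- enrichment_score(ranked, c("a", "b"), p)
  # hits: 0.9/1.4 then +0.5/1.4 -> 1.0; misses: three steps of -1/3 -> 0
  expect_equal(res$es, 1)
  expect_equal(res$running_sum,
               c(0.9 / 1.4, 1, 1 - 1 / 3, 1 - 2 / 3, 0))
  expect_equal(res$leading_edge, c("a", "b"))
  expect_equal(res$running_sum[5], 0, tolerance = 1e-12)
  # set outside size limits is skipped
  expect_null(enrichment_score(ranked, c("a", "b"),
                               gsea_params(min_set_size = 3)))
  expect_null(enrichment_score(ranked, ranked$gene_id,
                               gsea_params(min_set_size = 2)))
})

test_that("vectorized ES equals the brute-force oracle", {
  set.seed(13)
  for (i in 1:30) {
    n <- sample(20:80, 1)
    metric <- sort(rnorm(n), decreasing = TRUE)
    ranked <- data.frame(gene_id = sprintf("g%03d", 1:n), metric = metric)
    size <- sample(3:10, 1)
    gs <- sample(ranked$gene_id, size)
    pw <- sample(c(0, 1, 1.5), 1)
    res <- enrichment_score(ranked, gs,
                            gsea_params(weight_exponent = pw,
                                        min_set_size = 3))
    hit <- ranked$gene_id %in% gs
    expect_equal(res$es, es_bruteforce(metric, hit, pw))
    expect_equal(res$running_sum[n], 0, tolerance = 1e-9)
    expect_lte(abs(res$es), 1)
  }
})

test_that("unit-weight exponent zero reduces to the unweighted KS walk", {
  set.seed(14)
  n <- 40
  ranked <- data.frame(gene_id = sprintf("g%02d", 1:n),
                       metric = sort(rnorm(n), decreasing = TRUE))
  gs <- sample(ranked$gene_id, 8)
  res <- enrichment_score(ranked, gs, gsea_params(weight_exponent = 0))
  # direct KS-style computation: +1/Nhit on hits, -1/Nmiss on misses
  hit <- ranked$gene_id %in% gs
  walk <- cumsum(ifelse(hit, 1 / sum(hit), -1 / sum(!hit)))
  expect_equal(res$running_sum, walk)
  expect_equal(res$es, walk[which.max(abs(walk))])
})

test_that("NES and FDR flag a planted set and are deterministic", {
  sim <- generate_expression(sim_spec(n_genes = 400, n_planted_f = 10,
                                      n_planted_wh = 0, effect_size = 3,
                                      seed = 8))
  lg <- log_transform(fpkm_to_tpm(sim$matrix))
  cand <- sim$truth$gene_id[1]
  rk <- rank_for_candidate(lg, cand)
  sets <- generate_gene_sets(sim$truth, sim_spec(n_genes = 400,
                                                 n_planted_f = 10,
                                                 n_planted_wh = 0,
                                                 seed = 8))
  p <- gsea_params(n_permutations = 300, seed = 2)
  res <- nes_and_fdr(rk, sets, p)
  expect_true("planted_F_set" %in% res$set_name)
  planted_row <- res[res$set_name == "planted_F_set", ]
  expect_gt(planted_row$nes, 0)
  expect_lt(planted_row$fdr, 0.05)
  expect_true(all(res$nes > 0))
  expect_true(all(diff(res$fdr) >= 0))  # sorted by FDR
  expect_identical(res, nes_and_fdr(rk, sets, p))
})

test_that("GMT round trip preserves the collection", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g9", "g4"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gene_sets(path)
  expect_equal(back[["alpha"]], sets$alpha)
  expect_equal(back[["beta"]], sets$beta)
})
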