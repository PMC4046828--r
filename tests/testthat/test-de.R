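test_that("AC test closed forms and input validation", {
  # equal counts at equal depths: both tails >= 1/2, capped at 1
  expect_equal(ac_test(7, 7, 1e6, 1e6), 1)
  expect_equal(ac_test(0, 0, 1e6, 1e6), 1)
  # (x, 0) at equal depths: p(0|x) = (1/2)^(x+1), doubled
  expect_equal(ac_test(5, 0, 1e6, 1e6), 0.03125)
  expect_equal(ac_test(0, 5, 1e6, 1e6), 0.03125)
  expect_error(ac_test(-1, 0, 1e6, 1e6), "non-negative")
  expect_error(ac_test(1, 0, 0, 1e6), "positive")
  expect_error(ac_test(10, 0, 5, 1e6), "exceeds")
})

test_that("AC test is exactly symmetric under library swap", {
  cases <- expand.grid(x = c(0, 1, 3, 10, 50, 200), y = c(0, 2, 10, 77, 150),
                       n1 = c(1e5, 1e6), n2 = c(1e6, 5e6))
  p_ab <- ac_test(cases$x, cases$y, cases$n1, cases$n2)
  p_ba <- ac_test(cases$y, cases$x, cases$n2, cases$n1)
  expect_identical(p_ab, p_ba)
})

test_that("AC test matches the negative-binomial and summation oracles", {
  grid <- expand.grid(x = 0:60, y = 0:60)
  for (nn in list(c(1e6, 1e6), c(1e5, 1e6), c(5e6, 1e6))) {
    p <- ac_test(grid$x, grid$y, nn[1L], nn[2L])
    p_nb <- mapply(oracle_ac_nb, grid$x, grid$y, nn[1L], nn[2L])
    expect_lt(max(abs(p - p_nb)), 1e-9)
  }
  # plain-arithmetic term-wise summation on a sparse subset
  sub <- grid[seq(1, nrow(grid), by = 37L), ]
  p <- ac_test(sub$x, sub$y, 2e6, 1e6)
  p_sum <- mapply(oracle_ac_sum, sub$x, sub$y, 2e6, 1e6, k_max = 5000L)
  expect_lt(max(abs(p - p_sum)), 1e-9)
  # large counts still stable (upper tail guarded against cancellation)
  expect_equal(ac_test(100000, 100600, 5e6, 5e6),
               oracle_ac_nb(100000, 100600, 5e6, 5e6), tolerance = 1e-9)
})

test_that("AC p-value decreases as counts diverge", {
  x <- 10
  ys <- 0:40
  p <- ac_test(rep(x, length(ys)), ys, 1e6, 1e6)
  expect_true(all(diff(p[ys >= x]) <= 1e-12))
  expect_true(all(diff(p[ys <= x]) >= -1e-12))
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_fdr(0.004), 0.004)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  perm <- sample(seq_along(p))
  expect_equal(bh_fdr(p[perm]), adj[perm])
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("log2 ratio applies the zero substitution", {
  expect_equal(log2_ratio(12.5, 12.5), 0)
  expect_equal(log2_ratio(6.68, 159), log2(159 / 6.68))
  expect_equal(round(log2_ratio(6.68, 159), 3), 4.573)
  expect_equal(log2_ratio(0, 8.192), 13)
  expect_equal(log2_ratio(8.192, 0), -13)
  expect_error(log2_ratio(-1, 2), "non-negative")
})

test_that("DE calls combine both thresholds", {
  expect_equal(call_de(0.0005, 3), "up")
  expect_equal(call_de(0.0005, 0.5), "ns")
  expect_equal(call_de(0.0005, -3), "down")
  expect_equal(call_de(0.01, 3), "ns")
  expect_equal(call_de(0.01, 3, fdr_max = 0.05), "up")
  expect_equal(call_de(0.0005, 1.5, min_abs_log2 = 2), "ns")
})

test_that("dge_compare assembles a complete ranked table", {
  a <- c(g1 = 100, g2 = 5, g3 = 0)
  b <- c(g1 = 95, g2 = 80, g4 = 12)
  de <- dge_compare(a, b, 1e6, 1e6, library_ids = c("FS1", "FS2"))
  expect_s3_class(de, "dge_de_table")
  expect_setequal(de$gene_id, c("g1", "g2", "g3", "g4"))
  # absent genes are compared with count 0
  expect_equal(de$x[de$gene_id == "g4"], 0)
  expect_equal(de$y[de$gene_id == "g3"], 0)
  expect_true(all(de$FDR >= de$pvalue - 1e-12))
  expect_true(!is.unsorted(de$pvalue))
  # g2 jumps 5 -> 80: clearly significant and up
  expect_equal(de$call[de$gene_id == "g2"], "up")
  expect_equal(de$call[de$gene_id == "g1"], "ns")
})

test_that("TPM categories use left-closed boundaries", {
  expect_equal(as.character(tpm_category(c(0, 3, 5, 49.9, 50, 99, 100, 150))),
               c("rare", "rare", "low", "low", "moderate", "moderate",
                 "high", "high"))
  expect_error(tpm_category(-2), "non-negative")
})
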