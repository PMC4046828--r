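test_that("config validation rejects impossible settings", {
  expect_error(sim_config(length_max = 20), "CATG")
  expect_error(sim_config(length_min = 10), "length_min")
  expect_error(sim_config(gc_content = 1.2), "fraction")
  expect_error(sim_config(n_stages = 1), "n_stages")
  expect_error(sim_config(log2fc_min = 3, log2fc_max = 2), "log2fc_min")
  expect_error(sim_config(depth_per_stage = -1), "depth")
})

test_that("transcriptome generation handles empty and seeded cases", {
  expect_length(sim_transcriptome(small_cfg(n_genes = 0L)), 0L)
  cfg <- small_cfg()
  tr1 <- sim_transcriptome(cfg)
  tr2 <- sim_transcriptome(cfg)
  expect_identical(tr1, tr2)
  f1 <- tempfile(); f2 <- tempfile()
  write_transcripts_fasta(tr1, f1)
  write_transcripts_fasta(tr2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # default config: every transcript carries a qualifying tag site
  expect_true(all(grepl("CATG[ACGT]{17}", tr1)))
  expect_true(all(nchar(tr1) >= cfg$length_min & nchar(tr1) <= cfg$length_max))
})

test_that("CATG occurrence rate matches the i.i.d. closed form", {
  # unconditioned sequences (siteless allowed): expected sites per 400-bp
  # transcript at GC 0.5 is (400-3) * (1/4)^4
  cfg <- sim_config(n_genes = 500L, length_min = 400L, length_max = 400L,
                    gc_content = 0.5, siteless_fraction = 1, seed = 31L)
  tr <- sim_transcriptome(cfg)
  n_sites <- vapply(gregexpr("CATG", tr, fixed = TRUE),
                    function(m) sum(m > 0L), numeric(1))
  expected <- (400 - 3) / 4^4
  ci <- 2.576 * sd(n_sites) / sqrt(length(n_sites))
  expect_lt(abs(mean(n_sites) - expected), ci + 1e-12)
})

test_that("planted truth follows the configuration exactly", {
  cfg0 <- small_cfg(de_fraction = 0)
  tru0 <- sim_ground_truth(cfg0)
  expect_true(all(tru0$log2fc == 0))
  expect_false(any(tru0$de))
  expect_equal(colSums(tru0$abundance), rep(1, cfg0$n_stages),
               tolerance = 1e-9, ignore_attr = TRUE)

  cfg1 <- small_cfg(de_fraction = 1, log2fc_min = 2, log2fc_max = 2)
  tru1 <- sim_ground_truth(cfg1)
  expect_true(all(abs(tru1$log2fc[tru1$de]) == 2))
  expect_true(all(tru1$de))

  # exact-size subset sampling of DE genes
  cfg2 <- sim_config(n_genes = 1000L, de_fraction = 0.1, n_stages = 3L,
                     seed = 12L)
  tru2 <- sim_ground_truth(cfg2)
  expect_identical(unname(colSums(tru2$de)), c(100, 100))
  expect_identical(colSums(tru2$log2fc != 0), colSums(tru2$de))
})

test_that("tag streams have exact depth and honest noise bookkeeping", {
  cfg <- small_cfg()
  tr <- sim_transcriptome(cfg)
  tru <- sim_ground_truth(cfg)
  expect_length(sim_tag_library(tr, tru, 1L, small_cfg(depth_per_stage = 0L)), 0L)
  expect_error(sim_tag_library(tr, tru, 9L, cfg), "stage")

  raw <- sim_tag_library(tr, tru, 2L, cfg)
  expect_length(raw, cfg$depth_per_stage)
  expect_identical(raw, sim_tag_library(tr, tru, 2L, cfg))
  expect_identical(sum(attr(raw, "true_counts")),
                   sum(!grepl("N", raw, fixed = TRUE) & raw != cfg$adaptor_tag))

  # noiseless: every emitted tag is some gene's canonical tag
  cfg0 <- small_cfg(substitution_rate = 0, n_tag_rate = 0, adaptor_tag_rate = 0)
  raw0 <- sim_tag_library(tr, tru, 1L, cfg0)
  canon <- vapply(tr, function(s) canonical_tag(s)$tag, character(1))
  expect_true(all(raw0 %in% canon))
})

test_that("per-tag error fraction matches the closed form", {
  # single gene: every real tag is one canonical 21-mer with i.i.d. errors;
  # P(>=1 substitution) = 1 - (1-rate)^21
  cfg <- sim_config(n_genes = 1L, depth_per_stage = 1e5L, n_stages = 2L,
                    substitution_rate = 0.002, n_tag_rate = 0,
                    adaptor_tag_rate = 0, seed = 19L)
  tr <- sim_transcriptome(cfg)
  tru <- sim_ground_truth(cfg)
  raw <- sim_tag_library(tr, tru, 1L, cfg)
  canon <- canonical_tag(tr[[1L]])$tag
  frac <- mean(raw != canon)
  p <- 1 - (1 - 0.002)^21
  ci <- 2.576 * sqrt(p * (1 - p) / length(raw))
  expect_lt(abs(frac - p), ci)
})

test_that("artifact tags are planted at the configured rates", {
  cfg <- small_cfg(depth_per_stage = 20000L, n_tag_rate = 0.05,
                   adaptor_tag_rate = 0.03, substitution_rate = 0)
  tr <- sim_transcriptome(cfg)
  tru <- sim_ground_truth(cfg)
  raw <- sim_tag_library(tr, tru, 1L, cfg)
  n_frac <- mean(grepl("N", raw, fixed = TRUE))
  ad_frac <- mean(raw == cfg$adaptor_tag)
  expect_lt(abs(n_frac - 0.05), 3 * sqrt(0.05 * 0.95 / 20000))
  expect_lt(abs(ad_frac - 0.03), 3 * sqrt(0.03 * 0.97 / 20000))
})
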