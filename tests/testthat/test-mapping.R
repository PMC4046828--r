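mk_tag <- function(core17) paste0("CATG", core17)

test_that("map_tags status rules on constructed cases", {
  tA <- mk_tag(strrep("A", 17))
  tC <- mk_tag(strrep("C", 17))
  tG <- mk_tag(strrep("G", 17))
  tr <- c(g1 = paste0("TT", tA), g2 = paste0("TT", tC),
          g3 = paste0("AA", tC))   # g2 and g3 share a canonical tag
  idx <- build_tag_index(tr, "sense")

  res <- map_tags(c(tA, tC, tG), idx)
  expect_equal(res$status, c("exact_unique", "ambiguous", "unknown"))
  expect_equal(res$gene_id[1L], "g1")
  expect_true(is.na(res$gene_id[2L]))
  expect_setequal(res$genes[[2L]], c("g2", "g3"))
  expect_equal(res$mismatches[1:2], c(0L, 0L))

  # one substitution in the variable region rescues the tag
  t1mm <- mk_tag(paste0(strrep("A", 16), "T"))
  res2 <- map_tags(t1mm, idx)
  expect_equal(res2$status, "mismatch_unique")
  expect_equal(res2$gene_id, "g1")
  expect_equal(res2$mismatches, 1L)

  # with mismatch disabled it is unknown
  expect_equal(map_tags(t1mm, idx, max_mismatch = 0L)$status, "unknown")

  # two substitutions are beyond the budget
  t2mm <- mk_tag(paste0(strrep("A", 15), "TT"))
  expect_equal(map_tags(t2mm, idx)$status, "unknown")

  expect_error(map_tags("CATGnotatag", idx), "malformed")
  expect_error(map_tags(c(tA, tA), idx), "distinct")
})

test_that("ambiguous exact hits are final and strands of one gene collapse", {
  # CATG is its own reverse complement, so a site with 17 nt on both sides
  # yields distinct sense and antisense canonical tags for the same gene
  tr <- c(gX = paste0(strrep("C", 17), "CATG", strrep("A", 17)))
  idx <- build_tag_index(tr, "both")
  expect_equal(idx$stats$distinct_reference_tags, 2L)
  hits <- map_tags(idx$tags, idx)
  expect_true(all(hits$status == "exact_unique"))
  expect_true(all(hits$gene_id == "gX"))
})

test_that("mapping agrees with the exhaustive Hamming oracle", {
  cfg <- small_cfg(n_genes = 300L, seed = 41L)
  tr <- sim_transcriptome(cfg)
  idx <- build_tag_index(tr, "both")
  canon <- idx$entries$tag

  set.seed(77)
  n_q <- 1000L
  kind <- sample(1:4, n_q, replace = TRUE, prob = c(0.35, 0.35, 0.15, 0.15))
  queries <- character(n_q)
  for (i in seq_len(n_q)) {
    base <- sample(canon, 1L)
    q <- base
    n_mut <- c(0L, 1L, 2L, 5L)[kind[i]]
    if (n_mut > 0L) {
      pos <- sample(5:21, n_mut)
      for (p in pos) {
        cur <- substr(q, p, p)
        substr(q, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
      }
    }
    queries[i] <- q
  }
  queries <- unique(queries)
  res <- map_tags(queries, idx)
  for (i in seq_along(queries)) {
    want <- oracle_map_one(queries[i], idx$entries)
    expect_identical(res$status[i], want$status)
    expect_identical(res$gene_id[i], want$gene)
    expect_setequal(res$genes[[i]], want$genes)
  }
})

test_that("gene counting conserves copies and reproduces single-gene cases", {
  tA <- mk_tag(strrep("A", 17))
  tr <- c(g1 = paste0("TT", tA))
  idx <- build_tag_index(tr, "sense")
  cl <- filter_tags(rep(tA, 7), adaptor_tags = character(0), library_id = "L1")
  mp <- map_tags(cl, idx)
  cn <- count_genes(mp, cl, idx)
  expect_equal(cn$expression$raw_count, 7)
  expect_equal(cn$expression$gene_id, "g1")
  expect_equal(cn$expression$tpm, 1e6)

  # all-unknown library
  tZ <- mk_tag(paste0(strrep("G", 8), strrep("T", 9)))
  clu <- filter_tags(rep(tZ, 4), adaptor_tags = character(0))
  cnu <- count_genes(map_tags(clu, idx), clu, idx)
  expect_equal(nrow(cnu$expression), 0L)
  expect_equal(cnu$summary$value[cnu$summary$statistic == "Number of unknown tags"], 4)

  # conservation on a simulated library
  run <- shared_run()
  s <- run$cn$summary
  v <- function(k) s$value[s$statistic == k]
  expect_equal(v("Total number of tags mapping to genes") +
                 v("Number of unknown tags"), run$cl$clean_total)
  expect_equal(v("Total number of distinct tags mapping to gene") +
                 v("Number of distinct unknown tags"), run$cl$clean_distinct)
  copies <- run$cl$counts$count
  st <- run$mp$status[match(run$cl$counts$tag, run$mp$tag)]
  expect_equal(sum(copies[st %in% c("exact_unique", "mismatch_unique")]) +
                 sum(copies[st == "ambiguous"]) + sum(copies[st == "unknown"]),
               run$cl$clean_total)
  expect_error(count_genes(run$mp[-1L, ], run$cl, run$idx), "consistency")
})

test_that("TPM arithmetic and bounds", {
  expect_equal(tag_tpm(0, 5e6), 0)
  expect_equal(tag_tpm(5, 1e6), 5)
  expect_equal(tag_tpm(347, 5779213), 1e6 * 347 / 5779213)
  expect_equal(round(tag_tpm(347, 5779213), 4), 60.0428)
  expect_error(tag_tpm(3, 0), "clean_total")

  run <- shared_run()
  expect_lte(sum(run$cn$expression$tpm), 1e6 + 1e-6)
  # equality iff every clean tag maps unambiguously
  uniq_copies <- sum(run$cn$expression$raw_count)
  expect_equal(sum(run$cn$expression$tpm), 1e6 * uniq_copies / run$cl$clean_total)
})

test_that("noiseless simulation is quantified exactly", {
  cfg <- small_cfg(substitution_rate = 0, n_tag_rate = 0, adaptor_tag_rate = 0,
                   n_genes = 40L, depth_per_stage = 6000L, seed = 3L)
  tr <- sim_transcriptome(cfg)
  tru <- sim_ground_truth(cfg)
  idx <- build_tag_index(tr, "both")
  raw <- sim_tag_library(tr, tru, 1L, cfg)
  truth <- attr(raw, "true_counts")
  cl <- filter_tags(raw, adaptor_tags = character(0))
  mp <- map_tags(cl, idx)
  cn <- count_genes(mp, cl, idx)
  # genes whose canonical tag is unambiguous must be recovered exactly,
  # unless their true count was 1 (removed as a singleton at QC)
  canon <- vapply(tr, function(s) canonical_tag(s)$tag, character(1))
  amb_tags <- idx$tags[lengths(idx$genes) > 1L]
  clean_genes <- names(truth)[!(canon %in% amb_tags) & truth >= 2L]
  got <- setNames(cn$expression$raw_count, cn$expression$gene_id)
  expect_equal(unname(got[clean_genes]), unname(truth[clean_genes]))
})

test_that("expression_matrix aligns genes across libraries", {
  r1 <- data.frame(gene_id = c("a", "b"), library_id = "L1",
                   raw_count = c(2, 3), tpm = c(20, 30))
  r2 <- data.frame(gene_id = c("b", "c"), library_id = "L2",
                   raw_count = c(5, 7), tpm = c(50, 70))
  m <- expression_matrix(list(r1, r2))
  expect_equal(rownames(m$counts), c("a", "b", "c"))
  expect_equal(m$counts["a", ], c(L1 = 2, L2 = 0))
  expect_equal(m$tpm["c", ], c(L1 = 0, L2 = 70))
})
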