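# Independent oracles used across the suite. Each recomputes a quantity by a
# route different from the implementation it checks.

# AC two-sided p via the negative-binomial CDF closed form: the conditional
# count distribution p(k|x) at depth ratio r is NB(size = x+1, prob = 1/(1+r)).
# Same canonical orientation rule as ac_test (condition on the larger
# normalized count).
oracle_ac_nb <- function(x, y, n1, n2) {
  if (y / n2 > x / n1 ||
      (y / n2 == x / n1 && (y > x || (y == x && n2 < n1)))) {
    t <- x; x <- y; y <- t
    t <- n1; n1 <- n2; n2 <- t
  }
  pr <- 1 / (1 + n2 / n1)
  lower <- pnbinom(y, size = x + 1, prob = pr)
  upper <- if (y == 0) 1 else
    pnbinom(y - 1, size = x + 1, prob = pr, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

# AC two-sided p by plain term-wise summation of p(k|x) (no log space): only
# valid where terms do not underflow, i.e. modest counts
oracle_ac_sum <- function(x, y, n1, n2, k_max = 100000L) {
  if (y / n2 > x / n1 ||
      (y / n2 == x / n1 && (y > x || (y == x && n2 < n1)))) {
    t <- x; x <- y; y <- t
    t <- n1; n1 <- n2; n2 <- t
  }
  r <- n2 / n1
  term <- function(k) exp(k * log(r) + lgamma(x + k + 1) - lgamma(x + 1) -
                            lgamma(k + 1) - (x + k + 1) * log1p(r))
  lower <- sum(term(0:y))
  ks <- y:k_max
  upper <- sum(term(ks))
  min(1, 2 * min(lower, upper))
}

# brute-force tag mapping: anchor-respecting Hamming distance of the query
# against every reference entry, exact hits first, then distance-1 hits in
# the variable region, with gene-set union and the same tie rules
oracle_map_one <- function(tag, entries) {
  ref <- entries$tag
  qs <- strsplit(tag, "")[[1L]]
  d <- vapply(strsplit(ref, ""), function(rs) sum(rs != qs), integer(1))
  exact <- unique(entries$gene_id[d == 0L])
  if (length(exact) >= 1L) {
    if (length(exact) == 1L)
      return(list(status = "exact_unique", gene = exact, genes = exact))
    return(list(status = "ambiguous", gene = NA_character_, genes = exact))
  }
  # one mismatch allowed, but never inside the CATG anchor
  pos_diff <- lapply(strsplit(ref, ""), function(rs) which(rs != qs))
  ok <- d == 1L & vapply(pos_diff, function(p) length(p) == 1L && p > 4L, logical(1))
  genes <- unique(entries$gene_id[ok])
  if (length(genes) == 1L)
    return(list(status = "mismatch_unique", gene = genes, genes = genes))
  if (length(genes) > 1L)
    return(list(status = "ambiguous", gene = NA_character_, genes = genes))
  list(status = "unknown", gene = NA_character_, genes = character(0))
}

# brute-force canonical site: enumerate every CATG occurrence with substr
oracle_canonical <- function(s) {
  n <- nchar(s)
  best <- NULL
  i <- 1L
  while (i + 3L <= n) {
    if (substr(s, i, i + 3L) == "CATG" && i + 20L <= n) {
      win <- substr(s, i, i + 20L)
      if (!grepl("N", win, fixed = TRUE)) best <- list(tag = win, offset = i - 1L)
    }
    i <- i + 1L
  }
  best
}

# manual reverse complement, independent of Biostrings
oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
}

# hypergeometric upper tail by direct combinatorial summation
oracle_hyper <- function(N, n, M, m) {
  ks <- m:min(n, M)
  sum(choose(M, ks) * choose(N - M, n - ks)) / choose(N, n)
}

# one-pass independent QC re-count on a raw tag character vector
oracle_qc_partition <- function(tags, adaptors) {
  counts <- table(tags)
  tag <- names(counts)
  k <- as.integer(counts)
  is_ad <- tag %in% adaptors
  bad <- grepl("N", tag, fixed = TRUE) |
    (!grepl("^CATG[ACGT]{17}$", tag) & !is_ad)
  n_containing <- sum(k[bad])
  rest <- !bad
  adaptor_only <- sum(k[rest & is_ad])
  rest <- rest & !is_ad
  singleton <- sum(k[rest & k == 1L])
  clean <- sum(k[rest & k >= 2L])
  c(n_containing = n_containing, adaptor_only = adaptor_only,
    singleton_copies = singleton, clean = clean)
}
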