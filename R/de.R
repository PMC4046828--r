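# Pairwise differential expression between two tag libraries with the
# Audic-Claverie exact test. Under Poisson sampling the count y in library 2,
# conditioned on count x in library 1 with depth ratio r = N2/N1, follows
#   p(y | x) = r^y (x+y)! / ( x! y! (1+r)^(x+y+1) ),
# a negative-binomial distribution with size x+1 and success probability
# 1/(1+r). The two-sided p-value doubles the smaller inclusive tail, capped
# at 1. The doubled-tail construction depends on which library is
# conditioned on; ac_test() canonically conditions on the library with the
# larger normalized count (ties: larger raw count), which makes the p-value
# exactly symmetric under swapping the two libraries and reproduces the
# closed form p = 2 * (1/2)^(x+1) for (x, 0) at equal depths.

log_sum_exp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# log p(k | x) for the conditional count distribution at depth ratio r
ac_log_term <- function(k, x, log_r, log_1pr) {
  k * log_r + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
    (x + k + 1) * log_1pr
}

# lower tail P(K <= y | x) in log space (term-wise, exact summation)
ac_log_lower <- function(y, x, log_r, log_1pr) {
  log_sum_exp(ac_log_term(0:y, x, log_r, log_1pr))
}

# upper tail P(K >= y | x): via the complement when safe, otherwise by
# direct chunked summation upward from y (guards against cancellation when
# the lower tail is close to 1)
ac_upper <- function(y, x, log_r, log_1pr) {
  if (y == 0) return(1)
  lower_excl <- exp(ac_log_lower(y - 1, x, log_r, log_1pr))
  if (lower_excl < 0.9) return(1 - lower_excl)
  acc <- -Inf
  k0 <- y
  chunk <- 4096L
  repeat {
    ks <- seq.int(k0, k0 + chunk - 1L)
    lt <- ac_log_term(ks, x, log_r, log_1pr)
    block <- log_sum_exp(lt)
    acc <- log_sum_exp(c(acc, block))
    # stop once a whole block is negligible and we are past the mode
    if (block < acc - 40 && lt[chunk] < lt[1L]) break
    k0 <- k0 + chunk
    if (k0 > y + 5e7) stop("upper-tail summation failed to converge", call. = FALSE)
  }
  exp(acc)
}

ac_pvalue_one <- function(x, y, n1, n2) {
  # canonical orientation: condition on the library with the larger
  # normalized count (ties: larger raw count, then smaller depth);
  # symmetric by construction
  if (y / n2 > x / n1 ||
      (y / n2 == x / n1 && (y > x || (y == x && n2 < n1)))) {
    tmp <- x; x <- y; y <- tmp
    tmp <- n1; n1 <- n2; n2 <- tmp
  }
  r <- n2 / n1
  log_r <- log(r)
  log_1pr <- log1p(r)
  lower <- exp(ac_log_lower(y, x, log_r, log_1pr))
  upper <- ac_upper(y, x, log_r, log_1pr)
  min(1, 2 * min(lower, upper))
}

#' Audic-Claverie exact test for two tag counts
#'
#' Two-sided exact p-value for the difference of a gene's tag count between
#' two libraries of total clean-tag depths \code{n1} and \code{n2}. Computed
#' in log space via log-gamma with a cancellation-guarded upper tail.
#' Symmetric: \code{ac_test(x, y, n1, n2) == ac_test(y, x, n2, n1)} exactly.
#' Vectorized over \code{x} and \code{y}.
#'
#' @param x,y tag counts of the gene in library 1 and 2.
#' @param n1,n2 clean-tag totals of the two libraries (positive).
#' @return p-values in (0, 1].
#' @examples
#' ac_test(5, 0, 1e6, 1e6)   # 0.03125
#' @export
ac_test <- function(x, y, n1, n2) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library totals must be positive", call. = FALSE)
  if (any(x > n1) || any(y > n2)) stop("count exceeds its library total", call. = FALSE)
  k <- max(length(x), length(y))
  x <- rep_len(x, k); y <- rep_len(y, k)
  n1 <- rep_len(n1, k); n2 <- rep_len(n2, k)
  vapply(seq_len(k), function(i) ac_pvalue_one(x[i], y[i], n1[i], n2[i]),
         numeric(1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (smallest q at which each test would be called),
#' returned in input order. Wraps \code{stats::p.adjust(method = "BH")} after
#' validating the input range.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return Adjusted values in `[0, 1]`, element-wise >= the raw p-values.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}

#' Log2 expression ratio with zero substitution
#'
#' \code{log2(tpm_b / tpm_a)} after substituting 0.001 for any zero TPM, the
#' standard convention for genes undetected in one library. The substitution
#' applies to the ratio only, never to the test counts.
#'
#' @param tpm_a,tpm_b non-negative TPM values (vectorized).
#' @return log2 fold change of library B over library A.
#' @export
log2_ratio <- function(tpm_a, tpm_b) {
  if (any(tpm_a < 0) || any(tpm_b < 0)) stop("TPM must be non-negative", call. = FALSE)
  log2(pmax(tpm_b, 0.001) / pmax(tpm_a, 0.001))
}

#' Call differential expression
#'
#' \code{up} if \code{FDR <= fdr_max} and \code{log2Ratio >= min_abs_log2};
#' \code{down} if \code{FDR <= fdr_max} and \code{log2Ratio <= -min_abs_log2};
#' otherwise \code{ns}.
#'
#' @param fdr adjusted p-values.
#' @param log2ratio log2 fold changes (B over A).
#' @param fdr_max FDR threshold (default 0.001).
#' @param min_abs_log2 minimum absolute log2 fold change (default 1, i.e.
#'   2-fold).
#' @return Character vector of calls: \code{up}, \code{down}, \code{ns}.
#' @export
call_de <- function(fdr, log2ratio, fdr_max = 0.001, min_abs_log2 = 1) {
  ifelse(fdr <= fdr_max & log2ratio >= min_abs_log2, "up",
         ifelse(fdr <= fdr_max & log2ratio <= -min_abs_log2, "down", "ns"))
}

#' Compare two tag libraries gene by gene
#'
#' Runs the Audic-Claverie test for every gene over two libraries, adjusts by
#' Benjamini-Hochberg, computes TPM and the zero-substituted log2 ratio, and
#' calls differential expression. Genes absent from one library are compared
#' with count 0 there.
#'
#' @param counts_a,counts_b named numeric vectors of per-gene unambiguous tag
#'   counts (union of names is used; missing genes count 0).
#' @param n1,n2 clean-tag totals of the two libraries.
#' @param library_ids length-2 character, labels for the comparison.
#' @param fdr_max,min_abs_log2 thresholds passed to \code{\link{call_de}}.
#' @return data.frame of class \code{dge_de_table}: \code{gene_id}, \code{x},
#'   \code{y}, \code{tpm_a}, \code{tpm_b}, \code{log2Ratio}, \code{pvalue},
#'   \code{FDR}, \code{call}, ordered by p-value.
#' @export
dge_compare <- function(counts_a, counts_b, n1, n2,
                        library_ids = c("A", "B"),
                        fdr_max = 0.001, min_abs_log2 = 1) {
  genes <- sort(union(names(counts_a), names(counts_b)))
  if (length(genes) == 0L) stop("no genes to compare", call. = FALSE)
  x <- unname(counts_a[genes]); x[is.na(x)] <- 0
  y <- unname(counts_b[genes]); y[is.na(y)] <- 0
  tpm_a <- tag_tpm(x, n1)
  tpm_b <- tag_tpm(y, n2)
  p <- ac_test(x, y, n1, n2)
  out <- data.frame(
    gene_id = genes, x = as.numeric(x), y = as.numeric(y),
    tpm_a = tpm_a, tpm_b = tpm_b,
    log2Ratio = log2_ratio(tpm_a, tpm_b),
    pvalue = p, FDR = bh_fdr(p),
    stringsAsFactors = FALSE
  )
  out$call <- call_de(out$FDR, out$log2Ratio, fdr_max, min_abs_log2)
  out <- out[order(out$pvalue, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "library_ids") <- library_ids
  attr(out, "totals") <- c(n1 = n1, n2 = n2)
  attr(out, "thresholds") <- c(fdr_max = fdr_max, min_abs_log2 = min_abs_log2)
  class(out) <- c("dge_de_table", "data.frame")
  out
}

#' @export
print.dge_de_table <- function(x, ...) {
  ids <- attr(x, "library_ids")
  th <- attr(x, "thresholds")
  up <- sum(x$call == "up"); dn <- sum(x$call == "down")
  cat(sprintf("DGE comparison %s vs %s: %d genes, %d up / %d down (FDR <= %g, |log2R| >= %g)\n",
              ids[2L], ids[1L], nrow(x), up, dn,
              th[["fdr_max"]], th[["min_abs_log2"]]))
  print.data.frame(head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat(sprintf("  ... %d more genes\n", nrow(x) - 10L))
  invisible(x)
}

#' Expression-level category of a TPM value
#'
#' Standard abundance classes: rare `[0,5)`, low `[5,50)`, moderate
#' `[50,100)`, high `[100,Inf)`; boundaries are left-closed.
#'
#' @param tpm non-negative TPM values.
#' @return Factor with levels rare, low, moderate, high.
#' @export
tpm_category <- function(tpm) {
  if (any(tpm < 0)) stop("TPM must be non-negative", call. = FALSE)
  cut(tpm, breaks = c(0, 5, 50, 100, Inf), right = FALSE,
      labels = c("rare", "low", "moderate", "high"))
}
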