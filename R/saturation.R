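# Sequencing-saturation analysis: detected genes as a function of depth by
# nested (prefix) subsampling of the clean tag stream, plus expression-level
# distribution reports.

#' Saturation curve by nested subsampling
#'
#' For each replicate, draws one random permutation of the per-copy clean tag
#' stream (sampling without replacement) and evaluates the number of genes
#' with at least one unambiguously mapped tag at each grid depth as a prefix
#' statistic, so the curve is exactly non-decreasing within a replicate.
#'
#' @param mapping result of \code{\link{map_tags}} for the library's distinct
#'   tags, or any data.frame with columns \code{gene_id} (NA for tags not
#'   unambiguously mapped) and \code{copies}.
#' @param clean the \code{\link{filter_tags}} result; not needed when
#'   \code{mapping} already carries a \code{copies} column.
#' @param depth_grid ascending depths to evaluate; depths above the clean
#'   total are clipped with a warning. Default: 20 evenly spaced depths up to
#'   the clean total.
#' @param replicates number of independent permutations (default 5).
#' @param seed RNG seed.
#' @return data.frame: \code{replicate}, \code{depth}, \code{detected_genes}.
#' @export
saturation_curve <- function(mapping, clean = NULL, depth_grid = NULL,
                             replicates = 5L, seed = 1L) {
  if (!is.null(clean)) {
    stopifnot(inherits(clean, "clean_tag_library"))
    copies <- clean$counts$count[match(mapping$tag, clean$counts$tag)]
    if (anyNA(copies))
      stop("internal consistency error: clean copy number missing for a mapped tag",
           call. = FALSE)
  } else {
    copies <- mapping$copies
  }
  uniq <- if ("status" %in% names(mapping))
    mapping$status %in% c("exact_unique", "mismatch_unique")
  else !is.na(mapping$gene_id)
  gene_per_copy <- rep(ifelse(uniq, mapping$gene_id, NA_character_), copies)
  total <- length(gene_per_copy)
  if (is.null(depth_grid))
    depth_grid <- unique(round(seq(0, total, length.out = 21L)))
  if (is.unsorted(depth_grid)) stop("depth grid must be ascending", call. = FALSE)
  if (any(depth_grid > total)) {
    warning("depth grid clipped to the clean total (", total, ")")
    depth_grid <- unique(pmin(depth_grid, total))
  }
  out <- vector("list", replicates)
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      perm <- gene_per_copy[sample.int(total)]
      new_gene <- !is.na(perm) & !duplicated(perm, incomparables = NA)
      cum <- cumsum(new_gene)
      detected <- ifelse(depth_grid == 0L, 0L, cum[pmax(depth_grid, 1L)])
      out[[r]] <- data.frame(replicate = r, depth = depth_grid,
                             detected_genes = as.integer(detected))
    }
  })
  do.call(rbind, out)
}

#' Expected detected genes under uniform copy numbers
#'
#' Closed form for the toy case of G genes with exactly t tag copies each
#' (total T = G*t): the expected number of genes with at least one copy in a
#' without-replacement subsample of depth d is
#' \code{G * (1 - choose(T-t, d) / choose(T, d))}. Used as the independent
#' check of \code{\link{saturation_curve}}.
#'
#' @param d subsample depth (vectorized).
#' @param G number of genes.
#' @param t copies per gene.
#' @return Expected detected-gene count.
#' @export
expected_detected_uniform <- function(d, G, t) {
  T <- G * t
  # log-space hypergeometric inclusion probability; choose(T-t, d) = 0 for d > T-t
  miss <- ifelse(d > T - t, 0,
                 exp(lchoose(T - t, d) - lchoose(T, d)))
  G * (1 - miss)
}

#' Expression-level histogram
#'
#' Bins a library's per-gene TPM values into decade bins (plus a zero bin)
#' and reports the four abundance-category totals of
#' \code{\link{tpm_category}}.
#'
#' @param tpm numeric vector of per-gene TPM values.
#' @return List with \code{bins} (data.frame bin/genes) and
#'   \code{categories} (data.frame category/genes).
#' @export
expression_level_histogram <- function(tpm) {
  if (any(tpm < 0)) stop("TPM must be non-negative", call. = FALSE)
  pos <- tpm[tpm > 0]
  labs <- "0"
  cnts <- sum(tpm == 0)
  if (length(pos) > 0L) {
    lo <- floor(log10(min(pos)))
    hi <- ceiling(log10(max(pos)))
    if (hi == lo) hi <- lo + 1L
    brk <- 10^seq(lo, hi)
    bin <- cut(pos, breaks = brk, include.lowest = TRUE)
    labs <- c(labs, levels(bin))
    cnts <- c(cnts, as.integer(table(bin)))
  }
  cats <- table(tpm_category(tpm))
  list(
    bins = data.frame(bin = labs, genes = as.integer(cnts),
                      stringsAsFactors = FALSE),
    categories = data.frame(category = names(cats), genes = as.integer(cats),
                            stringsAsFactors = FALSE)
  )
}
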