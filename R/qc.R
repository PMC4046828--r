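# Raw-tag quality control: partition the raw stream into N/malformed,
# adaptor-only, singleton, and clean fractions. The partition conserves the
# raw total exactly; clean tags have correct 21-bp CATG structure and
# within-library copy number >= 2.

tag_count_table <- function(tags) {
  if (is.data.frame(tags)) {
    stopifnot(all(c("tag", "count") %in% names(tags)))
    tb <- tags[, c("tag", "count")]
    tb <- stats::aggregate(count ~ tag, data = tb, FUN = sum)
  } else {
    t0 <- table(tags)
    tb <- data.frame(tag = as.character(if (is.null(names(t0))) character(0)
                                        else names(t0)),
                     count = as.integer(t0), stringsAsFactors = FALSE)
  }
  tb <- tb[order(tb$tag), , drop = FALSE]
  rownames(tb) <- NULL
  tb
}

#' Filter a raw tag library
#'
#' Applies the three QC removals in fixed precedence: (1) tags containing N
#' or not matching the CATG + 17 nt structure (malformed length included);
#' (2) exact matches to a configured adaptor tag; (3) distinct tags seen only
#' once in this library (probable sequencing errors). What remains is the
#' clean library. The four partition counts are in raw-tag units and sum
#' exactly to the raw total. Filtering is idempotent.
#'
#' @param tags raw tags as a character vector (one element per sequenced tag)
#'   or a data.frame with columns \code{tag}, \code{count}.
#' @param adaptor_tags character vector of adaptor-only sequences removed by
#'   exact match (may be empty).
#' @param library_id label stored with the result.
#' @return Object of class \code{clean_tag_library}: list with
#'   \code{library_id}, \code{counts} (data.frame tag/count, all counts >= 2),
#'   \code{clean_total}, \code{clean_distinct}, \code{raw_total},
#'   \code{raw_distinct}, and \code{partition} (named integer:
#'   \code{n_containing}, \code{adaptor_only}, \code{singleton_copies},
#'   \code{clean}).
#' @export
filter_tags <- function(tags, adaptor_tags = DGE_ADAPTOR_TAG,
                        library_id = "library") {
  tb <- tag_count_table(tags)
  raw_total <- sum(tb$count)
  raw_distinct <- nrow(tb)
  # precedence: N/low-quality first, then adaptor-only, then singletons.
  # malformed non-adaptor tags (wrong length, missing CATG) count with the
  # N/low-quality category; an exact adaptor match is its own category even
  # though it lacks tag structure
  is_ad <- tb$tag %in% adaptor_tags
  bad_n <- grepl("N", tb$tag, fixed = TRUE) |
    (!grepl(TAG_REGEX, tb$tag) & !is_ad)
  n_containing <- sum(tb$count[bad_n])
  tb <- tb[!bad_n, , drop = FALSE]
  is_ad <- tb$tag %in% adaptor_tags
  adaptor_only <- sum(tb$count[is_ad])
  tb <- tb[!is_ad, , drop = FALSE]
  single <- tb$count < 2L
  singleton_copies <- sum(tb$count[single])
  tb <- tb[!single, , drop = FALSE]
  rownames(tb) <- NULL
  out <- list(
    library_id = library_id,
    counts = tb,
    clean_total = sum(tb$count),
    clean_distinct = nrow(tb),
    raw_total = raw_total,
    raw_distinct = raw_distinct,
    partition = c(n_containing = n_containing, adaptor_only = adaptor_only,
                  singleton_copies = singleton_copies, clean = sum(tb$count))
  )
  class(out) <- "clean_tag_library"
  out
}

#' @export
print.clean_tag_library <- function(x, ...) {
  cat(sprintf("Clean tag library '%s': %s clean tags (%s distinct) of %s raw (%s distinct)\n",
              x$library_id, format(x$clean_total, big.mark = ","),
              format(x$clean_distinct, big.mark = ","),
              format(x$raw_total, big.mark = ","),
              format(x$raw_distinct, big.mark = ",")))
  p <- x$partition
  cat(sprintf("  removed: %s N/malformed, %s adaptor-only, %s singleton copies\n",
              format(p[["n_containing"]], big.mark = ","),
              format(p[["adaptor_only"]], big.mark = ","),
              format(p[["singleton_copies"]], big.mark = ",")))
  invisible(x)
}

#' Percentage with half-up rounding to two decimals
#'
#' Report-style percentage: \code{100 * numerator / denominator}, rounded
#' half-up to 2 decimals (the convention of tag-library summary tables, where
#' e.g. 97.255 prints as 97.26). Scale-invariant in its arguments.
#'
#' @param numerator,denominator non-negative counts; the denominator must be
#'   positive.
#' @return Numeric percentage on the 0-100 scale.
#' @export
tag_percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("percentage undefined for denominator <= 0", call. = FALSE)
  v <- 100 * numerator / denominator
  floor(v * 100 + 0.5 + 1e-9) / 100
}

#' Copy-number distribution of a clean library
#'
#' Bins the clean library by within-library copy number into the standard
#' abundance groups 2-5, 6-10, 11-20, 21-50, 51-100 and above 100, and
#' reports, per bin, the total tag copies and the number of distinct tags.
#' The bins partition the library: totals sum to \code{clean_total} and
#' distinct counts to \code{clean_distinct}.
#'
#' @param clean a \code{\link{filter_tags}} result.
#' @return data.frame with columns \code{bin}, \code{total_copies},
#'   \code{distinct_tags}, \code{pct_copies}, \code{pct_distinct}.
#' @export
copy_number_distribution <- function(clean) {
  stopifnot(inherits(clean, "clean_tag_library"))
  breaks <- c(2, 6, 11, 21, 51, 101, Inf)
  labels <- c("[2,5]", "[6,10]", "[11,20]", "[21,50]", "[51,100]", ">100")
  bin <- cut(clean$counts$count, breaks = breaks, labels = labels,
             right = FALSE)
  total <- vapply(split(clean$counts$count, bin), sum, numeric(1))
  dist <- vapply(split(clean$counts$count, bin), length, numeric(1))
  data.frame(
    bin = labels,
    total_copies = as.numeric(total),
    distinct_tags = as.integer(dist),
    pct_copies = if (clean$clean_total > 0)
      tag_percent(total, clean$clean_total) else rep(0, length(labels)),
    pct_distinct = if (clean$clean_distinct > 0)
      tag_percent(dist, clean$clean_distinct) else rep(0, length(labels)),
    stringsAsFactors = FALSE
  )
}

#' Library QC summary table
#'
#' One summary column per library in report order: raw totals, clean totals,
#' the clean/raw percentage, and the QC partition percentages of the raw
#' total.
#'
#' @param ... \code{clean_tag_library} objects (or a single list of them).
#' @return data.frame, one row per statistic, one column per library.
#' @export
qc_summary <- function(...) {
  libs <- list(...)
  if (length(libs) == 1L && !inherits(libs[[1L]], "clean_tag_library"))
    libs <- libs[[1L]]
  stopifnot(all(vapply(libs, inherits, logical(1), "clean_tag_library")))
  cols <- lapply(libs, function(x) {
    c(`Total number of raw tags` = x$raw_total,
      `Total number of distinct raw tags` = x$raw_distinct,
      `Total number of clean tags` = x$clean_total,
      `Total number of distinct clean tags` = x$clean_distinct,
      `Clean tag/Raw tag (%)` = tag_percent(x$clean_total, x$raw_total),
      `N or malformed tags (% of raw)` = tag_percent(x$partition[["n_containing"]], x$raw_total),
      `Adaptor-only tags (% of raw)` = tag_percent(x$partition[["adaptor_only"]], x$raw_total),
      `Singleton tags (% of raw)` = tag_percent(x$partition[["singleton_copies"]], x$raw_total))
  })
  out <- data.frame(statistic = names(cols[[1L]]), stringsAsFactors = FALSE)
  for (i in seq_along(libs)) out[[libs[[i]]$library_id]] <- unname(cols[[i]])
  out
}
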