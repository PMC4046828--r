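# Round-trippable plain-text artifacts: FASTA for sequences, TSV for tables
# (tab-delimited, header row, '.' decimal), one-tag-per-line text for raw
# streams, JSON for stats and manifests.

#' Write transcripts as FASTA
#' @param transcripts named character vector of sequences.
#' @param path output file.
#' @export
write_transcripts_fasta <- function(transcripts, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(transcripts), path)
  invisible(path)
}

#' Read transcripts from FASTA
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_transcripts_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE,
                                      check.names = FALSE)

#' Write/read a raw tag stream (one tag per line)
#' @param tags character vector of tags.
#' @param path file path.
#' @export
write_tag_stream <- function(tags, path) {
  writeLines(tags, path)
  invisible(path)
}

#' @rdname write_tag_stream
#' @export
read_tag_stream <- function(path) readLines(path)

#' Write/read a tag count table (tag, count TSV)
#' @param counts data.frame with columns \code{tag}, \code{count}, or a
#'   \code{clean_tag_library}.
#' @param path file path.
#' @export
write_tag_counts <- function(counts, path) {
  if (inherits(counts, "clean_tag_library")) counts <- counts$counts
  write_tsv(counts[, c("tag", "count")], path)
}

#' @rdname write_tag_counts
#' @export
read_tag_counts <- function(path) read_tsv(path)

#' Write/read the reference tag index
#'
#' TSV with one row per (tag, strand) entry: tag, comma-joined gene ids,
#' strand, 0-based site offset. The companion stats JSON records the
#' distinct and unambiguous tag counts.
#'
#' @param index a \code{\link{build_tag_index}} object.
#' @param path TSV path.
#' @param stats_path optional JSON path for the index statistics.
#' @export
write_tag_index <- function(index, path, stats_path = NULL) {
  e <- index$entries
  agg <- stats::aggregate(gene_id ~ tag + strand + site_offset, data = e,
                          FUN = function(g) paste(sort(unique(g)), collapse = ","))
  agg <- agg[order(agg$tag, agg$strand), c("tag", "gene_id", "strand", "site_offset")]
  names(agg)[2L] <- "gene_ids"
  write_tsv(agg, path)
  if (!is.null(stats_path)) {
    jsonlite::write_json(index$stats, stats_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write a DE table, category table, or pattern table
#' @param x data.frame (list columns are comma-joined).
#' @param path TSV path.
#' @export
write_result_tsv <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.list(x[[j]]))
      x[[j]] <- vapply(x[[j]], paste, character(1), collapse = ",")
  }
  write_tsv(x, path)
}
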