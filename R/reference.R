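# In-silico NlaIII/MmeI digestion: canonical 21-bp reference tags and the
# mapping index. The protocol captures 3' cDNA fragments, so the canonical
# tag abuts the 3'-most CATG with a full 17-nt window downstream.

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical reference tag of a transcript
#'
#' Finds, on the requested strand (minus means the reverse complement is
#' scanned), the 3'-most CATG followed by at least 17 valid (non-N)
#' nucleotides, and returns the 21-mer CATG + 17 nt. Sites whose 17-nt window
#' contains an N are skipped in favour of the next qualifying site upstream.
#' Absence of a qualifying site is a valid empty result, not an error.
#'
#' @param sequence transcript sequence over A,C,G,T,N.
#' @param strand \code{"+"} or \code{"-"}.
#' @return \code{NULL} if no qualifying site; otherwise a list with
#'   \code{tag} (21-mer), \code{strand}, and \code{site_offset} (0-based
#'   position of the CATG on the oriented strand).
#' @export
canonical_tag <- function(sequence, strand = "+") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  strand <- match.arg(strand, c("+", "-"))
  s <- toupper(sequence)
  if (!grepl("^[ACGTN]*$", s)) stop("sequence must be over A,C,G,T,N", call. = FALSE)
  if (strand == "-") s <- revcomp(s)
  scan_canonical(s, strand)
}

# scan an already-oriented sequence for the 3'-most qualifying CATG site
scan_canonical <- function(s, strand) {
  hits <- gregexpr(ANCHOR, s, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(NULL)
  n <- nchar(s)
  for (pos in rev(as.integer(hits))) {       # 3'-most first
    if (pos + 20L > n) next
    win <- substr(s, pos, pos + 20L)
    if (!grepl("N", win, fixed = TRUE)) {
      return(list(tag = win, strand = strand, site_offset = pos - 1L))
    }
  }
  NULL
}

#' Build the reference tag index
#'
#' Digests every transcript into its canonical tag on the sense strand and,
#' by default, also on the antisense strand, and indexes tag -> gene set.
#' Tags shared by more than one gene are retained but ambiguous; only tags
#' with a single gene are usable for quantification. Index content is a set:
#' it does not depend on transcript input order.
#'
#' @param transcripts named character vector (names are unique gene ids).
#' @param strand_mode \code{"both"} (default) or \code{"sense"}.
#' @return Object of class \code{tag_index}: list with \code{entries}
#'   (data.frame tag/gene_id/strand/site_offset), \code{tags} (sorted distinct
#'   tag vector), \code{genes} (list of gene-id sets parallel to \code{tags}),
#'   \code{n_genes}, \code{gene_ids}, and \code{stats}
#'   (\code{distinct_reference_tags}, \code{unambiguous_reference_tags}).
#' @export
build_tag_index <- function(transcripts, strand_mode = c("both", "sense")) {
  strand_mode <- match.arg(strand_mode)
  if (length(transcripts) == 0L) stop("no transcripts supplied", call. = FALSE)
  ids <- names(transcripts)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("transcripts must be named by gene id", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate gene_id in transcripts", call. = FALSE)
  strands <- if (strand_mode == "both") c("+", "-") else "+"
  seqs <- toupper(as.character(transcripts))
  if (!all(grepl("^[ACGTN]*$", seqs)))
    stop("sequences must be over A,C,G,T,N", call. = FALSE)
  oriented <- list("+" = seqs)
  if (strand_mode == "both") oriented[["-"]] <- revcomp(seqs)
  tag_v <- character(0); gene_v <- character(0)
  strand_v <- character(0); off_v <- integer(0)
  for (st in strands) {
    cts <- lapply(oriented[[st]], scan_canonical, strand = st)
    ok <- !vapply(cts, is.null, logical(1))
    tag_v <- c(tag_v, vapply(cts[ok], `[[`, character(1), "tag"))
    gene_v <- c(gene_v, ids[ok])
    strand_v <- c(strand_v, rep(st, sum(ok)))
    off_v <- c(off_v, vapply(cts[ok], `[[`, integer(1), "site_offset"))
  }
  entries <- data.frame(tag = tag_v, gene_id = gene_v, strand = strand_v,
                        site_offset = off_v, stringsAsFactors = FALSE)
  entries <- entries[order(entries$tag, entries$gene_id, entries$strand), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  tags <- sort(unique(entries$tag))
  genes <- lapply(split(entries$gene_id, factor(entries$tag, levels = tags)),
                  unique)
  idx <- list(
    entries = entries,
    tags = tags,
    genes = unname(genes),
    n_genes = length(transcripts),
    gene_ids = ids,
    strand_mode = strand_mode,
    stats = list(
      distinct_reference_tags = length(tags),
      unambiguous_reference_tags = sum(lengths(genes) == 1L)
    )
  )
  class(idx) <- "tag_index"
  idx
}

#' @export
print.tag_index <- function(x, ...) {
  cat(sprintf("Reference tag index (%s strand): %d genes, %d distinct tags, %d unambiguous\n",
              x$strand_mode, x$n_genes, x$stats$distinct_reference_tags,
              x$stats$unambiguous_reference_tags))
  invisible(x)
}
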