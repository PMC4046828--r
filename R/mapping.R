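# Tag-to-gene assignment with at most one mismatch. Exact hits take
# precedence; an ambiguous exact hit is final (no rescue through mismatch
# neighbors). Mismatches are confined to the 17-nt variable region: the CATG
# anchor is structurally exact, since anchor-corrupted tags were already
# removed at QC.

BASES <- c("A", "C", "G", "T")
# for each base, the three substitution alternatives (rows indexed by base)
ALT_BASES <- matrix(c("C", "G", "T",
                      "A", "G", "T",
                      "A", "C", "T",
                      "A", "C", "G"),
                    nrow = 4L, byrow = TRUE, dimnames = list(BASES, NULL))

# all 51 single-substitution neighbors of each tag, anchor held fixed;
# returns a character vector of length 51 * length(tags), grouped by tag
tag_neighbors <- function(tags) {
  n <- length(tags)
  if (n == 0L) return(character(0))
  reps <- rep(tags, each = 51L)
  pos <- rep(rep(5:21, each = 3L), times = n)
  altk <- rep(rep(1:3, times = 17L), times = n)
  orig <- substring(reps, pos, pos)
  alt <- ALT_BASES[cbind(match(orig, BASES), altk)]
  substring(reps, pos, pos) <- alt
  reps
}

#' Map clean tags to genes
#'
#' Assigns each distinct clean tag to a gene with at most one mismatch.
#' Exact index lookup comes first: a unique gene gives status
#' \code{exact_unique}, several genes give \code{ambiguous} with no mismatch
#' fallback. Tags without an exact hit have their 51 single-substitution
#' neighbors of the 17-nt variable region looked up; the union of hit gene
#' sets decides \code{mismatch_unique}, \code{ambiguous}, or \code{unknown}.
#' A tag hitting the sense and antisense reference tags of the same gene is
#' unique to that gene.
#'
#' @param tags distinct clean tags (character vector) or a
#'   \code{\link{filter_tags}} result.
#' @param index a \code{\link{build_tag_index}} object.
#' @param max_mismatch 0 or 1.
#' @return data.frame with one row per distinct tag: \code{tag},
#'   \code{status} (\code{exact_unique}, \code{mismatch_unique},
#'   \code{ambiguous}, \code{unknown}), \code{gene_id} (NA unless unique),
#'   \code{mismatches}, and a list column \code{genes} holding the full gene
#'   set hit by the tag (empty for unknown).
#' @export
map_tags <- function(tags, index, max_mismatch = 1L) {
  stopifnot(inherits(index, "tag_index"))
  if (inherits(tags, "clean_tag_library")) tags <- tags$counts$tag
  if (length(tags) > 0L && !all(grepl(TAG_REGEX, tags)))
    stop("malformed query tag: clean tags are CATG + 17 nt over A,C,G,T", call. = FALSE)
  if (anyDuplicated(tags)) stop("query tags must be distinct", call. = FALSE)
  if (!max_mismatch %in% c(0L, 1L)) stop("max_mismatch must be 0 or 1", call. = FALSE)
  n <- length(tags)
  status <- rep("unknown", n)
  gene_id <- rep(NA_character_, n)
  mismatches <- rep(NA_integer_, n)
  genes <- vector("list", n)
  for (i in seq_len(n)) genes[[i]] <- character(0)

  pos <- match(tags, index$tags)
  hit <- !is.na(pos)
  if (any(hit)) {
    gsets <- index$genes[pos[hit]]
    sizes <- lengths(gsets)
    st <- ifelse(sizes == 1L, "exact_unique", "ambiguous")
    status[hit] <- st
    gene_id[hit][sizes == 1L] <- vapply(gsets[sizes == 1L], `[[`, character(1), 1L)
    mismatches[hit] <- 0L
    genes[hit] <- gsets
  }

  miss <- which(!hit)
  if (max_mismatch >= 1L && length(miss) > 0L) {
    nb <- tag_neighbors(tags[miss])
    npos <- match(nb, index$tags)
    grp <- rep(seq_along(miss), each = 51L)
    found <- !is.na(npos)
    if (any(found)) {
      per_tag <- split(npos[found], grp[found])
      for (key in names(per_tag)) {
        i <- miss[as.integer(key)]
        gs <- unique(unlist(index$genes[per_tag[[key]]], use.names = FALSE))
        genes[[i]] <- gs
        mismatches[i] <- 1L
        if (length(gs) == 1L) {
          status[i] <- "mismatch_unique"
          gene_id[i] <- gs
        } else {
          status[i] <- "ambiguous"
        }
      }
    }
  }
  out <- data.frame(tag = tags, status = status, gene_id = gene_id,
                    mismatches = mismatches, stringsAsFactors = FALSE)
  out$genes <- genes
  out
}

#' Transcripts per million clean tags
#'
#' @param raw_count unambiguous tag copies of a gene (vectorized).
#' @param clean_total total clean tags of the library; must be positive.
#' @return \code{1e6 * raw_count / clean_total}.
#' @export
tag_tpm <- function(raw_count, clean_total) {
  if (any(clean_total <= 0)) stop("TPM undefined for clean_total <= 0", call. = FALSE)
  1e6 * raw_count / clean_total
}

#' Per-gene expression and library mapping summary
#'
#' Aggregates mapping results into per-gene unambiguous tag counts and TPM,
#' and computes the standard library mapping report: tags mapping to genes
#' (copies and distinct), all tag-mapped genes (any hit, ambiguous included),
#' unambiguous tags and genes, and unknown tags, with copy percentages over
#' the clean total, distinct percentages over the distinct clean count, and
#' gene percentages over the number of reference genes.
#'
#' @param mapping result of \code{\link{map_tags}} on the clean library's
#'   distinct tags.
#' @param clean the \code{\link{filter_tags}} result.
#' @param index the \code{\link{build_tag_index}} object.
#' @return List with \code{expression} (data.frame \code{gene_id},
#'   \code{library_id}, \code{raw_count}, \code{tpm}; genes with zero counts
#'   omitted) and \code{summary} (data.frame statistic/value).
#' @export
count_genes <- function(mapping, clean, index) {
  stopifnot(inherits(clean, "clean_tag_library"), inherits(index, "tag_index"))
  ct <- clean$counts
  mrow <- match(ct$tag, mapping$tag)
  if (anyNA(mrow))
    stop("internal consistency error: mapping result missing for a clean tag",
         call. = FALSE)
  status <- mapping$status[mrow]
  copies <- ct$count
  uniq <- status %in% c("exact_unique", "mismatch_unique")
  gene <- mapping$gene_id[mrow]

  raw_count <- vapply(split(copies[uniq], gene[uniq]), sum, numeric(1))
  expr <- data.frame(gene_id = names(raw_count),
                     library_id = rep(clean$library_id, length(raw_count)),
                     raw_count = as.numeric(raw_count),
                     tpm = if (clean$clean_total > 0)
                       tag_tpm(as.numeric(raw_count), clean$clean_total) else
                       rep(0, length(raw_count)),
                     stringsAsFactors = FALSE)
  expr <- expr[order(expr$gene_id), , drop = FALSE]
  rownames(expr) <- NULL

  mapped <- status != "unknown"
  all_genes <- unique(unlist(mapping$genes[mrow[mapped]], use.names = FALSE))
  uniq_genes <- unique(gene[uniq])
  ctot <- clean$clean_total
  cdis <- clean$clean_distinct
  ngen <- index$n_genes
  pc <- function(x, d) if (d > 0) tag_percent(x, d) else NA_real_
  stats <- c(
    `Total number of clean tags` = ctot,
    `Total number of distinct clean tags` = cdis,
    `Total number of tags mapping to genes` = sum(copies[mapped]),
    `% of tags mapping to genes` = pc(sum(copies[mapped]), ctot),
    `Total number of distinct tags mapping to gene` = sum(mapped),
    `% of distinct tags mapping to gene` = pc(sum(mapped), cdis),
    `Number of all tag-mapped genes` = length(all_genes),
    `% of all tag-mapped genes` = pc(length(all_genes), ngen),
    `Number of unambiguous tags mapping to gene` = sum(copies[uniq]),
    `% of unambiguous tags mapping to gene` = pc(sum(copies[uniq]), ctot),
    `Number of distinct unambiguous tags mapping to gene` = sum(uniq),
    `% of distinct unambiguous tags mapping to gene` = pc(sum(uniq), cdis),
    `Number of unambiguous tag-mapped genes` = length(uniq_genes),
    `% of unambiguous tag-mapped genes` = pc(length(uniq_genes), ngen),
    `Number of unknown tags` = sum(copies[!mapped]),
    `% of unknown tags` = pc(sum(copies[!mapped]), ctot),
    `Number of distinct unknown tags` = sum(!mapped),
    `% of distinct unknown tags` = pc(sum(!mapped), cdis)
  )
  list(expression = expr,
       summary = data.frame(statistic = names(stats), value = unname(stats),
                            stringsAsFactors = FALSE))
}

#' Expression matrix across libraries
#'
#' Convenience: binds per-library expression records into a genes x libraries
#' count matrix and TPM matrix (genes absent from a library get 0).
#'
#' @param records list of \code{count_genes()$expression} data.frames.
#' @return List with \code{counts} and \code{tpm} matrices (rownames gene
#'   ids, colnames library ids).
#' @export
expression_matrix <- function(records) {
  stopifnot(length(records) > 0L)
  genes <- sort(unique(unlist(lapply(records, `[[`, "gene_id"))))
  libs <- vapply(records, function(r) r$library_id[1L], character(1))
  cnt <- matrix(0, length(genes), length(records),
                dimnames = list(genes, libs))
  tpm <- cnt
  for (j in seq_along(records)) {
    r <- records[[j]]
    i <- match(r$gene_id, genes)
    cnt[i, j] <- r$raw_count
    tpm[i, j] <- r$tpm
  }
  list(counts = cnt, tpm = tpm)
}
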