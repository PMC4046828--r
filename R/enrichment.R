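# Hypergeometric pathway enrichment of a differentially-expressed gene set
# against a gene -> pathway annotation, on the standard variables:
# N annotated genes, n DEGs among them, M genes in the pathway, m DEGs in it.

#' Read a GMT annotation file
#'
#' One pathway per line: id, description, then member gene ids,
#' tab-separated.
#'
#' @param path file path.
#' @return List with \code{pathways} (named list of gene-id vectors) and
#'   \code{descriptions} (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("GMT lines need id, description and at least one gene", call. = FALSE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate pathway id in GMT", call. = FALSE)
  pw <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(pw) <- ids
  list(pathways = pw,
       descriptions = setNames(vapply(parts, `[[`, character(1), 2L), ids))
}

#' Write a GMT annotation file
#'
#' @param annotation list with \code{pathways} and \code{descriptions} as
#'   returned by \code{\link{read_gmt}} or \code{\link{sim_annotation}}.
#' @param path file path.
#' @export
write_gmt <- function(annotation, path) {
  ids <- names(annotation$pathways)
  lines <- vapply(ids, function(id) {
    paste(c(id, annotation$descriptions[[id]], annotation$pathways[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Hypergeometric pathway enrichment
#'
#' For each pathway, tests whether the DEG set is over-represented among its
#' members: with N annotated genes, n DEGs among them, M pathway members and
#' m DEG members, P = P(X >= m) for X hypergeometric(N, M, n). DEGs without
#' any annotation are dropped (with a message). Significance is flagged on
#' the raw P at \code{p_max}; a Benjamini-Hochberg column is provided
#' alongside.
#'
#' @param deg_set character vector of differentially expressed gene ids.
#' @param annotation list with \code{pathways} (named list of gene vectors)
#'   and optional \code{descriptions}.
#' @param p_max raw-P significance threshold (default 0.05).
#' @return data.frame sorted by P: \code{pathway_id}, \code{description},
#'   \code{N}, \code{n}, \code{M}, \code{m}, \code{P}, \code{P_adjusted},
#'   \code{significant}.
#' @export
pathway_enrich <- function(deg_set, annotation, p_max = 0.05) {
  pw <- annotation$pathways
  if (is.null(pw) || length(pw) == 0L) stop("empty annotation", call. = FALSE)
  if (any(lengths(pw) == 0L)) stop("annotation retains an empty pathway", call. = FALSE)
  desc <- annotation$descriptions
  if (is.null(desc)) desc <- setNames(rep("", length(pw)), names(pw))
  universe <- unique(unlist(pw, use.names = FALSE))
  deg_set <- unique(deg_set)
  dropped <- setdiff(deg_set, universe)
  if (length(dropped) > 0L)
    message(length(dropped), " DEG(s) without annotation dropped")
  degs <- intersect(deg_set, universe)
  N <- length(universe)
  n <- length(degs)
  M <- lengths(lapply(pw, unique))
  m <- vapply(pw, function(g) length(intersect(g, degs)), integer(1))
  if (any(m > pmin(n, M)))
    stop("internal consistency error: m exceeds min(n, M)", call. = FALSE)
  P <- phyper(m - 1, M, N - M, n, lower.tail = FALSE)
  out <- data.frame(
    pathway_id = names(pw),
    description = unname(desc[names(pw)]),
    N = N, n = n, M = as.integer(M), m = as.integer(m),
    P = as.numeric(P),
    P_adjusted = bh_fdr(as.numeric(P)),
    stringsAsFactors = FALSE
  )
  out$significant <- out$P <= p_max
  out <- out[order(out$P, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
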