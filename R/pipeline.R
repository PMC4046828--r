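# End-to-end orchestration: simulate -> build reference -> QC -> map ->
# quantify -> pairwise DE -> categories & patterns -> enrichment ->
# saturation, with every artifact written as plain text and a manifest that
# reproduces the run byte-identically.

#' Run the full tag-DGE pipeline on a simulated experiment
#'
#' Chains all analysis stages for a \code{\link{sim_config}} experiment and
#' writes the artifacts under \code{out_dir}: transcript FASTA, ground-truth
#' TSV, per-stage raw tag streams and clean tag counts, QC and mapping
#' summaries, count/TPM matrices, per-pair DE tables, expression categories,
#' five-stage pattern calls (when \code{n_stages == 5}), pathway enrichment
#' of each DE set (when an annotation is supplied or simulated), saturation
#' curves, and a JSON manifest with the configuration and seed. All
#' randomness flows from \code{config$seed}; a re-run with the same
#' configuration is byte-identical.
#'
#' @param config a \code{\link{sim_config}} object.
#' @param out_dir output directory (created if missing); \code{NULL} runs the
#'   pipeline in memory only.
#' @param annotation optional annotation list (\code{pathways},
#'   \code{descriptions}); if \code{NULL}, one is simulated from the gene set.
#' @param strand_mode passed to \code{\link{build_tag_index}}.
#' @param max_mismatch passed to \code{\link{map_tags}}.
#' @param fdr_max,min_abs_log2 DE thresholds, see \code{\link{call_de}}.
#' @param saturation logical: compute saturation curves (stage 1 library).
#' @param saturation_replicates replicates for the saturation curve.
#' @return Invisibly, a list with all in-memory stage results: \code{config},
#'   \code{transcripts}, \code{truth}, \code{index}, \code{clean} (list),
#'   \code{mappings} (list), \code{counts} (list), \code{matrix},
#'   \code{summaries}, \code{de} (list of \code{dge_de_table}),
#'   \code{categories}, \code{patterns}, \code{enrichment}, \code{saturation}.
#' @export
run_dge_pipeline <- function(config, out_dir = NULL, annotation = NULL,
                             strand_mode = c("both", "sense"),
                             max_mismatch = 1L,
                             fdr_max = 0.001, min_abs_log2 = 1,
                             saturation = TRUE, saturation_replicates = 3L) {
  stopifnot(inherits(config, "dge_sim_config"))
  strand_mode <- match.arg(strand_mode)
  emit <- !is.null(out_dir)
  if (emit && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  pth <- function(...) file.path(out_dir, paste0(...))

  transcripts <- sim_transcriptome(config)
  truth <- sim_ground_truth(config)
  index <- build_tag_index(transcripts, strand_mode)
  if (is.null(annotation))
    annotation <- sim_annotation(names(transcripts), seed = config$seed + 7L)

  stages <- seq_len(config$n_stages)
  lib_ids <- paste0("FS", stages)
  clean <- vector("list", length(stages)); names(clean) <- lib_ids
  mappings <- clean; counts <- clean
  for (s in stages) {
    raw <- sim_tag_library(transcripts, truth, s, config)
    if (emit) write_tag_stream(raw, pth("raw_tags_", lib_ids[s], ".txt"))
    cl <- filter_tags(raw, adaptor_tags = config$adaptor_tag,
                      library_id = lib_ids[s])
    mp <- map_tags(cl, index, max_mismatch = max_mismatch)
    cn <- count_genes(mp, cl, index)
    clean[[s]] <- cl; mappings[[s]] <- mp; counts[[s]] <- cn
    if (emit) {
      write_tag_counts(cl, pth("clean_tags_", lib_ids[s], ".tsv"))
      write_result_tsv(mp[, c("tag", "status", "gene_id", "mismatches")],
                       pth("mapping_", lib_ids[s], ".tsv"))
    }
  }

  mat <- expression_matrix(lapply(counts, `[[`, "expression"))
  qc_tab <- qc_summary(clean)
  map_tab <- counts[[1L]]$summary
  for (s in stages[-1L]) map_tab[[lib_ids[s]]] <- counts[[s]]$summary$value
  names(map_tab)[2L] <- lib_ids[1L]

  de <- vector("list", config$n_stages - 1L)
  names(de) <- paste0(lib_ids[-length(lib_ids)], "_vs_", lib_ids[-1L])
  enr <- vector("list", length(de)); names(enr) <- names(de)
  for (p in seq_along(de)) {
    a <- setNames(mat$counts[, p], rownames(mat$counts))
    b <- setNames(mat$counts[, p + 1L], rownames(mat$counts))
    de[[p]] <- dge_compare(a, b, clean[[p]]$clean_total,
                           clean[[p + 1L]]$clean_total,
                           library_ids = lib_ids[c(p, p + 1L)],
                           fdr_max = fdr_max, min_abs_log2 = min_abs_log2)
    degs <- de[[p]]$gene_id[de[[p]]$call != "ns"]
    enr[[p]] <- if (length(degs) > 0L)
      suppressMessages(pathway_enrich(degs, annotation)) else NULL
  }

  categories <- data.frame(
    gene_id = rep(rownames(mat$tpm), times = ncol(mat$tpm)),
    library_id = rep(colnames(mat$tpm), each = nrow(mat$tpm)),
    tpm = as.numeric(mat$tpm),
    category = as.character(tpm_category(as.numeric(mat$tpm))),
    stringsAsFactors = FALSE
  )
  patterns <- if (config$n_stages == 5L) classify_patterns(mat$tpm) else NULL

  sat <- if (saturation)
    saturation_curve(mappings[[1L]], clean[[1L]],
                     replicates = saturation_replicates,
                     seed = config$seed + 13L) else NULL

  if (emit) {
    write_transcripts_fasta(transcripts, pth("transcripts.fasta"))
    truth_df <- data.frame(gene_id = rownames(truth$abundance),
                           truth$abundance, truth$log2fc,
                           de = apply(truth$de, 1L, any),
                           check.names = FALSE)
    write_tsv(truth_df, pth("ground_truth.tsv"))
    write_tag_index(index, pth("reference_tags.tsv"), pth("reference_stats.json"))
    write_tsv(qc_tab, pth("qc_summary.tsv"))
    write_tsv(map_tab, pth("mapping_summary.tsv"))
    write_tsv(data.frame(gene_id = rownames(mat$counts), mat$counts,
                         check.names = FALSE), pth("counts.tsv"))
    write_tsv(data.frame(gene_id = rownames(mat$tpm), mat$tpm,
                         check.names = FALSE), pth("tpm.tsv"))
    for (p in names(de))
      write_result_tsv(de[[p]], pth("de_", p, ".tsv"))
    write_tsv(categories, pth("categories.tsv"))
    if (!is.null(patterns)) write_tsv(patterns, pth("patterns.tsv"))
    for (p in names(enr))
      if (!is.null(enr[[p]])) write_result_tsv(enr[[p]], pth("enrichment_", p, ".tsv"))
    if (!is.null(sat)) write_tsv(sat, pth("saturation.tsv"))
    write_gmt(annotation, pth("annotation.gmt"))
    manifest <- list(
      package = "tagdge",
      version = as.character(utils::packageVersion("tagdge")),
      config = unclass(config),
      strand_mode = strand_mode, max_mismatch = max_mismatch,
      fdr_max = fdr_max, min_abs_log2 = min_abs_log2,
      saturation = saturation, saturation_replicates = saturation_replicates
    )
    jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  invisible(list(config = config, transcripts = transcripts, truth = truth,
                 index = index, annotation = annotation, clean = clean,
                 mappings = mappings, counts = counts, matrix = mat,
                 summaries = list(qc = qc_tab, mapping = map_tab),
                 de = de, categories = categories, patterns = patterns,
                 enrichment = enr, saturation = sat))
}

#' Re-run a pipeline from its manifest
#'
#' Reads a \code{manifest.json} written by \code{\link{run_dge_pipeline}} and
#' repeats the run with the identical configuration, seed and thresholds.
#'
#' @param manifest_path path to a manifest JSON.
#' @param out_dir output directory for the re-run.
#' @return See \code{\link{run_dge_pipeline}}.
#' @export
rerun_from_manifest <- function(manifest_path, out_dir) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- do.call(sim_config, m$config[setdiff(names(m$config), character(0))])
  run_dge_pipeline(cfg, out_dir = out_dir,
                   strand_mode = m$strand_mode,
                   max_mismatch = as.integer(m$max_mismatch),
                   fdr_max = m$fdr_max, min_abs_log2 = m$min_abs_log2,
                   saturation = isTRUE(m$saturation),
                   saturation_replicates = as.integer(m$saturation_replicates))
}
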