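# Seeded simulation of transcript references and raw tag libraries with known
# ground truth. The simulator is first-class: every downstream stage of the
# pipeline is tested against the truth it plants.

#' Simulation configuration
#'
#' Builds and validates the configuration for a simulated tag-DGE experiment.
#' Defaults describe a five-stage fruit-development style experiment at
#' sequencing scale: ~90k reference transcripts, ~6 million raw tags per
#' library, a per-base substitution error rate of 0.002, and small fractions
#' of N-containing and adaptor-only artifact tags. Tests and examples
#' typically override \code{n_genes} and \code{depth_per_stage} downwards.
#'
#' @param n_genes number of reference transcripts.
#' @param length_min,length_max transcript length bounds (bp, uniform).
#'   \code{length_min} must be at least 25 so a CATG site plus 17 downstream
#'   nucleotides can fit.
#' @param gc_content GC fraction of simulated bases, in `[0,1]`.
#' @param n_stages number of developmental stages (libraries), at least 2.
#' @param expr_log_mean,expr_log_sd log-normal parameters of the baseline
#'   relative abundance of each gene.
#' @param de_fraction fraction of genes planted as differentially expressed
#'   per adjacent stage pair (an exact-size random subset).
#' @param log2fc_min,log2fc_max bounds of the planted absolute log2 fold
#'   change; the sign of each planted effect is random.
#' @param depth_per_stage raw tags emitted per library.
#' @param substitution_rate per-base substitution error probability applied
#'   i.i.d. to all 21 tag positions (including the CATG anchor).
#' @param n_tag_rate fraction of raw stream positions replaced by
#'   N-containing artifact tags.
#' @param adaptor_tag_rate fraction of raw stream positions replaced by the
#'   adaptor-only artifact tag.
#' @param siteless_fraction fraction of transcripts allowed to lack a
#'   qualifying CATG site (0 = every transcript is rejection-sampled to carry
#'   one; 1 = unconditioned i.i.d. sequences).
#' @param adaptor_tag the 21-mer emitted as adaptor-only artifact.
#' @param seed integer RNG seed; all simulator randomness derives from it.
#' @return A validated list of class \code{dge_sim_config}.
#' @export
sim_config <- function(n_genes = 90227L,
                       length_min = 150L, length_max = 900L,
                       gc_content = 0.45,
                       n_stages = 5L,
                       expr_log_mean = 0, expr_log_sd = 2,
                       de_fraction = 0.05,
                       log2fc_min = 1, log2fc_max = 4,
                       depth_per_stage = 6e6,
                       substitution_rate = 0.002,
                       n_tag_rate = 0.005,
                       adaptor_tag_rate = 0.002,
                       siteless_fraction = 0,
                       adaptor_tag = DGE_ADAPTOR_TAG,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), length_min = as.integer(length_min),
    length_max = as.integer(length_max), gc_content = gc_content,
    n_stages = as.integer(n_stages),
    expr_log_mean = expr_log_mean, expr_log_sd = expr_log_sd,
    de_fraction = de_fraction, log2fc_min = log2fc_min,
    log2fc_max = log2fc_max, depth_per_stage = as.integer(depth_per_stage),
    substitution_rate = substitution_rate, n_tag_rate = n_tag_rate,
    adaptor_tag_rate = adaptor_tag_rate,
    siteless_fraction = siteless_fraction,
    adaptor_tag = as.character(adaptor_tag), seed = as.integer(seed)
  )
  frac <- c("gc_content", "de_fraction", "substitution_rate", "n_tag_rate",
            "adaptor_tag_rate", "siteless_fraction")
  for (f in frac) {
    if (!is.numeric(cfg[[f]]) || is.na(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("'%s' must be a fraction in [0,1]", f), call. = FALSE)
  }
  if (cfg$n_genes < 0) stop("'n_genes' must be non-negative", call. = FALSE)
  if (cfg$length_max < 25L)
    stop("'length_max' below 25 bp leaves no room for a CATG site plus 17 nt",
         call. = FALSE)
  if (cfg$length_min < 25L) stop("'length_min' must be at least 25", call. = FALSE)
  if (cfg$length_min > cfg$length_max)
    stop("'length_min' must not exceed 'length_max'", call. = FALSE)
  if (cfg$n_stages < 2L) stop("'n_stages' must be at least 2", call. = FALSE)
  if (cfg$log2fc_min > cfg$log2fc_max)
    stop("'log2fc_min' must not exceed 'log2fc_max'", call. = FALSE)
  if (cfg$log2fc_min < 0) stop("planted |log2fc| bounds must be non-negative", call. = FALSE)
  if (cfg$depth_per_stage < 0) stop("'depth_per_stage' must be non-negative", call. = FALSE)
  if (cfg$n_tag_rate + cfg$adaptor_tag_rate > 1)
    stop("artifact rates must sum to at most 1", call. = FALSE)
  if (is.na(cfg$seed) || cfg$seed < 0L || cfg$seed > 2^31 - 1e6)
    stop("'seed' must be a non-negative integer below 2^31 - 1e6", call. = FALSE)
  class(cfg) <- "dge_sim_config"
  cfg
}

# evaluate expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

has_tag_site <- function(seqs) grepl("CATG[ACGT]{17}", seqs)

#' Simulate a transcript reference
#'
#' Generates \code{n_genes} transcripts with i.i.d. bases at the configured GC
#' content and uniform lengths. By default every transcript is
#' rejection-sampled to contain at least one CATG with 17 nt downstream (so a
#' canonical tag exists); \code{siteless_fraction} relaxes this for edge-case
#' testing. Deterministic under \code{config$seed}.
#'
#' @param config a \code{\link{sim_config}} object.
#' @return Named character vector of transcript sequences (names are gene ids
#'   \code{g000001, ...}).
#' @export
sim_transcriptome <- function(config) {
  stopifnot(inherits(config, "dge_sim_config"))
  g <- config$n_genes
  if (g == 0L) return(setNames(character(0), character(0)))
  with_seed(config$seed, {
    lens <- if (config$length_min == config$length_max)
      rep(config$length_min, g)
    else
      sample(seq.int(config$length_min, config$length_max), g, replace = TRUE)
    bases <- random_bases(sum(lens), config$gc_content)
    seqs <- vapply(split(bases, rep.int(seq_len(g), lens)), paste0,
                   character(1), collapse = "")
    names(seqs) <- NULL
    allowed <- floor(config$siteless_fraction * g)
    siteless <- which(!has_tag_site(seqs))
    # keep at most `allowed` siteless transcripts (first encountered),
    # regenerate the rest until they carry a qualifying site
    redo <- siteless[seq_along(siteless) > allowed]
    guard <- 0L
    while (length(redo) > 0L) {
      ln <- lens[redo]
      nb <- random_bases(sum(ln), config$gc_content)
      seqs[redo] <- vapply(split(nb, rep.int(seq_along(redo), ln)), paste0,
                           character(1), collapse = "")
      redo <- redo[!has_tag_site(seqs[redo])]
      guard <- guard + 1L
      if (guard > 10000L)
        stop("rejection sampling failed to place CATG sites; lengthen transcripts")
    }
    setNames(seqs, sprintf("g%06d", seq_len(g)))
  })
}

#' Plant per-stage expression levels and fold changes
#'
#' Draws a log-normal baseline abundance for every gene, normalizes each stage
#' to the unit simplex, and for each adjacent stage pair multiplies an
#' exact-size random subset (\code{de_fraction} of genes) by
#' \code{2^(s*u)} with \code{u ~ Uniform[log2fc_min, log2fc_max]} and random
#' sign \code{s}, re-normalizing afterwards. The planted (pre-normalization)
#' log2 fold change is recorded as truth; non-planted genes have exactly 0.
#'
#' @param config a \code{\link{sim_config}} object.
#' @return List of class \code{dge_ground_truth}: \code{abundance}
#'   (genes x stages, columns sum to 1), \code{log2fc} and \code{de}
#'   (genes x adjacent pairs).
#' @export
sim_ground_truth <- function(config) {
  stopifnot(inherits(config, "dge_sim_config"))
  g <- config$n_genes
  s <- config$n_stages
  ids <- sprintf("g%06d", seq_len(g))
  with_seed(config$seed + 1L, {
    base <- rlnorm(g, config$expr_log_mean, config$expr_log_sd)
    ab <- matrix(0, g, s, dimnames = list(ids, paste0("FS", seq_len(s))))
    fc <- matrix(0, g, s - 1L,
                 dimnames = list(ids, paste0("FS", seq_len(s - 1L), "_FS", 2:s)))
    de <- matrix(FALSE, g, s - 1L, dimnames = dimnames(fc))
    if (g > 0L) {
      w <- base / sum(base)
      ab[, 1L] <- w
      n_de <- round(config$de_fraction * g)
      for (p in seq_len(s - 1L)) {
        idx <- sample.int(g, n_de)
        u <- runif(n_de, config$log2fc_min, config$log2fc_max)
        sgn <- sample(c(-1, 1), n_de, replace = TRUE)
        fc[idx, p] <- sgn * u
        de[idx, p] <- TRUE
        w <- w * 2^fc[, p]
        w <- w / sum(w)
        ab[, p + 1L] <- w
      }
    }
    structure(list(abundance = ab, log2fc = fc, de = de),
              class = "dge_ground_truth")
  })
}

# mutate k>=1 random positions of each tag (character vector), substitution
# to one of the three other bases; positions uniform over the full 21-mer
mutate_tags <- function(tags, n_subs) {
  if (length(tags) == 0L) return(tags)
  mat <- matrix(unlist(strsplit(tags, "", fixed = TRUE), use.names = FALSE),
                nrow = length(tags), byrow = TRUE)
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(tags)) {
    pos <- sample.int(TAG_WIDTH, n_subs[i])
    for (p in pos) {
      mat[i, p] <- sample(bases[bases != mat[i, p]], 1L)
    }
  }
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

#' Simulate one raw tag library
#'
#' Emits exactly \code{depth_per_stage} 21-bp tags for one stage. Each real
#' tag is the source gene's canonical sense-strand tag with i.i.d. base
#' substitutions at \code{substitution_rate}; fractions \code{n_tag_rate} and
#' \code{adaptor_tag_rate} of stream positions are replaced by artifact tags
#' (a canonical tag with an N planted at a random position; the configured
#' adaptor 21-mer). Artifacts replace rather than add, so the stream length is
#' exact. Genes without a canonical tag receive sampling weight zero.
#'
#' @param transcripts named character vector from \code{\link{sim_transcriptome}}.
#' @param truth a \code{\link{sim_ground_truth}} result.
#' @param stage stage index in \code{1..n_stages}.
#' @param config a \code{\link{sim_config}} object.
#' @return Character vector of raw tags (length \code{depth_per_stage}) with
#'   attribute \code{true_counts}: the per-gene count of real tags sampled
#'   from each gene before error injection (named integer vector).
#' @export
sim_tag_library <- function(transcripts, truth, stage, config) {
  stopifnot(inherits(config, "dge_sim_config"))
  if (stage < 1L || stage > config$n_stages) stop("stage index out of range", call. = FALSE)
  g <- length(transcripts)
  canon <- rep(NA_character_, g)
  if (g > 0L) {
    ct <- lapply(transcripts, canonical_tag)
    ok <- lengths(ct) > 0L
    canon[ok] <- vapply(ct[ok], function(x) x$tag, character(1))
  }
  n <- config$depth_per_stage
  out <- character(n)
  if (n == 0L) {
    attr(out, "true_counts") <- setNames(integer(g), names(transcripts))
    return(out)
  }
  w <- truth$abundance[, stage]
  w[is.na(canon)] <- 0
  if (sum(w) <= 0) stop("no gene with a canonical tag has positive abundance", call. = FALSE)
  with_seed(config$seed + 100L + stage, {
    u <- runif(n)
    kind <- ifelse(u < config$n_tag_rate, 1L,
                   ifelse(u < config$n_tag_rate + config$adaptor_tag_rate, 2L, 0L))
    n_real <- sum(kind == 0L)
    gene_idx <- sample.int(g, n_real, replace = TRUE, prob = w)
    tags <- canon[gene_idx]
    n_subs <- rbinom(n_real, TAG_WIDTH, config$substitution_rate)
    err <- which(n_subs > 0L)
    if (length(err) > 0L) tags[err] <- mutate_tags(tags[err], n_subs[err])
    out[kind == 0L] <- tags
    n_art <- sum(kind == 1L)
    if (n_art > 0L) {
      src <- canon[sample.int(g, n_art, replace = TRUE, prob = w)]
      pos <- sample.int(TAG_WIDTH, n_art, replace = TRUE)
      substring(src, pos, pos) <- "N"
      out[kind == 1L] <- src
    }
    out[kind == 2L] <- config$adaptor_tag
    attr(out, "true_counts") <- setNames(tabulate(gene_idx, nbins = g),
                                         names(transcripts))
    out
  })
}

#' Simulate gene-to-pathway annotation
#'
#' Random pathway membership for enrichment analysis on simulated data: each
#' pathway draws a uniform random gene set of size within \code{size_range}.
#' Genes may belong to several pathways; empty pathways cannot occur.
#'
#' @param gene_ids character vector of gene identifiers.
#' @param n_pathways number of pathways.
#' @param size_range integer bounds of pathway size (clipped to the number of
#'   genes available).
#' @param seed RNG seed.
#' @return List with \code{pathways} (named list of gene-id vectors) and
#'   \code{descriptions} (named character).
#' @export
sim_annotation <- function(gene_ids, n_pathways = 20L, size_range = c(10L, 100L),
                           seed = 1L) {
  stopifnot(length(gene_ids) > 0L, n_pathways >= 1L)
  size_range <- pmin(pmax(as.integer(size_range), 1L), length(gene_ids))
  with_seed(seed, {
    ids <- sprintf("path%03d", seq_len(n_pathways))
    sizes <- if (size_range[1L] == size_range[2L])
      rep(size_range[1L], n_pathways)
    else
      sample(seq.int(size_range[1L], size_range[2L]), n_pathways,
             replace = TRUE)
    pw <- lapply(sizes, function(k) sample(gene_ids, k))
    names(pw) <- ids
    list(pathways = pw,
         descriptions = setNames(paste("simulated pathway", seq_len(n_pathways)), ids))
  })
}

#' @export
print.dge_sim_config <- function(x, ...) {
  cat("Tag-DGE simulation config:\n")
  cat(sprintf("  %d genes (%d-%d bp, GC %.2f), %d stages, depth %s tags/stage\n",
              x$n_genes, x$length_min, x$length_max, x$gc_content, x$n_stages,
              format(x$depth_per_stage, big.mark = ",")))
  cat(sprintf("  DE: %.1f%% of genes per pair, |log2FC| in [%g, %g]\n",
              100 * x$de_fraction, x$log2fc_min, x$log2fc_max))
  cat(sprintf("  noise: substitution %.4g/base, N-artifacts %.4g, adaptor %.4g; seed %d\n",
              x$substitution_rate, x$n_tag_rate, x$adaptor_tag_rate, x$seed))
  invisible(x)
}
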