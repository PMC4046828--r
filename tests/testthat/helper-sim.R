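# small, fast study configurations used across tests

small_cfg <- function(...) {
  args <- list(n_genes = 60L, depth_per_stage = 8000L,
               length_min = 100L, length_max = 300L,
               n_stages = 3L, seed = 7L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# simulated experiment shared by conservation-style tests
shared_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- small_cfg()
      tr <- sim_transcriptome(cfg)
      tru <- sim_ground_truth(cfg)
      idx <- build_tag_index(tr)
      raw <- sim_tag_library(tr, tru, 1L, cfg)
      cl <- filter_tags(raw, cfg$adaptor_tag, "FS1")
      mp <- map_tags(cl, idx)
      cn <- count_genes(mp, cl, idx)
      cache <<- list(cfg = cfg, tr = tr, tru = tru, idx = idx, raw = raw,
                     cl = cl, mp = mp, cn = cn)
    }
    cache
  }
})
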