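# Write a small synthetic multi-TF dataset (BEDs + layout + config) to `dir`
# and return the path of the YAML config for run_all().
write_fixture_config <- function(dir, seed = 1L, n_hubs = 6L,
                                 background_per_tf = 40L, null_reps = 50L) {
  spec <- hub_fixture_spec(seed = seed, n_hubs = n_hubs,
                           background_per_tf = background_per_tf)
  gen <- generate_sitesets(spec)
  beds <- list()
  for (s in gen$sitesets) {
    p <- file.path(dir, paste0(tf_label(s), ".bed"))
    writeLines(sprintf("%s\t%s\t%s", s$chrom,
                       format(s$position, scientific = FALSE, trim = TRUE),
                       format(s$position + 1, scientific = FALSE, trim = TRUE)),
               p)
    beds[[tf_label(s)]] <- p
  }
  layout_path <- file.path(dir, "layout.tsv")
  write_chromosome_lengths(spec$layout, layout_path)
  cfg_path <- file.path(dir, "run.yaml")
  yaml::write_yaml(list(beds = beds, layout = layout_path,
                        gap = 200, span_cap = 500, window = 200,
                        null_reps = null_reps, seed = seed,
                        outdir = file.path(dir, "out")),
                   cfg_path)
  cfg_path
}
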