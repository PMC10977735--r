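# Shared heavy computations, evaluated lazily and cached for the test run.

.series_cache <- new.env(parent = emptyenv())

# per-cell feature rows along a one-knob generator series
pheno_series_cells <- function(knob, values = c(0, 0.25, 0.5, 0.75, 1),
                               n_fields = 5, base_seed = 100) {
  key <- paste0(knob, "_", n_fields, "_", base_seed)
  if (!is.null(.series_cache[[key]])) return(.series_cache[[key]])
  out <- lapply(values, function(v) {
    rows <- do.call(rbind, lapply(seq_len(n_fields), function(i) {
      p <- unclass(synth_params(seed = base_seed + i))
      p[[knob]] <- v
      sim <- generate_field(do.call(synth_params, p))
      feats <- process_field(sim$field)$features
      feats$level <- v
      feats
    }))
    rows
  })
  res <- do.call(rbind, out)
  .series_cache[[key]] <- res
  res
}

series_level_means <- function(cells, feature) {
  tapply(cells[[feature]], cells$level, mean, na.rm = TRUE)
}

# noiseless field + full pipeline result, cached per seed
recovery_fixture <- function(seed = 3) {
  key <- paste0("rec_", seed)
  if (!is.null(.series_cache[[key]])) return(.series_cache[[key]])
  sim <- generate_field(synth_params(seed = seed, noise_level = 0,
                                     psf_sigma = 0.5))
  res <- process_field(sim$field)
  .series_cache[[key]] <- list(sim = sim, res = res)
  .series_cache[[key]]
}

# small single-cell fields written as TIFF triplets, plus pipeline runs at
# 1 and 2 workers; cached
pipeline_fixture <- function() {
  if (!is.null(.series_cache$pipeline)) return(.series_cache$pipeline)
  root <- file.path(tempdir(), "mitomorph-pipeline-fixture")
  in_dir <- file.path(root, "in")
  for (i in 1:3) {
    sim <- generate_field(synth_params(n_cells = 1, image_side = 300,
                                       seed = 200 + i),
                          field_id = sprintf("f%02d", i))
    write_field_tiffs(sim$field, in_dir, id = sprintf("f%02d", i))
  }
  pats <- list(nuclei = "*_c1.tif", cell = "*_c2.tif", mito = "*_c3.tif")
  out1 <- file.path(root, "out1"); out2 <- file.path(root, "out2")
  r1 <- run_pipeline(run_config(in_dir, pats, out1, n_workers = 1,
                                condition = "ctrl"))
  r2 <- run_pipeline(run_config(in_dir, pats, out2, n_workers = 2,
                                condition = "ctrl"))
  .series_cache$pipeline <- list(in_dir = in_dir, patterns = pats,
                                 out1 = out1, out2 = out2, r1 = r1, r2 = r2)
  .series_cache$pipeline
}
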