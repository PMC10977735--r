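# Batch processing: discover fields in a folder by channel glob patterns,
# process each field independently (optionally in parallel), write masks,
# the folder-level per-cell CSV and a run manifest; condition comparison
# runs the morphospace stage end-to-end.

#' Assemble a run configuration
#'
#' @param input_dir folder containing one TIFF triplet per field.
#' @param channel_patterns named list/vector of glob patterns binding files
#'   to roles, e.g. `list(nuclei = "*_c1.tif", cell = "*_c2.tif",
#'   mito = "*_c3.tif")`. The non-wildcard part of each pattern is stripped
#'   to derive the field id; roles are never inferred from pixel content.
#' @param out_dir output directory.
#' @param params a [seg_params].
#' @param n_workers number of parallel workers (per-field parallelism only;
#'   outputs are identical for any worker count).
#' @param condition condition label attached to every cell row.
#' @param pixel_size_um physical pixel size in micrometers.
#' @param write_mask_files write the five label masks per field.
#' @return an object of class `run_config`.
#' @export
run_config <- function(input_dir, channel_patterns, out_dir,
                       params = seg_params(), n_workers = 1,
                       condition = "", pixel_size_um = 0.108333,
                       write_mask_files = TRUE) {
  need <- c("nuclei", "cell", "mito")
  if (!all(need %in% names(channel_patterns)))
    stop("channel_patterns must name roles: nuclei, cell, mito")
  structure(list(input_dir = input_dir,
                 channel_patterns = as.list(channel_patterns[need]),
                 out_dir = out_dir, params = params,
                 n_workers = as.integer(n_workers),
                 condition = condition, pixel_size_um = pixel_size_um,
                 write_mask_files = isTRUE(write_mask_files)),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param config a [run_config].
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  lst <- unclass(config)
  lst$params <- unclass(lst$params)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  pars <- do.call(seg_params, lst$params[!vapply(lst$params, is.null, TRUE)])
  run_config(lst$input_dir, lst$channel_patterns, lst$out_dir, pars,
             lst$n_workers, lst$condition, lst$pixel_size_um,
             lst$write_mask_files)
}

#' discover field triplets under a folder given per-role glob patterns
#' @noRd
discover_fields <- function(input_dir, patterns) {
  ids <- NULL
  by_role <- list()
  for (role in names(patterns)) {
    pat <- patterns[[role]]
    files <- Sys.glob(file.path(input_dir, pat))
    # field id = filename with the pattern's fixed parts removed
    fixed <- Filter(nzchar, strsplit(basename(pat), "*", fixed = TRUE)[[1]])
    id <- basename(files)
    for (f in fixed) id <- sub(f, "", id, fixed = TRUE)
    by_role[[role]] <- setNames(files, id)
    ids <- if (is.null(ids)) id else intersect(ids, id)
  }
  if (!length(ids))
    stop(sprintf("no fields matched under '%s' (patterns: %s)", input_dir,
                 paste(sprintf("%s=%s", names(patterns), unlist(patterns)),
                       collapse = ", ")))
  lapply(sort(ids), function(i)
    list(field_id = i,
         paths = vapply(names(patterns), function(r) by_role[[r]][[i]],
                        character(1))))
}

#' Process one field end-to-end
#'
#' Segmentation (five masks), skeleton decomposition, isolated-mitochondria
#' re-segmentation and the 31-feature table.
#'
#' @param field a [field_image].
#' @param params a [seg_params].
#' @return list with the five [label_mask]s, the skeleton graph, the
#'   cluster map and `features` (per-cell data.frame).
#' @export
process_field <- function(field, params = seg_params()) {
  seg <- segment_field(field, params)
  graph <- skeletonize_clusters(seg$clusters, seg$cluster_to_cell)
  iso <- segment_isolated_mito(seg$clusters, graph)
  feats <- compute_cell_features(field, seg, graph, iso)
  branch_mask <- label_mask(graph$branches, "skeleton_branches",
                            field$field_id)
  list(nuclei = seg$nuclei, cells = seg$cells, clusters = seg$clusters,
       skeleton_branches = branch_mask, isolated = iso$isolated,
       cluster_to_cell = seg$cluster_to_cell, graph = graph,
       features = feats)
}

#' Run the pipeline over a folder of fields
#'
#' Every field is processed independently (deterministically, so outputs
#' are identical regardless of worker count); per-field failures are
#' recorded in the manifest and skipped, never silently dropped. Writes the
#' five masks per field, one folder-level CSV (one row per cell) and a JSON
#' manifest (package version, parameters, per-field cell counts, failures).
#'
#' @param config a [run_config].
#' @return invisibly, a list with `csv`, `manifest`, `n_failed`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  fields <- discover_fields(config$input_dir, config$channel_patterns)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  worker <- function(fd) {
    tryCatch({
      fi <- read_field(fd$paths, field_id = fd$field_id,
                       condition = config$condition,
                       pixel_size_um = config$pixel_size_um)
      res <- process_field(fi, config$params)
      if (config$write_mask_files)
        write_masks(res[c("nuclei", "cells", "clusters",
                          "skeleton_branches", "isolated")],
                    file.path(config$out_dir, "masks"))
      list(ok = TRUE, field_id = fd$field_id, features = res$features,
           n_cells = max(res$cells$labels))
    }, error = function(e)
      list(ok = FALSE, field_id = fd$field_id, error = conditionMessage(e)))
  }
  results <- if (config$n_workers > 1) {
    parallel::mclapply(fields, worker, mc.cores = config$n_workers,
                       mc.preschedule = FALSE)
  } else {
    lapply(fields, worker)
  }

  ok <- vapply(results, function(r) isTRUE(r$ok), logical(1))
  feats <- do.call(rbind, lapply(results[ok], `[[`, "features"))
  if (is.null(feats)) feats <- compute_cell_features_empty()
  csv_path <- file.path(config$out_dir, "cell_features.csv")
  write_cell_table(feats, csv_path)

  manifest <- list(
    package = "mitomorph",
    version = as.character(utils::packageVersion("mitomorph")),
    condition = config$condition,
    params = unclass(config$params),
    pixel_size_um = config$pixel_size_um,
    fields = lapply(results, function(r)
      if (r$ok) list(field_id = r$field_id, status = "ok",
                     n_cells = r$n_cells)
      else list(field_id = r$field_id, status = "failed", error = r$error)),
    n_failed = sum(!ok))
  man_path <- file.path(config$out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  if (any(!ok))
    warning(sprintf("%d field(s) failed; see %s", sum(!ok), man_path),
            call. = FALSE)
  invisible(list(csv = csv_path, manifest = man_path, n_failed = sum(!ok)))
}

#' @noRd
compute_cell_features_empty <- function() {
  feats <- mito_feature_names()
  cbind(data.frame(condition = character(0), field_id = character(0),
                   cell_id = integer(0)),
        as.data.frame(setNames(rep(list(numeric(0)), length(feats)), feats)))
}

#' Compare conditions: normalize, test, classify, render
#'
#' Reads one per-cell CSV per condition, computes condition means, min-max
#' normalized profiles, per-feature t-test tiers against the reference, the
#' morphospace code per condition, and writes a spider plot (SVG), a stats
#' CSV and a sigil JSON with the rule-firing trace.
#'
#' @param csv_paths named character vector: condition id -> per-cell CSV.
#'   Alternatively pass a single combined data.frame via `cell_table`.
#' @param reference reference condition id.
#' @param out_dir output directory.
#' @param cell_table optional combined per-cell data.frame (used instead of
#'   `csv_paths`).
#' @param unit statistical unit passed to [significance_tiers].
#' @return invisibly, list with `profile`, `tiers`, `sigils`, `files`.
#' @export
compare_conditions <- function(csv_paths = NULL, reference, out_dir,
                               cell_table = NULL, unit = "cell") {
  if (is.null(cell_table)) {
    if (length(csv_paths) < 2) stop("need >= 2 conditions")
    tabs <- lapply(names(csv_paths), function(cond) {
      df <- read_cell_table(csv_paths[[cond]])
      df$condition <- cond
      df
    })
    cell_table <- do.call(rbind, tabs)
  }
  if (length(unique(cell_table$condition)) < 2)
    stop("need >= 2 conditions")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  feats <- mito_feature_names()
  means <- stats::aggregate(cell_table[feats],
                            by = cell_table["condition"],
                            FUN = function(v) mean(v, na.rm = TRUE))
  M <- as.matrix(means[feats])
  rownames(M) <- means$condition
  profile <- normalize_profiles(M, reference)
  tiers <- suppressWarnings(
    significance_tiers(cell_table, reference, feats, unit = unit))
  sigils <- lapply(split(tiers, tiers$condition), classify_sigil)

  svg_path <- file.path(out_dir, "spider.svg")
  render_spider(profile, tiers, svg_path)
  stats_path <- file.path(out_dir, "feature_stats.csv")
  utils::write.csv(tiers, stats_path, row.names = FALSE)
  sigil_path <- file.path(out_dir, "sigils.json")
  jsonlite::write_json(lapply(sigils, unclass), sigil_path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(profile = profile, tiers = tiers, sigils = sigils,
                 files = c(spider = svg_path, stats = stats_path,
                           sigils = sigil_path)))
}
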