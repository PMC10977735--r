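# On-disk contract of the pipeline: single-plane grayscale TIFF per channel
# in, 16-bit integer label TIFFs and an RFC-4180 per-cell CSV out.

MASK_KINDS <- c("nuclei", "cells", "clusters", "skeleton_branches", "isolated_mito")

#' Construct a three-channel field image
#'
#' A field is one microscope position: three aligned 2D intensity channels
#' (blue = nuclei stain, green = plasma-membrane stain, red = mitochondrial
#' stain) plus pixel-size metadata. Geometry is computed in pixels
#' throughout; `pixel_size_um` is carried for reporting only.
#'
#' @param nuclei,cell,mito 2D non-negative intensity matrices of identical size.
#' @param pixel_size_um physical pixel size in micrometers.
#' @param field_id,condition identifier strings.
#' @return an object of class `field_image`.
#' @export
field_image <- function(nuclei, cell, mito, pixel_size_um = 0.108333,
                        field_id = "field", condition = "") {
  chans <- list(nuclei = nuclei, cell = cell, mito = mito)
  for (nm in names(chans)) {
    ch <- chans[[nm]]
    if (!is.matrix(ch)) stop(sprintf("channel '%s' must be a 2D matrix", nm))
    if (!all(is.finite(ch)) || any(ch < 0))
      stop(sprintf("channel '%s' must be finite and non-negative", nm))
  }
  dims <- vapply(chans, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("channel shape mismatch: all three channels must share height x width")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 || pixel_size_um <= 0)
    stop("pixel_size_um must be a positive scalar")
  structure(list(nuclei = nuclei, cell = cell, mito = mito,
                 pixel_size_um = pixel_size_um,
                 field_id = as.character(field_id),
                 condition = as.character(condition)),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("<field_image> %s (%s): %d x %d px, pixel size %.6f um\n",
              x$field_id, if (nzchar(x$condition)) x$condition else "no condition",
              nrow(x$nuclei), ncol(x$nuclei), x$pixel_size_um))
  invisible(x)
}

#' Construct a label mask
#'
#' @param labels 2D integer matrix; 0 = background, k > 0 = object k.
#'   Labels must be compact (every value in 1..K present).
#' @param kind one of `"nuclei"`, `"cells"`, `"clusters"`,
#'   `"skeleton_branches"`, `"isolated_mito"`.
#' @param parent_field field identifier the mask belongs to.
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(labels, kind, parent_field = "") {
  kind <- match.arg(kind, MASK_KINDS)
  if (!is.matrix(labels)) stop("labels must be a 2D matrix")
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  if (any(labels < 0)) stop("labels must be >= 0")
  K <- max(labels)
  if (K > 0) {
    present <- tabulate(labels[labels > 0], nbins = K) > 0
    if (!all(present))
      stop("labels are not compact: every value in 1..K must be present")
  }
  structure(list(labels = labels, kind = kind,
                 parent_field = as.character(parent_field)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> kind=%s, %d x %d px, %d objects (field %s)\n",
              x$kind, nrow(x$labels), ncol(x$labels), max(x$labels),
              x$parent_field))
  invisible(x)
}

#' Number of labeled objects in a mask
#' @export
n_objects <- function(mask) max(mask$labels)

# read one single-plane grayscale TIFF as an integer/numeric matrix
#' @noRd
read_channel_tiff <- function(path) {
  if (!file.exists(path)) stop(sprintf("missing file: %s", path))
  pages <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
  if (length(pages) != 1)
    stop(sprintf(paste0("'%s' has %d pages: multi-page TIFFs (z-stacks, ",
                        "stitched composites) are not supported; supply one ",
                        "single-plane TIFF per channel"),
                 path, length(pages)))
  img <- pages[[1]]
  if (length(dim(img)) == 3)
    stop(sprintf(paste0("'%s' is an RGB/multi-sample TIFF; supply one ",
                        "single-channel grayscale TIFF per channel"), path))
  matrix(as.numeric(img), nrow(img), ncol(img))
}

#' Read a field from three single-channel TIFF files
#'
#' Channel-to-role binding is explicit: `paths` must be a named vector with
#' entries `nuclei`, `cell` and `mito`. Roles are never guessed from file
#' names or pixel statistics.
#'
#' @param paths named character vector of length 3 with names
#'   `c("nuclei", "cell", "mito")`.
#' @param field_id,condition identifiers attached to the field.
#' @param pixel_size_um physical pixel size in micrometers.
#' @return a [field_image].
#' @export
read_field <- function(paths, field_id = NULL, condition = "",
                       pixel_size_um = 0.108333) {
  need <- c("nuclei", "cell", "mito")
  if (is.null(names(paths)) || !all(need %in% names(paths)))
    stop("'paths' must be named with roles: nuclei, cell, mito")
  chans <- lapply(paths[need], read_channel_tiff)
  if (is.null(field_id))
    field_id <- tools::file_path_sans_ext(basename(paths[["nuclei"]]))
  field_image(chans$nuclei, chans$cell, chans$mito,
              pixel_size_um = pixel_size_um,
              field_id = field_id, condition = condition)
}

#' Write label masks as lossless 16-bit integer TIFF files
#'
#' One file per mask, named `<field>_<kind>.tif`; reading the file back with
#' [read_mask] reproduces the labels bit-exactly (labels up to 65535).
#'
#' @param masks a [label_mask] or list of them.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_masks <- function(masks, out_dir) {
  if (inherits(masks, "label_mask")) masks <- list(masks)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create output directory '%s'", out_dir))
  paths <- character(0)
  for (m in masks) {
    stopifnot(inherits(m, "label_mask"))
    if (max(m$labels) > 65535)
      stop("more than 65535 labels cannot be stored losslessly in 16-bit TIFF")
    fid <- if (nzchar(m$parent_field)) m$parent_field else "field"
    path <- file.path(out_dir, sprintf("%s_%s.tif", fid, m$kind))
    tiff::writeTIFF(m$labels / 65535, path, bits.per.sample = 16,
                    compression = "none")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a label mask written by [write_masks]
#' @param path TIFF file path.
#' @param kind mask kind (defaults to parsing the filename suffix).
#' @param parent_field field id (defaults to parsing the filename).
#' @export
read_mask <- function(path, kind = NULL, parent_field = NULL) {
  base <- tools::file_path_sans_ext(basename(path))
  if (is.null(kind)) {
    kind <- MASK_KINDS[vapply(MASK_KINDS, function(k)
      grepl(paste0("_", k, "$"), base), logical(1))][1]
    if (is.na(kind)) stop("cannot infer mask kind from filename; pass 'kind'")
  }
  if (is.null(parent_field))
    parent_field <- sub(paste0("_", kind, "$"), "", base)
  img <- tiff::readTIFF(path, as.is = TRUE)
  lab <- matrix(as.integer(round(img)), nrow(img), ncol(img))
  label_mask(compactify_labels(lab), kind, parent_field)
}

#' The 31 per-cell feature names, in canonical column order
#' @export
mito_feature_names <- function() {
  c("Cell_Area", "Cell_MeanIntensity", "Cell_MaxIntensity", "Cell_Perimeter",
    "Cell_Compaction", "Cell_Roundness",
    "MitoCluster_Fractal2", "MitoCluster_Fractal8", "MitoCluster_Fractal32",
    "MitoCluster_Count", "MitoCluster_Area", "MitoCluster_Elongation",
    "MitoCluster_Compaction", "MitoCluster_Roundness",
    "MitoCluster_EulerNumber", "Mito_MeanIntensity", "Mito_MaxIntensity",
    "MitoCluster_Perimeter", "MitoCluster_Solidity",
    "Skel_Width", "Skel_Length", "Skel_BranchPointsCount",
    "Skel_EndPointsCount", "Skel_BranchPointsEndPointsRatio",
    "Mito_Compaction", "Mito_Elongation", "Mito_Roundness", "Mito_Length",
    "DistToMembrane", "DistToNuclei", "RatioDistMemb0Nucl1")
}

ID_COLUMNS <- c("condition", "field_id", "cell_id")

#' Write the per-cell feature table as CSV
#'
#' One row per cell; header = identifier columns (`condition`, `field_id`,
#' `cell_id`) followed by the 31 feature names in canonical order. Missing
#' features (e.g. cells without mitochondria) are written as empty fields,
#' never as zero.
#'
#' @param records data.frame with the identifier and feature columns.
#' @param out_path output CSV path.
#' @return invisibly, `out_path`.
#' @export
write_cell_table <- function(records, out_path) {
  cols <- c(ID_COLUMNS, mito_feature_names())
  if (nrow(records) > 0 && !all(cols %in% names(records)))
    stop("records do not share the expected 31-feature schema; missing: ",
         paste(setdiff(cols, names(records)), collapse = ", "))
  if (nrow(records) == 0) {
    records <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  } else {
    records <- records[, cols, drop = FALSE]
  }
  utils::write.csv(records, out_path, row.names = FALSE, na = "")
  invisible(out_path)
}

#' Read a per-cell feature table written by [write_cell_table]
#' @param path CSV file path.
#' @export
read_cell_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(condition = "character",
                                       field_id = "character"))
  cols <- c(ID_COLUMNS, mito_feature_names())
  if (!all(cols %in% names(df)))
    stop(sprintf("'%s' is not a per-cell feature table (schema mismatch)", path))
  df
}
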