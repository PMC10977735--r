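# Stages 1-3 of the segmentation: nuclei, cells, mitochondrial clusters.
# Every stage is deterministic (no RNG anywhere); re-running on identical
# input yields an identical mask.

#' Segmentation parameters
#'
#' Defaults follow the reference protocol: nuclei are band-passed with
#' Gaussian sigmas 3 and 12 px, thresholded at the median of the filtered
#' image, components below 2000 px dropped, holes filled, a 3 px disk
#' dilation applied, touching nuclei split by watershed on the distance
#' transform, and border objects removed. Mitochondria are band-passed with
#' sigmas 1 and 4 px and thresholded at mean + 1 SD of the filtered image,
#' dropping components below 10 px.
#'
#' @param nuclei_sigma_lo,nuclei_sigma_hi band-pass sigmas (px) for the
#'   nuclei channel; `lo` removes sharp objects, `hi` removes background.
#' @param nuclei_mad_k robustness guard on the nuclei threshold: pixels must
#'   exceed `median + nuclei_mad_k * MAD` of the band-passed image. On a
#'   clean background the MAD of the band-passed image is 0 and the rule
#'   reduces to the plain median threshold; on noisy backgrounds the guard
#'   keeps the exact-median rule from passing ~half of the background noise
#'   (which percolates into large spurious components). `0` gives the
#'   literal median rule.
#' @param nuclei_min_area_px minimum nucleus component area (px).
#' @param nuclei_dilate_radius_px disk radius (px) of the post-fill dilation.
#' @param cell_intensity_floor cell-channel intensity below which pixels are
#'   excluded from cells; `NULL` selects an Otsu threshold of the cell
#'   channel automatically. This is the user-adjustable cell-marker
#'   threshold.
#' @param mito_sigma_lo,mito_sigma_hi band-pass sigmas (px) for the
#'   mitochondrial channel.
#' @param mito_threshold_k_sd threshold at mean + k * SD of the band-passed
#'   mitochondrial channel.
#' @param mito_min_area_px minimum cluster component area (px).
#' @param connectivity component/border connectivity (8, the default, or 4).
#' @param ws_tolerance watershed tolerance (intensity units) for the basin
#'   detection of the cell stage; basins shallower than this merge into
#'   their neighbor. `NULL` (default) selects 1 percent of the relief's
#'   intensity range. Shot noise otherwise seeds one basin per noise bump,
#'   which only inflates the residual-merge workload without changing the
#'   result.
#' @param ws_smooth_sigma Gaussian sigma (px) applied to the cell channel
#'   before basin detection only; boundary-intensity statistics for the
#'   residual merge and the intensity floor always use the raw channel.
#'   `0` disables the regularization.
#' @return an object of class `seg_params`.
#' @export
seg_params <- function(nuclei_sigma_lo = 3, nuclei_sigma_hi = 12,
                       nuclei_mad_k = 3,
                       nuclei_min_area_px = 2000, nuclei_dilate_radius_px = 3,
                       cell_intensity_floor = NULL,
                       mito_sigma_lo = 1, mito_sigma_hi = 4,
                       mito_threshold_k_sd = 1, mito_min_area_px = 10,
                       connectivity = 8, ws_tolerance = NULL,
                       ws_smooth_sigma = 1.5) {
  if (nuclei_sigma_lo >= nuclei_sigma_hi || mito_sigma_lo >= mito_sigma_hi)
    stop("band-pass requires sigma_lo < sigma_hi")
  if (nuclei_min_area_px <= 0 || nuclei_dilate_radius_px <= 0 ||
      mito_min_area_px <= 0)
    stop("areas and radii must be positive")
  structure(list(nuclei_sigma_lo = nuclei_sigma_lo,
                 nuclei_sigma_hi = nuclei_sigma_hi,
                 nuclei_mad_k = nuclei_mad_k,
                 nuclei_min_area_px = nuclei_min_area_px,
                 nuclei_dilate_radius_px = nuclei_dilate_radius_px,
                 cell_intensity_floor = cell_intensity_floor,
                 mito_sigma_lo = mito_sigma_lo,
                 mito_sigma_hi = mito_sigma_hi,
                 mito_threshold_k_sd = mito_threshold_k_sd,
                 mito_min_area_px = mito_min_area_px,
                 connectivity = connectivity,
                 ws_tolerance = ws_tolerance,
                 ws_smooth_sigma = ws_smooth_sigma),
            class = "seg_params")
}

#' Difference-of-Gaussians band-pass filter
#'
#' `blur(x, sigma_lo) - blur(x, sigma_hi)`: the narrow blur removes sharp
#' noise, subtracting the wide blur removes slowly varying background. The
#' response is zero on constant images.
#'
#' @param channel 2D intensity matrix.
#' @param sigma_lo,sigma_hi Gaussian sigmas in px, `sigma_lo < sigma_hi`.
#' @return signed matrix of the same size.
#' @export
bandpass <- function(channel, sigma_lo, sigma_hi) {
  if (!is.matrix(channel)) stop("bandpass: input must be a 2D matrix")
  if (sigma_lo >= sigma_hi) stop("bandpass requires sigma_lo < sigma_hi")
  gaussian_blur(channel, sigma_lo) - gaussian_blur(channel, sigma_hi)
}

#' Segment nuclei from the blue channel
#'
#' Pipeline, in order: band-pass (sigmas 3/12) -> threshold strictly above
#' the median of the filtered image (plus `nuclei_mad_k` MADs as a noise
#' guard; see [seg_params]) -> remove components smaller than
#' `nuclei_min_area_px` -> fill holes -> dilate by a disk of radius
#' `nuclei_dilate_radius_px` -> split touching nuclei by watershed on the
#' distance transform -> remove objects touching the image border ->
#' compact relabeling. An empty mask is a valid result.
#'
#' @param nuclei_channel 2D intensity matrix (blue channel).
#' @param params a [seg_params].
#' @param parent_field field id stored on the returned mask.
#' @return a [label_mask] of kind `"nuclei"`.
#' @export
segment_nuclei <- function(nuclei_channel, params = seg_params(),
                           parent_field = "") {
  bp <- bandpass(nuclei_channel, params$nuclei_sigma_lo, params$nuclei_sigma_hi)
  b <- bp > stats::median(bp) + params$nuclei_mad_k * stats::mad(bp)
  b <- remove_small(b, params$nuclei_min_area_px, params$connectivity)
  b <- fill_holes(b)
  b <- dilate_disk(b, params$nuclei_dilate_radius_px)
  # split touching nuclei: watershed on the distance transform of the mask;
  # tolerance 2 px ignores sub-pixel relief maxima along necks
  d <- distmap_padded(b)
  lab <- EBImage::watershed(d, tolerance = 2, ext = 1)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  drop <- setdiff(border_labels(lab), 0L)
  if (length(drop)) lab[lab %in% drop] <- 0L
  label_mask(compactify_labels(lab), "nuclei", parent_field)
}

#' Segment cells from the membrane channel, seeded by nuclei
#'
#' The negated cell channel is the watershed relief, with nucleus interiors
#' forced below every other pixel so that each nucleus seeds one catchment
#' basin (implemented as forcing the peak map to global max + 1). Basins
#' intersecting a nucleus take that nucleus' label; residual basins are
#' merged iteratively -- a residual touching exactly one labeled cell joins
#' it, one touching several joins the neighbor with the lowest mean cell-
#' channel intensity along the shared boundary (ties: lower cell label;
#' residuals processed in decreasing area) -- until none remains. Finally
#' pixels below `cell_intensity_floor` are set to background. Cell label k
#' corresponds to nucleus label k.
#'
#' @param cell_channel 2D intensity matrix (green channel).
#' @param nuclei nuclei [label_mask] from [segment_nuclei] on the same field.
#' @param params a [seg_params].
#' @return a [label_mask] of kind `"cells"`.
#' @export
segment_cells <- function(cell_channel, nuclei, params = seg_params()) {
  stopifnot(inherits(nuclei, "label_mask"), nuclei$kind == "nuclei")
  if (!all(dim(cell_channel) == dim(nuclei$labels)))
    stop("cell channel and nuclei mask shapes differ")
  nlab <- nuclei$labels
  if (max(nlab) == 0) {
    return(label_mask(matrix(0L, nrow(nlab), ncol(nlab)), "cells",
                      nuclei$parent_field))
  }
  floor_val <- params$cell_intensity_floor
  if (is.null(floor_val)) floor_val <- auto_intensity_floor(cell_channel)

  # peak map for EBImage's maxima-based watershed == negated relief;
  # lightly smoothed for basin detection only
  smooth <- if (params$ws_smooth_sigma > 0)
    gaussian_blur(cell_channel, params$ws_smooth_sigma) else cell_channel
  tol <- params$ws_tolerance
  if (is.null(tol)) tol <- max(0.01 * diff(range(smooth)), 1e-9)
  relief <- smooth - min(smooth) + 1
  # nucleus interiors forced well over the max so watershed tolerance can
  # never merge two nucleus plateaus across a bright ridge
  relief[nlab > 0] <- max(relief) + 10 * tol + 1
  ws <- EBImage::watershed(relief, tolerance = tol, ext = 1)
  ws <- matrix(as.integer(ws), nrow(ws), ncol(ws))
  if (any(ws == 0)) { # guard: assign stray unlabeled pixels to a basin
    filled <- EBImage::propagate(relief, ws, mask = array(1, dim(ws)))
    ws <- matrix(as.integer(filled), nrow(ws), ncol(ws))
  }

  cells <- merge_residual_basins(ws, nlab, cell_channel, floor_val)
  cells[cell_channel < floor_val & nlab == 0] <- 0L
  label_mask(cells, "cells", nuclei$parent_field)
}

# Default cell-marker floor: Otsu threshold of the cell channel.
#' @noRd
auto_intensity_floor <- function(channel) {
  rng <- range(channel)
  if (diff(rng) == 0) return(rng[1])
  x <- (channel - rng[1]) / diff(rng)
  t01 <- EBImage::otsu(EBImage::Image(x), range = c(0, 1))
  rng[1] + t01 * diff(rng)
}

# Map watershed basins to nucleus labels and merge residual basins into
# cells on a region-adjacency graph (4-connected boundary pairs); edge
# weight = mean cell-channel intensity over the boundary pixel pairs.
# Basins entirely below the cell-marker floor can never contribute cell
# pixels and are kept out of the merge (they would otherwise bridge
# unrelated cells across dark background).
#' @noRd
merge_residual_basins <- function(ws, nlab, intensity, floor_val = -Inf) {
  nb <- max(ws)
  # basin -> nucleus assignment (a basin can contain at most one forced
  # nucleus plateau)
  hit <- nlab > 0 & ws > 0
  basin_nucleus <- integer(nb)
  if (any(hit)) {
    tab <- unique(cbind(ws[hit], nlab[hit]))
    basin_nucleus[tab[, 1]] <- tab[, 2]
  }
  area <- tabulate(ws[ws > 0], nbins = nb)
  lit <- ws > 0 & intensity >= floor_val
  active <- logical(nb)
  if (any(lit)) active[unique(ws[lit])] <- TRUE
  active[basin_nucleus > 0] <- TRUE

  # 4-connected adjacency with summed boundary intensity; junctions whose
  # pixels lie below the floor are background contacts, not cell junctions
  edges <- rbind(adj_pairs(ws, intensity, 1, 0, floor_val),
                 adj_pairs(ws, intensity, 0, 1, floor_val))
  if (nrow(edges)) {
    key <- paste(edges[, 1], edges[, 2])
    sums <- rowsum(edges[, 3:4, drop = FALSE], key)
    ab <- do.call(rbind, lapply(strsplit(rownames(sums), " "), as.integer))
    edges <- cbind(ab, sums)
  } else {
    edges <- matrix(numeric(0), 0, 4)
  }

  if (nrow(edges)) {
    keep <- active[edges[, 1]] & active[edges[, 2]]
    edges <- edges[keep, , drop = FALSE]
  }
  assign <- basin_nucleus # 0 = residual
  repeat {
    resid <- which(assign == 0L & area > 0 & active)
    if (!length(resid)) break
    # residuals touching >=1 labeled basin, processed in decreasing area
    touch <- unique(c(edges[assign[edges[, 1]] > 0, 2],
                      edges[assign[edges[, 2]] > 0, 1]))
    touch <- touch[assign[touch] == 0L]
    if (!length(touch)) break # disconnected residuals stay background
    r <- touch[order(-area[touch], touch)][1]
    # candidate cells adjacent to r with mean boundary intensity
    sel <- (edges[, 1] == r & assign[edges[, 2]] > 0) |
           (edges[, 2] == r & assign[edges[, 1]] > 0)
    e <- edges[sel, , drop = FALSE]
    other <- ifelse(e[, 1] == r, e[, 2], e[, 1])
    cand <- rowsum(e[, 3:4, drop = FALSE], assign[other])
    cell_lab <- as.integer(rownames(cand))
    mean_int <- cand[, 2] / cand[, 1]
    pick <- cell_lab[order(mean_int, cell_lab)][1]
    assign[r] <- pick
  }
  lut <- c(0L, assign)
  matrix(lut[ws + 1L], nrow(ws), ncol(ws))
}

# boundary pairs between different basins along offset (dr, dc):
# columns basin_a, basin_b (a < b), n_pairs, sum of mean pair intensity
#' @noRd
adj_pairs <- function(ws, intensity, dr, dc, floor_val = -Inf) {
  a <- ws; b <- shift0(ws, dr, dc)
  ia <- intensity; ib <- shift0(intensity, dr, dc)
  keep <- a > 0 & b > 0 & a != b & ia >= floor_val & ib >= floor_val
  if (!any(keep)) return(matrix(numeric(0), 0, 4))
  lo <- pmin(a[keep], b[keep]); hi <- pmax(a[keep], b[keep])
  val <- (ia[keep] + ib[keep]) / 2
  cbind(lo, hi, 1, val)
}

#' Segment mitochondrial clusters from the red channel
#'
#' Band-pass (sigmas 1/4) -> keep pixels strictly above mean + k * SD of the
#' filtered image -> remove components below `mito_min_area_px` -> intersect
#' with the cell foreground (a cluster straddling two cells is split per
#' cell) -> connected components labeled compactly, each mapped to the cell
#' containing it.
#'
#' @param mito_channel 2D intensity matrix (red channel).
#' @param cells cells [label_mask] from [segment_cells].
#' @param params a [seg_params].
#' @return list with `clusters` (a [label_mask] of kind `"clusters"`) and
#'   `cluster_to_cell` (integer vector mapping cluster label -> cell label).
#' @export
segment_mito_clusters <- function(mito_channel, cells, params = seg_params()) {
  stopifnot(inherits(cells, "label_mask"), cells$kind == "cells")
  if (!all(dim(mito_channel) == dim(cells$labels)))
    stop("mito channel and cell mask shapes differ")
  bp <- bandpass(mito_channel, params$mito_sigma_lo, params$mito_sigma_hi)
  thr <- mean(bp) + params$mito_threshold_k_sd * stats::sd(bp)
  b <- bp > thr
  b <- remove_small(b, params$mito_min_area_px, params$connectivity)
  b <- b & cells$labels > 0
  # label within each cell so a cluster never spans two cells
  comp <- label_components(b, params$connectivity)
  if (max(comp) > 0) {
    # split components crossing cell boundaries: re-key by (component, cell)
    keyed <- comp
    keyed[comp > 0] <- comp[comp > 0] + max(comp) * (cells$labels[comp > 0] - 1L)
    comp <- compactify_labels(keyed)
  }
  cl_mask <- label_mask(comp, "clusters", cells$parent_field)
  K <- max(comp)
  map <- integer(K)
  if (K > 0) {
    inb <- comp > 0
    tab <- unique(cbind(comp[inb], cells$labels[inb]))
    map[tab[, 1]] <- tab[, 2]
  }
  list(clusters = cl_mask, cluster_to_cell = map)
}

#' Run the three mask-level segmentation stages on a field
#'
#' @param field a [field_image].
#' @param params a [seg_params].
#' @return list with `nuclei`, `cells`, `clusters` ([label_mask]s) and
#'   `cluster_to_cell` (integer map).
#' @export
segment_field <- function(field, params = seg_params()) {
  stopifnot(inherits(field, "field_image"))
  nuc <- segment_nuclei(field$nuclei, params, parent_field = field$field_id)
  cells <- segment_cells(field$cell, nuc, params)
  cl <- segment_mito_clusters(field$mito, cells, params)
  list(nuclei = nuc, cells = cells, clusters = cl$clusters,
       cluster_to_cell = cl$cluster_to_cell)
}
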