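# The 31 per-cell descriptors: cellular shape and intensity, mitochondrial
# cluster morphology and fractality, skeleton connectivity, isolated-
# mitochondria shape, and localization relative to nucleus and membrane.
# All geometry is in pixel units.

#' Shape descriptors of a single binary region
#'
#' * `area`: pixel count.
#' * `perimeter`: length of the oriented boundary contour, diagonal steps
#'   weighted sqrt(2); floored at 1 px for degenerate regions.
#' * `compaction` / `elongation`: minor/major (resp. major/minor) axis of
#'   the moment-equivalent ellipse (second central moments with the 1/12 px
#'   correction), so `elongation * compaction == 1` exactly.
#' * `roundness`: `equivalent_diameter / (perimeter / pi)` with
#'   `equivalent_diameter = sqrt(4 * area / pi)`; 1 for a perfect circle.
#' * `euler`: connected components minus holes (1 for a solid blob, 0 for
#'   an annulus).
#' * `solidity`: convex-hull perimeter / object perimeter (a perimeter
#'   ratio, not the conventional area ratio).
#'
#' @param mask binary matrix containing exactly one region (nonzero pixels).
#' @return named list of the seven descriptors.
#' @export
shape_descriptors <- function(mask) {
  b <- mask != 0
  area <- sum(b)
  if (area == 0) stop("shape_descriptors: empty region")
  rc <- which(b, arr.ind = TRUE)
  # moment-equivalent ellipse axes (MATLAB regionprops convention);
  # the 1/12 term is the variance of a unit pixel
  if (area > 1) {
    mu_rr <- stats::var(rc[, 1]) * (area - 1) / area + 1 / 12
    mu_cc <- stats::var(rc[, 2]) * (area - 1) / area + 1 / 12
    mu_rc <- stats::cov(rc[, 1], rc[, 2]) * (area - 1) / area
  } else {
    mu_rr <- mu_cc <- 1 / 12
    mu_rc <- 0
  }
  common <- sqrt((mu_rr - mu_cc)^2 + 4 * mu_rc^2)
  major <- 2 * sqrt(2) * sqrt(mu_rr + mu_cc + common)
  minor <- 2 * sqrt(2) * sqrt(max(mu_rr + mu_cc - common, 0))
  if (minor <= 0) minor <- major # degenerate: treat as round
  perim <- max(contour_perimeter(b), 1)
  eqdiam <- sqrt(4 * area / pi)
  hull_perim <- convex_hull_perimeter(rc)
  list(area = area,
       perimeter = perim,
       compaction = minor / major,
       elongation = major / minor,
       roundness = eqdiam / (perim / pi),
       euler = euler_number(b),
       solidity = max(hull_perim, 1) / perim)
}

# chain length of every oriented boundary contour of the region
#' @noRd
contour_perimeter <- function(b) {
  oc <- EBImage::ocontour((b != 0) * 1)
  total <- 0
  for (pts in oc) {
    if (nrow(pts) < 2) next
    d <- rbind(diff(pts), pts[1, ] - pts[nrow(pts), ])
    total <- total + sum(sqrt(rowSums(d^2)))
  }
  total
}

#' @noRd
convex_hull_perimeter <- function(rc) {
  if (nrow(rc) < 3) return(2 * sqrt(sum((apply(rc, 2, max) - apply(rc, 2, min))^2)))
  h <- grDevices::chull(rc[, 2], rc[, 1])
  pts <- rc[h, , drop = FALSE]
  d <- rbind(diff(pts), pts[1, ] - pts[nrow(pts), ])
  sum(sqrt(rowSums(d^2)))
}

# components minus holes; foreground 8-connected, background 4-connected
#' @noRd
euler_number <- function(b) {
  n_comp <- max(label_components(b, 8))
  n <- nrow(b); p <- ncol(b)
  pad <- matrix(TRUE, n + 2, p + 2)
  pad[2:(n + 1), 2:(p + 1)] <- !b
  bg <- label_components(pad, 4)
  n_holes <- max(bg) - 1L # one background component touches the pad border
  n_comp - n_holes
}

#' Box-counting profile and fractal dimensions of a binary mask
#'
#' The mask is cropped to its nonzero bounding box and zero-padded to a
#' `2^P x 2^P` square with P minimal such that `max(dim) <= 2^P`. Occupied
#' boxes are counted at sizes `2^0 .. 2^P`; the fractal-dimension vector is
#' `FD = -gradient(log N) / gradient(log R)` with central differences in
#' the interior and one-sided differences at the ends. `Fractal2`,
#' `Fractal8` and `Fractal32` are the FD values at box sizes 4, 16 and 64
#' px respectively (NA when the padded side is smaller than the box).
#'
#' @param mask binary matrix (may be empty: all outputs NA).
#' @return list with `R` (box sizes), `N` (occupied-box counts), `FD`,
#'   `padded_side`, and `fractal2`, `fractal8`, `fractal32`.
#' @export
box_count_fd <- function(mask) {
  b <- mask != 0
  if (!any(b)) {
    return(list(R = numeric(0), N = numeric(0), FD = numeric(0),
                padded_side = 0L,
                fractal2 = NA_real_, fractal8 = NA_real_, fractal32 = NA_real_))
  }
  rc <- which(b, arr.ind = TRUE)
  b <- b[min(rc[, 1]):max(rc[, 1]), min(rc[, 2]):max(rc[, 2]), drop = FALSE]
  P <- max(0L, ceiling(log2(max(dim(b)))))
  side <- 2L^P
  M <- matrix(FALSE, side, side)
  M[seq_len(nrow(b)), seq_len(ncol(b))] <- b
  N <- numeric(P + 1)
  N[1] <- sum(M)
  cur <- M
  if (P >= 1) for (k in 1:P) {
    s <- nrow(cur)
    odd <- seq(1, s, by = 2)
    cur <- (cur[odd, , drop = FALSE] | cur[odd + 1, , drop = FALSE])
    cur <- (cur[, odd, drop = FALSE] | cur[, odd + 1, drop = FALSE])
    N[k + 1] <- sum(cur)
  }
  R <- 2^(0:P)
  FD <- if (P == 0) 0 else -num_gradient(log(N)) / num_gradient(log(R))
  pick <- function(size) {
    i <- match(size, R)
    if (is.na(i)) NA_real_ else FD[i]
  }
  list(R = R, N = N, FD = FD, padded_side = side,
       fractal2 = pick(4), fractal8 = pick(16), fractal32 = pick(64))
}

# numerical gradient: central differences inside, one-sided at the ends
#' @noRd
num_gradient <- function(v) {
  n <- length(v)
  if (n == 1) return(0)
  g <- numeric(n)
  g[1] <- v[2] - v[1]
  g[n] <- v[n] - v[n - 1]
  if (n > 2) g[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / 2
  g
}

#' Skeleton connectivity features for one cell
#'
#' `Skel_Length` is the summed geodesic branch length, `Skel_Width` the
#' total cluster area divided by the total skeleton length (a mean tubule
#' width proxy), `Skel_BranchPointsCount` the number of merged junction
#' nodes, `Skel_EndPointsCount` the number of end-point pixels, and the
#' ratio `B / (B + E)` (0 when `B + E == 0`).
#'
#' @param graph a [skeletonize_clusters] result.
#' @param clusters the cluster [label_mask].
#' @param cluster_to_cell integer map cluster label -> cell label.
#' @param cell_label the cell to summarize.
#' @return named list of the five skeleton features (NA when the cell has
#'   no clusters).
#' @export
skeleton_features <- function(graph, clusters, cluster_to_cell, cell_label) {
  cl_ids <- which(cluster_to_cell == cell_label)
  if (!length(cl_ids)) {
    return(list(Skel_Width = NA_real_, Skel_Length = NA_real_,
                Skel_BranchPointsCount = NA_real_,
                Skel_EndPointsCount = NA_real_,
                Skel_BranchPointsEndPointsRatio = NA_real_))
  }
  in_cell <- clusters$labels %in% cl_ids
  info <- graph$branch_info
  lens <- info$length[info$cluster %in% cl_ids]
  total_len <- sum(lens)
  E <- sum(graph$end_points & in_cell)
  jn <- unique(graph$junction_nodes[graph$junction_nodes > 0 & in_cell])
  B <- length(jn)
  area <- sum(in_cell)
  list(Skel_Width = if (total_len > 0) area / total_len else area,
       Skel_Length = total_len,
       Skel_BranchPointsCount = as.numeric(B),
       Skel_EndPointsCount = as.numeric(E),
       Skel_BranchPointsEndPointsRatio = if (B + E > 0) B / (B + E) else 0)
}

#' Localization of the mitochondrial skeleton within a cell
#'
#' For every skeleton pixel of cell k: the Euclidean distance to the cell
#' boundary (`DistToMembrane`) and to the boundary of nucleus k
#' (`DistToNuclei`), both in px. The per-cell features are means over
#' skeleton pixels; `RatioDistMemb0Nucl1 = dN / (dM + dN)` is computed per
#' pixel and then averaged (0 at the nuclear envelope, 1 at the membrane).
#'
#' @param skel_px logical matrix of the cell's skeleton pixels.
#' @param cell_mask,nucleus_mask logical matrices of cell k and nucleus k.
#' @return named list with `DistToMembrane`, `DistToNuclei`,
#'   `RatioDistMemb0Nucl1` (NA when there is no skeleton pixel).
#' @export
localization_features <- function(skel_px, cell_mask, nucleus_mask) {
  if (!any(skel_px)) {
    return(list(DistToMembrane = NA_real_, DistToNuclei = NA_real_,
                RatioDistMemb0Nucl1 = NA_real_))
  }
  d_mem <- distmap_padded(cell_mask)       # image border counts as membrane
  d_out <- distmap_raw(!nucleus_mask)      # distance to the nucleus, outside
  d_in <- distmap_raw(nucleus_mask)        # distance to the envelope, inside
  d_nuc <- ifelse(nucleus_mask, d_in, d_out)
  dm <- d_mem[skel_px]
  dn <- d_nuc[skel_px]
  denom <- dm + dn
  ratio <- ifelse(denom > 0, dn / denom, 0.5)
  list(DistToMembrane = mean(dm), DistToNuclei = mean(dn),
       RatioDistMemb0Nucl1 = mean(ratio))
}

#' Aggregate per-object mitochondrial features to one cell
#'
#' Areas and lengths are summed over objects; every other per-object
#' feature is the arithmetic mean; counts are object counts. Aggregating a
#' single object is the identity on its features.
#'
#' @param cluster_shapes list of [shape_descriptors] results, one per
#'   cluster of the cell.
#' @param cluster_max_int numeric vector of per-cluster maximum red
#'   intensity.
#' @param iso_shapes list of [shape_descriptors] results, one per isolated
#'   mitochondrion.
#' @param iso_lengths numeric vector of per-isolated-mitochondrion skeleton
#'   branch lengths.
#' @return named list of the aggregated cluster and isolated-mitochondria
#'   features.
#' @export
aggregate_cell <- function(cluster_shapes, cluster_max_int,
                           iso_shapes, iso_lengths) {
  g <- function(lst, f) vapply(lst, function(s) s[[f]], numeric(1))
  out <- list(
    MitoCluster_Count = length(cluster_shapes),
    MitoCluster_Area = sum(g(cluster_shapes, "area")),
    MitoCluster_Elongation = mean(g(cluster_shapes, "elongation")),
    MitoCluster_Compaction = mean(g(cluster_shapes, "compaction")),
    MitoCluster_Roundness = mean(g(cluster_shapes, "roundness")),
    MitoCluster_EulerNumber = mean(g(cluster_shapes, "euler")),
    Mito_MaxIntensity = mean(cluster_max_int),
    MitoCluster_Perimeter = mean(g(cluster_shapes, "perimeter")),
    MitoCluster_Solidity = mean(g(cluster_shapes, "solidity")),
    Mito_Compaction = mean(g(iso_shapes, "compaction")),
    Mito_Elongation = mean(g(iso_shapes, "elongation")),
    Mito_Roundness = mean(g(iso_shapes, "roundness")),
    Mito_Length = sum(iso_lengths))
  lapply(out, as.numeric)
}

#' Compute the 31-feature record for every cell of a segmented field
#'
#' Runs the skeleton stages if not supplied, measures per-object
#' descriptors, aggregates them per cell (sums for areas and lengths, means
#' otherwise), computes the box-counting fractal dimensions once on the
#' per-cell cluster-union mask, and attaches cell-level shape/intensity and
#' localization features. Cells without mitochondria are still emitted,
#' with the mitochondrial features missing (NA).
#'
#' @param field a [field_image].
#' @param seg a [segment_field] result (computed if NULL).
#' @param graph a [skeletonize_clusters] result (computed if NULL).
#' @param iso a [segment_isolated_mito] result (computed if NULL).
#' @param params a [seg_params] (used only when `seg` is NULL).
#' @return data.frame with `condition`, `field_id`, `cell_id` and the 31
#'   feature columns of [mito_feature_names].
#' @export
compute_cell_features <- function(field, seg = NULL, graph = NULL, iso = NULL,
                                  params = seg_params()) {
  stopifnot(inherits(field, "field_image"))
  if (is.null(seg)) seg <- segment_field(field, params)
  if (is.null(graph))
    graph <- skeletonize_clusters(seg$clusters, seg$cluster_to_cell)
  if (is.null(iso)) iso <- segment_isolated_mito(seg$clusters, graph)

  cells <- seg$cells$labels
  nuclei <- seg$nuclei$labels
  clusters <- seg$clusters$labels
  isolab <- iso$isolated$labels
  cl_crops <- region_crops(clusters)
  iso_crops <- region_crops(isolab)
  cl_max_int <- if (max(clusters) > 0)
    as.numeric(tapply(field$mito[clusters > 0],
                      factor(clusters[clusters > 0],
                             levels = seq_len(max(clusters))), max))
  else numeric(0)
  n_cells <- max(cells)
  feats <- mito_feature_names()
  rows <- vector("list", n_cells)
  if (n_cells == 0) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(feats)), feats))
    return(cbind(data.frame(condition = character(0), field_id = character(0),
                            cell_id = integer(0)), df))
  }

  # per-isolated-object cell assignment via the cluster it lives in
  iso_cell <- integer(max(isolab))
  if (max(isolab) > 0) {
    inb <- isolab > 0
    tab <- unique(cbind(isolab[inb], clusters[inb]))
    iso_cell[tab[, 1]] <- seg$cluster_to_cell[tab[, 2]]
  }
  # isolated-object lengths: geodesic length of the seeding branch
  iso_len <- numeric(max(isolab))
  bi <- graph$branch_info
  if (nrow(bi) && length(iso$branch_to_mito)) {
    m <- iso$branch_to_mito[as.character(bi$branch)]
    ok <- !is.na(m)
    iso_len[m[ok]] <- bi$length[ok]
  }

  for (k in seq_len(n_cells)) {
    cmask <- cells == k
    nmask <- nuclei == k
    rec <- setNames(as.list(rep(NA_real_, length(feats))), feats)

    cs <- shape_descriptors(cmask)
    rec$Cell_Area <- cs$area
    rec$Cell_MeanIntensity <- mean(field$cell[cmask])
    rec$Cell_MaxIntensity <- max(field$cell[cmask])
    rec$Cell_Perimeter <- cs$perimeter
    rec$Cell_Compaction <- cs$compaction
    rec$Cell_Roundness <- cs$roundness

    cl_ids <- which(seg$cluster_to_cell == k)
    if (length(cl_ids)) {
      cluster_shapes <- lapply(cl_crops[as.character(cl_ids)], shape_descriptors)
      cluster_max <- cl_max_int[cl_ids]
      iso_ids <- which(iso_cell == k)
      iso_shapes <- lapply(iso_crops[as.character(iso_ids)], shape_descriptors)
      agg <- aggregate_cell(cluster_shapes, cluster_max,
                            iso_shapes, iso_len[iso_ids])
      rec[names(agg)] <- agg

      union_mask <- matrix(clusters %in% cl_ids, nrow(clusters))
      fd <- box_count_fd(union_mask)
      rec$MitoCluster_Fractal2 <- fd$fractal2
      rec$MitoCluster_Fractal8 <- fd$fractal8
      rec$MitoCluster_Fractal32 <- fd$fractal32
      rec$Mito_MeanIntensity <- mean(field$mito[union_mask])

      sf <- skeleton_features(graph, seg$clusters, seg$cluster_to_cell, k)
      rec[names(sf)] <- sf
      skel_px <- graph$skeleton & union_mask
      rec[c("DistToMembrane", "DistToNuclei", "RatioDistMemb0Nucl1")] <-
        localization_features(skel_px, cmask, nmask)
    }
    rows[[k]] <- cbind(data.frame(condition = field$condition,
                                  field_id = field$field_id, cell_id = k,
                                  stringsAsFactors = FALSE),
                       as.data.frame(rec))
  }
  do.call(rbind, rows)
}

# crop a logical mask to the bounding box of its nonzero pixels
#' @noRd
crop_region <- function(b) {
  rc <- which(b, arr.ind = TRUE)
  b[min(rc[, 1]):max(rc[, 1]), min(rc[, 2]):max(rc[, 2]), drop = FALSE]
}

# one-pass extraction of per-label cropped logical masks (named by label)
#' @noRd
region_crops <- function(lab) {
  rc <- which(lab > 0, arr.ind = TRUE)
  if (!nrow(rc)) return(list())
  v <- lab[lab > 0]
  sp <- split(seq_len(nrow(rc)), v)
  lapply(sp, function(rows) {
    co <- rc[rows, , drop = FALSE]
    r0 <- min(co[, 1]); c0 <- min(co[, 2])
    m <- matrix(FALSE, max(co[, 1]) - r0 + 1L, max(co[, 2]) - c0 + 1L)
    m[cbind(co[, 1] - r0 + 1L, co[, 2] - c0 + 1L)] <- TRUE
    m
  })
}
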