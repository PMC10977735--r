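# Stages 4-5: skeletonize the mitochondrial clusters, decompose the
# skeleton into branches / end points / junction points, and re-segment the
# clusters into isolated mitochondria seeded by the skeleton branches.

#' Zhang-Suen morphological thinning
#'
#' Topology-preserving reduction of a binary mask to 1-px-wide curves. The
#' classical two-subiteration scheme, vectorized over shifted matrices;
#' iterates until stable. Isolated single pixels are retained.
#'
#' @param b binary matrix (nonzero = foreground).
#' @return logical matrix of the skeleton.
#' @export
thin_binary <- function(b) {
  S <- (b != 0) * 1
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift0(S, -1,  0); p3 <- shift0(S, -1,  1)
      p4 <- shift0(S,  0,  1); p5 <- shift0(S,  1,  1)
      p6 <- shift0(S,  1,  0); p7 <- shift0(S,  1, -1)
      p8 <- shift0(S,  0, -1); p9 <- shift0(S, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1) {
        cond <- p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      del <- S == 1 & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        S[del] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  S > 0
}

#' Skeletonize mitochondrial clusters and decompose into branches
#'
#' Each cluster is thinned to a 1-px skeleton; skeleton pixels are classed
#' by their 8-neighbor count (0 or 1 neighbor = end point, >= 3 = junction
#' point). A branch is the skeleton path bounded by two of {end point,
#' junction point}: operationally, an 8-connected component of the skeleton
#' minus the junction pixels. An isolated single-pixel skeleton is one
#' degenerate branch of length 0 with one end point. Junction pixels that
#' are 8-adjacent are merged into a single junction node for counting. A
#' cluster whose skeleton consists only of junction pixels (tiny clumps)
#' contributes one degenerate branch spanning those pixels so that every
#' cluster with a skeleton owns at least one branch.
#'
#' @param clusters a [label_mask] of kind `"clusters"`.
#' @param cluster_to_cell optional integer map cluster label -> cell label.
#' @return an object of class `skeleton_graph`: list with `skeleton`
#'   (logical matrix), `branches` (integer branch-label matrix),
#'   `end_points` / `junction_points` (logical matrices),
#'   `junction_nodes` (integer node-label matrix of merged junctions) and
#'   `branch_info` (data.frame: branch, cluster, cell, n_px, length).
#' @export
skeletonize_clusters <- function(clusters, cluster_to_cell = NULL) {
  stopifnot(inherits(clusters, "label_mask"), clusters$kind == "clusters")
  cl <- clusters$labels
  skel <- thin_binary(cl > 0)
  # thinning can erase very compact blobs entirely (e.g. a final 2x2 block
  # satisfies both deletion subiterations); restore a single medial pixel
  # so every cluster keeps a degenerate skeleton
  lost <- setdiff(unique(cl[cl > 0]), unique(cl[skel]))
  if (length(lost)) {
    d <- distmap_raw(cl > 0)
    for (oc in lost) {
      idx <- which(cl == oc)
      skel[idx[which.max(d[idx])]] <- TRUE
    }
  }
  nc <- neighbor_count8(skel)
  nc[!skel] <- -1L
  end_pts <- skel & nc <= 1          # includes isolated single pixels
  junction <- skel & nc >= 3

  branch_px <- skel & !junction
  branches <- label_components(branch_px, 8)
  # degenerate case: skeleton present but all pixels are junctions
  skel_cl <- unique(cl[skel])
  branch_cl <- unique(cl[branches > 0])
  orphan <- setdiff(skel_cl, branch_cl)
  for (oc in orphan) {
    sel <- skel & cl == oc
    branches[sel] <- max(branches) + 1L
  }
  junction_nodes <- label_components(junction, 8)

  K <- max(branches)
  info <- data.frame(branch = integer(0), cluster = integer(0),
                     cell = integer(0), n_px = integer(0), length = numeric(0))
  if (K > 0) {
    inb <- branches > 0
    bc <- unique(cbind(branches[inb], cl[inb]))
    bc <- bc[order(bc[, 1]), , drop = FALSE]
    lens <- branch_lengths(branches)
    npx <- tabulate(branches[inb], nbins = K)
    cell <- if (is.null(cluster_to_cell)) rep(NA_integer_, K) else
      as.integer(cluster_to_cell[bc[, 2]])
    info <- data.frame(branch = bc[, 1], cluster = bc[, 2], cell = cell,
                       n_px = npx[bc[, 1]], length = lens[bc[, 1]])
  }
  structure(list(skeleton = skel, branches = branches,
                 end_points = end_pts, junction_points = junction,
                 junction_nodes = junction_nodes,
                 branch_info = info, parent_field = clusters$parent_field),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d skeleton px, %d branches, %d end points, %d junction nodes\n",
              sum(x$skeleton), max(x$branches), sum(x$end_points),
              max(x$junction_nodes)))
  invisible(x)
}

# Geodesic length per branch label: axial steps count 1, diagonal steps
# sqrt(2); a diagonal pair sharing an axial neighbor inside the same branch
# is dropped (chain-length correction for staircase corners).
#' @noRd
branch_lengths <- function(branches) {
  K <- max(branches)
  if (K == 0) return(numeric(0))
  len <- numeric(K)
  add_pairs <- function(dr, dc, w, excl_offsets = NULL) {
    a <- branches; b <- shift0(branches, dr, dc)
    keep <- a > 0 & a == b
    if (!is.null(excl_offsets)) {
      for (off in excl_offsets) {
        nb <- shift0(branches, off[1], off[2])
        keep <- keep & !(nb == a)
      }
    }
    if (any(keep)) {
      s <- rowsum(rep(w, sum(keep)), a[keep])
      len[as.integer(rownames(s))] <<- len[as.integer(rownames(s))] + s[, 1]
    }
  }
  add_pairs(1, 0, 1)
  add_pairs(0, 1, 1)
  # pair (p, p+(1,1)): skip if p+(1,0) or p+(0,1) is in the same branch
  add_pairs(1, 1, sqrt(2), list(c(1, 0), c(0, 1)))
  # pair (p, p+(1,-1)): skip if p+(1,0) or p+(0,-1) is in the same branch
  add_pairs(1, -1, sqrt(2), list(c(1, 0), c(0, -1)))
  len
}

#' Re-segment clusters into isolated mitochondria seeded by skeleton branches
#'
#' Within each cluster every pixel is assigned to exactly one skeleton
#' branch by geodesic nearest-branch propagation (watershed on the negated
#' distance-to-branch relief, seeded by the branch labels and confined to
#' the cluster support). The union of isolated labels' support equals the
#' cluster support pixel-exactly.
#'
#' @param clusters a [label_mask] of kind `"clusters"`.
#' @param graph the [skeletonize_clusters] result for the same mask.
#' @return list with `isolated` (a [label_mask] of kind `"isolated_mito"`)
#'   and `branch_to_mito` (integer bijection branch label -> isolated label).
#' @export
segment_isolated_mito <- function(clusters, graph) {
  stopifnot(inherits(clusters, "label_mask"), clusters$kind == "clusters",
            inherits(graph, "skeleton_graph"))
  cl <- clusters$labels
  if (max(cl) == 0) {
    return(list(isolated = label_mask(matrix(0L, nrow(cl), ncol(cl)),
                                      "isolated_mito", clusters$parent_field),
                branch_to_mito = integer(0)))
  }
  seeds <- graph$branches
  # propagate is geodesic within the mask, so labels never cross clusters
  iso <- EBImage::propagate(x = array(0, dim(cl)), seeds = seeds,
                            mask = cl > 0, lambda = 1e8)
  iso <- matrix(as.integer(iso), nrow(cl), ncol(cl))
  # any cluster with no seed at all (cannot occur for >=1 px skeletons,
  # guarded anyway): label its pixels as one isolated object
  left <- cl > 0 & iso == 0
  if (any(left)) {
    extra <- label_components(left, 8)
    iso[left] <- max(iso) + extra[left]
  }
  u <- sort(unique(iso[iso > 0]))
  lut <- integer(max(u) + 1L)
  lut[u + 1L] <- seq_along(u)
  iso_c <- matrix(lut[iso + 1L], nrow(cl), ncol(cl))
  b2m <- setNames(lut[u + 1L], u) # original branch label -> compact iso label
  list(isolated = label_mask(iso_c, "isolated_mito", clusters$parent_field),
       branch_to_mito = b2m)
}
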