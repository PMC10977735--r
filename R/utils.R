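# Low-level matrix helpers shared across the segmentation and skeleton code.
# All images are plain base-R numeric/integer matrices, row-major, origin at
# the top-left corner; EBImage is called on them directly where it provides
# the primitive (labeling, watershed, distance maps, contours).

#' Gaussian kernel (1D, normalized)
#' @noRd
gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Separable Gaussian blur with symmetric (reflective) boundary handling
#'
#' Reflective padding avoids the border roll-off of circular convolution,
#' which would otherwise interact with the border-object filter in the
#' nuclei stage.
#'
#' @param x numeric matrix.
#' @param sigma standard deviation in pixels; `sigma <= 0` returns `x`.
#' @return blurred matrix, same dimensions.
#' @export
gaussian_blur <- function(x, sigma) {
  if (!is.matrix(x)) stop("gaussian_blur: 'x' must be a 2D matrix")
  if (sigma <= 0) return(x)
  k <- gauss_kernel(sigma)
  x <- blur_1d(x, k)          # along rows (vertical)
  t(blur_1d(t(x), k))         # along columns (horizontal)
}

# convolve each column of x with kernel k, symmetric padding
#' @noRd
blur_1d <- function(x, k) {
  n <- nrow(x)
  r <- (length(k) - 1L) / 2L
  r <- min(r, n - 1L)
  k <- k[seq(length(k) / 2 + 0.5 - r, length(k) / 2 + 0.5 + r)]
  k <- k / sum(k)
  idx <- c(r:1, 1:n, n:(n - r + 1))
  if (r == 0L) idx <- 1:n
  xp <- x[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(x))
  for (i in seq_along(k)) {
    out <- out + k[i] * xp[i:(i + n - 1L), , drop = FALSE]
  }
  out
}

#' Shift a matrix by (dr, dc), zero-filling exposed borders
#' @noRd
shift0 <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(0, n, p)
  if (abs(dr) >= n || abs(dc) >= p) return(out)
  rs <- max(1, 1 + dr):min(n, n + dr)
  cs <- max(1, 1 + dc):min(p, p + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Count of 8-neighbors that are nonzero, per pixel
#' @noRd
neighbor_count8 <- function(b) {
  b <- (b != 0) * 1
  shift0(b, 1, 0) + shift0(b, -1, 0) + shift0(b, 0, 1) + shift0(b, 0, -1) +
    shift0(b, 1, 1) + shift0(b, 1, -1) + shift0(b, -1, 1) + shift0(b, -1, -1)
}

# minimal union-find used to merge diagonally adjacent 4-connected labels
#' @noRd
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' 8-connected component labeling
#'
#' EBImage's `bwlabel` uses 4-connectivity; diagonal adjacencies between its
#' labels are merged with a union-find pass so that components follow the
#' 8-connectivity convention used throughout the pipeline.
#'
#' @param b binary matrix (nonzero = foreground).
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of compact labels 0..K.
#' @export
label_components <- function(b, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  lab <- EBImage::bwlabel((b != 0) * 1)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  K <- max(lab)
  if (connectivity == 4 || K < 2) return(compactify_labels(lab))
  pairs <- rbind(
    diag_pairs(lab, 1, 1),
    diag_pairs(lab, 1, -1)
  )
  if (nrow(pairs)) {
    storage.mode(pairs) <- "integer"
    parent <- seq_len(K)
    for (i in seq_len(nrow(pairs))) {
      a <- uf_find(parent, pairs[i, 1]); bb <- uf_find(parent, pairs[i, 2])
      if (a != bb) parent[max(a, bb)] <- min(a, bb)
    }
    root <- vapply(seq_len(K), function(i) uf_find(parent, i), integer(1))
    lut <- c(0L, root)
    lab <- matrix(lut[lab + 1L], nrow(lab), ncol(lab))
  }
  compactify_labels(lab)
}

# unique label pairs (a < b) that touch along a diagonal offset
#' @noRd
diag_pairs <- function(lab, dr, dc) {
  a <- lab
  b <- shift0(lab, dr, dc)
  keep <- a > 0 & b > 0 & a != b
  if (!any(keep)) return(matrix(integer(0), 0, 2))
  pr <- cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]))
  unique(pr)
}

#' Relabel an integer mask to compact labels 1..K (order of first appearance
#' by original label value)
#' @export
compactify_labels <- function(lab) {
  u <- sort(unique(as.integer(lab[lab > 0])))
  if (!length(u)) return(matrix(0L, nrow(lab), ncol(lab)))
  lut <- integer(max(u) + 1L)
  lut[u + 1L] <- seq_along(u)
  matrix(lut[as.integer(lab) + 1L], nrow(lab), ncol(lab))
}

#' Remove connected components smaller than `min_area` pixels
#' @noRd
remove_small <- function(b, min_area, connectivity = 8) {
  lab <- label_components(b, connectivity)
  if (max(lab) == 0) return(lab > 0)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(sizes >= min_area)
  matrix(lab %in% keep, nrow(b), ncol(b))
}

#' Pixels of labeled objects that touch the image border
#' @noRd
border_labels <- function(lab) {
  unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
}

#' Euclidean distance map (distance of foreground pixels to nearest
#' background pixel), treating the image border as background
#' @noRd
distmap_padded <- function(b) {
  n <- nrow(b); p <- ncol(b)
  pad <- matrix(0, n + 2, p + 2)
  pad[2:(n + 1), 2:(p + 1)] <- (b != 0) * 1
  d <- EBImage::distmap(pad)
  matrix(d[2:(n + 1), 2:(p + 1)], n, p)
}

#' Euclidean distance map without border padding (the image edge is not
#' treated as background; needed when the zero set is an object, e.g. the
#' nucleus, rather than the surround)
#' @noRd
distmap_raw <- function(b) {
  d <- EBImage::distmap((b != 0) * 1)
  matrix(as.numeric(d), nrow(b), ncol(b))
}

#' Disk-shaped structuring element offsets of radius r (pixels)
#' @noRd
disk_offsets <- function(r) {
  s <- -floor(r):floor(r)
  g <- expand.grid(dr = s, dc = s)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

#' Binary dilation with a disk kernel
#' @noRd
dilate_disk <- function(b, radius) {
  brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  EBImage::dilate((b != 0) * 1, brush) > 0
}

#' Fill holes of a binary mask
#' @noRd
fill_holes <- function(b) {
  EBImage::fillHull((b != 0) * 1) > 0
}
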