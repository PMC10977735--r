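# Geometric fixtures and independent oracles, built in code at test time.

disk_mask <- function(side, r, ctr = c((side + 1) / 2, (side + 1) / 2)) {
  m <- matrix(0, side, side)
  m[(row(m) - ctr[1])^2 + (col(m) - ctr[2])^2 <= r^2] <- 1
  m
}

ellipse_fix <- function(side, a, b, ctr = c((side + 1) / 2, (side + 1) / 2)) {
  m <- matrix(0, side, side)
  m[((row(m) - ctr[1]) / a)^2 + ((col(m) - ctr[2]) / b)^2 <= 1] <- 1
  m
}

bar_mask <- function(side, len, wid, ctr = c(side / 2, side / 2)) {
  m <- matrix(0, side, side)
  r0 <- round(ctr[1] - wid / 2 + 1); r1 <- r0 + wid - 1
  c0 <- round(ctr[2] - len / 2 + 1); c1 <- c0 + len - 1
  m[r0:r1, c0:c1] <- 1
  m
}

plus_mask <- function(side = 81, arm = 61, wid = 5) {
  m <- bar_mask(side, arm, wid)
  m + t(m) > 0
}

# independent dense 2D Gaussian convolution (zero padding; compare away
# from borders)
dense_gauss2d <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  xs <- -r:r
  k2 <- exp(-outer(xs^2, xs^2, "+") / (2 * sigma^2))
  k2 <- k2 / sum(k2)
  n <- nrow(img); p <- ncol(img)
  out <- matrix(0, n, p)
  for (i in seq_along(xs)) for (j in seq_along(xs)) {
    sh <- matrix(0, n, p)
    dr <- xs[i]; dc <- xs[j]
    rs <- max(1, 1 + dr):min(n, n + dr)
    cs <- max(1, 1 + dc):min(p, p + dc)
    sh[rs, cs] <- img[rs - dr, cs - dc]
    out <- out + k2[i, j] * sh
  }
  out
}

# brute-force box counting: double loop over boxes, any() occupancy
brute_box_counts <- function(mask) {
  b <- mask != 0
  rc <- which(b, arr.ind = TRUE)
  b <- b[min(rc[, 1]):max(rc[, 1]), min(rc[, 2]):max(rc[, 2]), drop = FALSE]
  P <- max(0L, ceiling(log2(max(dim(b)))))
  side <- 2L^P
  M <- matrix(FALSE, side, side)
  M[seq_len(nrow(b)), seq_len(ncol(b))] <- b
  sapply(0:P, function(k) {
    R <- 2L^k
    cnt <- 0L
    for (i in seq(1, side, by = R)) for (j in seq(1, side, by = R)) {
      if (any(M[i:(i + R - 1), j:(j + R - 1)])) cnt <- cnt + 1L
    }
    cnt
  })
}

# write a field's three channels as 16-bit grayscale TIFFs; returns paths
write_field_tiffs <- function(field, dir, id = field$field_id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(nuclei = file.path(dir, paste0(id, "_c1.tif")),
             cell = file.path(dir, paste0(id, "_c2.tif")),
             mito = file.path(dir, paste0(id, "_c3.tif")))
  for (role in names(paths)) {
    img <- pmin(field[[role]], 65535) / 65535
    tiff::writeTIFF(img, paths[[role]], bits.per.sample = 16,
                    compression = "none")
  }
  paths
}

# best-match per-object IoU of true labels against recovered labels
best_iou <- function(true_lab, rec_lab) {
  sapply(seq_len(max(true_lab)), function(k) {
    tr <- true_lab == k
    if (max(rec_lab) == 0) return(0)
    ov <- tabulate(rec_lab[tr & rec_lab > 0], nbins = max(rec_lab))
    j <- which.max(ov)
    sum(tr & rec_lab == j) / sum(tr | rec_lab == j)
  })
}
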