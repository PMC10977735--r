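test_that("band-pass is a difference of Gaussians", {
  # constant image: exactly zero response
  expect_true(all(bandpass(matrix(7, 32, 32), 2, 6) == 0))

  # single impulse: response equals the explicit 2D kernel difference
  img <- matrix(0, 64, 64); img[32, 32] <- 1
  got <- bandpass(img, 2, 6)
  want <- dense_gauss2d(img, 2) - dense_gauss2d(img, 6)
  expect_equal(got, want, tolerance = 1e-12)

  # nucleus blob on a slowly varying background: peak preserved, background
  # suppressed by > 90 percent
  side <- 300
  grad <- matrix(rep(seq(0, 200, length.out = side), each = side), side)
  blob <- 1000 * disk_mask(side, 20, ctr = c(220, 220))
  bp <- bandpass(grad + blob, 3, 12)
  # background strip away from the blob halo and the reflected borders
  interior <- bp[50:120, 50:250]
  expect_lt(max(abs(interior)), 0.1 * 200)
  expect_gt(bp[220, 220], 100)          # blob center response survives

  expect_error(bandpass(array(0, c(4, 4, 2)), 1, 2), "2D")
  expect_error(bandpass(matrix(0, 4, 4), 3, 2), "sigma_lo < sigma_hi")
})

test_that("nuclei segmentation follows the staged protocol", {
  p <- seg_params()
  bg <- matrix(100, 256, 256)

  # large centered blob: exactly one nucleus
  one <- segment_nuclei(bg + 1000 * disk_mask(256, 40), p)
  expect_equal(max(one$labels), 1)
  # dilation by 3 px: recovered area close to (and above) the disk area
  expect_gt(sum(one$labels == 1), pi * 40^2)
  expect_lt(sum(one$labels == 1), pi * 46^2)

  # same blob scaled below the 2000 px floor: removed
  none <- segment_nuclei(bg + 1000 * disk_mask(256, 20), p)
  expect_equal(max(none$labels), 0)

  # blob touching the border: removed
  border <- segment_nuclei(bg + 1000 * disk_mask(256, 40, ctr = c(10, 128)), p)
  expect_equal(max(border$labels), 0)

  # two blobs bridged by a thin neck: watershed splits them
  two_img <- bg + 1000 * (disk_mask(256, 35, c(128, 75)) +
                            disk_mask(256, 35, c(128, 180)) > 0)
  two_img[126:130, 75:180] <- 1100
  two <- segment_nuclei(two_img, p)
  expect_equal(max(two$labels), 2)

  # empty channel: empty mask is a valid result
  expect_equal(max(segment_nuclei(bg, p)$labels), 0)

  # no label touches the border; deterministic re-run
  expect_false(any(setdiff(mitomorph:::border_labels(two$labels), 0L) > 0))
  expect_identical(two$labels, segment_nuclei(two_img, p)$labels)
})

test_that("cell segmentation seeds from nuclei and honors the floor", {
  side <- 128
  nuc_lab <- matrix(0L, side, side)
  nuc_lab[disk_mask(side, 12, c(64, 40)) > 0] <- 1L
  nuclei <- label_mask(nuc_lab, "nuclei", "f")

  # uniform green above the floor: one cell covering everything
  uni <- matrix(500, side, side)
  cells <- segment_cells(uni, nuclei, seg_params(cell_intensity_floor = 100))
  expect_true(all(cells$labels == 1L))

  # floor above the maximum: only the nucleus-forced core survives
  hi <- segment_cells(uni, nuclei, seg_params(cell_intensity_floor = 1000))
  expect_identical(hi$labels > 0, nuc_lab > 0)

  # two nuclei with a bright membrane ridge: two cells whose shared
  # boundary stays within the ridge band and its basin flank. Cytoplasm
  # brightens toward each nucleus (as around a real perinuclear region) so
  # the relief has one basin per cell; the ridge forms its own residual
  # basin that merges to one side, so the boundary can sit on either flank
  # of the ridge but never deep inside a cell body.
  nuc2 <- nuc_lab
  nuc2[disk_mask(side, 12, c(64, 88)) > 0] <- 2L
  nuclei2 <- label_mask(nuc2, "nuclei", "f")
  green <- matrix(100, side, side)
  d1 <- sqrt((row(green) - 64)^2 + (col(green) - 40)^2)
  d2 <- sqrt((row(green) - 64)^2 + (col(green) - 88)^2)
  rect_r <- 40:88; rect_c <- 12:116
  green[rect_r, rect_c] <- (3000 + 2000 * pmax(exp(-d1^2 / 1250),
                                               exp(-d2^2 / 1250)))[rect_r, rect_c]
  green[rect_r, 62:66] <- 9000   # ridge between the two cells
  cells2 <- segment_cells(green, nuclei2,
                          seg_params(cell_intensity_floor = 1500))
  expect_equal(max(cells2$labels), 2)
  expect_equal(cells2$labels[64, 40], 1L)
  expect_equal(cells2$labels[64, 88], 2L)
  # each side is uniformly one cell away from the ridge neighborhood
  expect_true(all(cells2$labels[rect_r, 15:58] == 1L))
  expect_true(all(cells2$labels[rect_r, 85:113] == 2L))
  # the shared boundary never leaves the ridge band + flank
  boundary_cols <- which(apply(cells2$labels[rect_r, , drop = FALSE], 2,
                               function(col) any(col == 1) & any(col == 2)))
  expect_true(all(boundary_cols >= 59 & boundary_cols <= 84))
  # below-floor pixels excluded from cells
  expect_true(all(cells2$labels[green < 1500] == 0L))

  expect_error(segment_cells(matrix(0, 64, 64), nuclei), "shape")
})

test_that("mito cluster segmentation thresholds, filters and maps to cells", {
  side <- 200
  cells <- label_mask(matrix(1L, side, side), "cells", "f")
  img <- matrix(100, side, side)
  bars <- list(c(30, 30), c(30, 120), c(90, 30), c(90, 120), c(150, 80))
  for (b in bars) img[b[1]:(b[1] + 2), b[2]:(b[2] + 24)] <- 2100
  res <- segment_mito_clusters(img, cells, seg_params())
  expect_equal(max(res$clusters$labels), 5)
  expect_true(all(res$cluster_to_cell == 1L))

  # a tiny speck whose thresholded component stays below 10 px: removed
  img2 <- img
  img2[170, 170] <- 2100
  res2 <- segment_mito_clusters(img2, cells, seg_params())
  expect_equal(max(res2$clusters$labels), 5)

  # tubule partially outside any cell: only the in-cell fragment retained
  half <- matrix(0L, side, side); half[, 1:100] <- 1L
  cells_half <- label_mask(half, "cells", "f")
  img3 <- matrix(100, side, side)
  img3[100:102, 60:140] <- 2100
  res3 <- segment_mito_clusters(img3, cells_half, seg_params())
  expect_equal(max(res3$clusters$labels), 1)
  expect_true(all(which(res3$clusters$labels > 0, arr.ind = TRUE)[, 2] <= 100))

  # cluster straddling two cells is split per cell
  two <- matrix(1L, side, side); two[, 101:side] <- 2L
  res4 <- segment_mito_clusters(img3, label_mask(two, "cells", "f"),
                                seg_params())
  expect_equal(max(res4$clusters$labels), 2)
  expect_setequal(res4$cluster_to_cell, c(1L, 2L))
})

test_that("cells partition their foreground with one nucleus each", {
  fx <- recovery_fixture(seed = 3)
  cells <- fx$res$cells$labels
  nuclei <- fx$res$nuclei$labels
  expect_equal(max(cells), max(nuclei))
  for (k in seq_len(max(cells))) {
    nuc_in_cell <- unique(nuclei[cells == k & nuclei > 0])
    expect_equal(nuc_in_cell, k)  # cell k contains exactly nucleus k
  }
  # clusters lie inside labeled cells and the map is total
  cl <- fx$res$clusters$labels
  expect_true(all(cells[cl > 0] > 0))
  expect_true(all(fx$res$cluster_to_cell > 0))
  expect_length(fx$res$cluster_to_cell, max(cl))
})
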