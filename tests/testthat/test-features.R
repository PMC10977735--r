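test_that("shape descriptors recover known geometry", {
  # rasterized disk: circular symmetry
  d <- shape_descriptors(disk_mask(80, 30))
  expect_equal(d$area, sum(disk_mask(80, 30)))
  expect_equal(d$compaction, 1, tolerance = 0.05)
  expect_equal(d$elongation, 1, tolerance = 0.05)
  expect_equal(d$roundness, 1, tolerance = 0.05)
  expect_equal(d$euler, 1)

  # 2:1 ellipse: elongation 2, compaction 0.5
  e <- shape_descriptors(ellipse_fix(120, 20, 40))
  expect_equal(e$elongation, 2, tolerance = 0.05)
  expect_equal(e$compaction, 0.5, tolerance = 0.05)
  expect_equal(e$elongation * e$compaction, 1, tolerance = 1e-9)

  # annulus: one component, one hole
  ann <- disk_mask(80, 30) - disk_mask(80, 15)
  a <- shape_descriptors(ann)
  expect_equal(a$euler, 0)
  expect_lt(a$solidity, 1)  # hull perimeter shorter than the two contours

  # degenerate single pixel
  px <- matrix(0, 5, 5); px[3, 3] <- 1
  s <- shape_descriptors(px)
  expect_equal(s$compaction, 1)
  expect_equal(s$elongation, 1)
  expect_gte(s$perimeter, 1)
  expect_error(shape_descriptors(matrix(0, 4, 4)), "empty")
})

test_that("shape invariants hold on random regions", {
  set.seed(21)
  for (i in 1:25) {
    m <- matrix(0, 40, 40)
    r0 <- sample(5:20, 1)
    m[r0:(r0 + sample(1:15, 1)), sample(5:20, 1) + 0:sample(1:15, 1)] <- 1
    s <- shape_descriptors(m)
    expect_gte(s$elongation, 1)
    expect_gt(s$compaction, 0); expect_lte(s$compaction, 1)
    expect_equal(s$elongation * s$compaction, 1, tolerance = 1e-9)
  }
})

test_that("box counting pads to a power-of-two square", {
  m <- matrix(0, 320, 200)
  m[1, 1] <- 1; m[320, 200] <- 1   # span the full 320 x 200 extent
  prof <- box_count_fd(m)
  expect_equal(prof$padded_side, 512)
  expect_length(prof$N, 10)        # P + 1 = 10 counts, sizes 2^0..2^9
  expect_length(prof$R, length(prof$FD))
})

test_that("fractal dimension limits: plane 2, line 1, point 0", {
  full <- matrix(1, 256, 256)
  pf <- box_count_fd(full)
  expect_equal(pf$N, (256 / pf$R)^2)
  expect_true(all(abs(pf$FD - 2) < 1e-12))
  expect_equal(pf$fractal2, 2); expect_equal(pf$fractal32, 2)

  pt <- matrix(0, 64, 64); pt[10, 20] <- 1
  pp <- box_count_fd(pt)
  expect_true(all(pp$N == 1))
  expect_true(all(pp$FD == 0))

  ln <- matrix(0, 256, 256); ln[128, ] <- 1
  pl <- box_count_fd(ln)
  interior <- 2:(length(pl$FD) - 1)
  expect_true(all(abs(pl$FD[interior] - 1) < 1e-12))

  # empty mask: missing, not zero
  pe <- box_count_fd(matrix(0, 32, 32))
  expect_true(is.na(pe$fractal2) && is.na(pe$fractal8) && is.na(pe$fractal32))
  # box counts are non-increasing in box size; N(1) = pixel count
  expect_equal(pl$N[1], sum(ln))
  expect_true(all(diff(pl$N) <= 0))
})

test_that("box counts match a brute-force oracle on random masks", {
  set.seed(31)
  for (i in 1:100) {
    m <- matrix(rbinom(64 * 64, 1, runif(1, 0.02, 0.6)), 64, 64)
    if (!any(m)) m[sample(64, 1), sample(64, 1)] <- 1
    prof <- box_count_fd(m)
    expect_identical(as.integer(prof$N), as.integer(brute_box_counts(m)))
    expect_true(all(prof$FD >= -1e-12 & prof$FD <= 2 + 1e-12))
  }
})

test_that("localization ratio spans nucleus (0) to membrane (1)", {
  side <- 121
  cellm <- disk_mask(side, 55) > 0
  nucm <- disk_mask(side, 15) > 0
  at <- function(r, c) { m <- matrix(FALSE, side, side); m[r, c] <- TRUE; m }
  ctr <- 61
  near_nuc <- localization_features(at(ctr, ctr + 17), cellm, nucm)
  expect_lt(near_nuc$RatioDistMemb0Nucl1, 0.1)
  near_mem <- localization_features(at(ctr, ctr + 54), cellm, nucm)
  expect_gt(near_mem$RatioDistMemb0Nucl1, 0.9)
  middle <- localization_features(at(ctr, ctr + 35), cellm, nucm)
  expect_equal(middle$RatioDistMemb0Nucl1, 0.5, tolerance = 0.05)
  # distances are consistent with the radial geometry
  expect_equal(near_nuc$DistToNuclei, 2, tolerance = 1)
  expect_equal(near_mem$DistToMembrane, 1, tolerance = 1)
  none <- localization_features(matrix(FALSE, side, side), cellm, nucm)
  expect_true(is.na(none$DistToNuclei))
})

test_that("aggregation sums areas and lengths, averages the rest", {
  s1 <- list(area = 100, perimeter = 40, compaction = 1, elongation = 1,
             roundness = 1.0, euler = 1, solidity = 0.9)
  s2 <- list(area = 50, perimeter = 20, compaction = 0.5, elongation = 2,
             roundness = 0.5, euler = 0, solidity = 1.1)
  agg <- aggregate_cell(list(s1, s2), cluster_max_int = c(800, 400),
                        iso_shapes = list(s1, s2), iso_lengths = c(10, 5))
  expect_equal(agg$MitoCluster_Count, 2)
  expect_equal(agg$MitoCluster_Area, 150)          # summed
  expect_equal(agg$Mito_Length, 15)                # summed
  expect_equal(agg$MitoCluster_Roundness, 0.75)    # averaged
  expect_equal(agg$MitoCluster_Perimeter, 30)      # averaged
  expect_equal(agg$MitoCluster_EulerNumber, 0.5)
  expect_equal(agg$Mito_MaxIntensity, 600)         # mean of per-cluster maxima
  expect_equal(agg$Mito_Elongation, 1.5)

  # aggregating a single object is the identity
  one <- aggregate_cell(list(s1), 800, list(s1), 10)
  expect_equal(one$MitoCluster_Area, s1$area)
  expect_equal(one$MitoCluster_Roundness, s1$roundness)
  expect_equal(one$MitoCluster_Solidity, s1$solidity)
  expect_equal(one$Mito_Length, 10)
  expect_equal(one$MitoCluster_Count, 1)
})

test_that("per-cell records carry 31 features; empty cells stay missing", {
  fx <- recovery_fixture(seed = 3)
  feats <- fx$res$features
  expect_equal(ncol(feats) - 3, 31)
  expect_true(all(mito_feature_names() %in% names(feats)))
  expect_equal(nrow(feats), max(fx$res$cells$labels))
  # ratio features in [0, 1]; elongation/compaction reciprocal
  expect_true(all(feats$RatioDistMemb0Nucl1 >= 0 &
                    feats$RatioDistMemb0Nucl1 <= 1, na.rm = TRUE))
  expect_true(all(feats$Skel_BranchPointsEndPointsRatio >= 0 &
                    feats$Skel_BranchPointsEndPointsRatio <= 1, na.rm = TRUE))
  expect_true(all(feats$Cell_Compaction > 0 & feats$Cell_Compaction <= 1))

  # a field with no mitochondrial signal still emits cellular features
  sim <- generate_field(synth_params(n_cells = 1, image_side = 300, seed = 5))
  f2 <- sim$field
  f2$mito <- matrix(100, 300, 300)
  rec <- process_field(f2)$features
  expect_equal(nrow(rec), 1)
  expect_false(is.na(rec$Cell_Area))
  expect_true(is.na(rec$MitoCluster_Area))
  expect_true(is.na(rec$Skel_Length))
})
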