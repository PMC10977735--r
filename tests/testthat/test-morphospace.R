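mk_means <- function(...) {
  rows <- list(...)
  M <- do.call(rbind, rows)
  colnames(M) <- mito_feature_names()[seq_len(ncol(M))]
  M
}

test_that("min-max normalization follows the Vn identity", {
  M <- matrix(c(2, 4, 6), 3, 1, dimnames = list(c("a", "b", "c"), "Cell_Area"))
  pr <- normalize_profiles(M, reference = "a")
  expect_equal(unname(pr$Vn[, 1]), c(0, 0.5, 1))
  expect_false(pr$degenerate[["Cell_Area"]])

  # Vp == Vmin maps to 0 regardless of scale
  M2 <- cbind(M, Cell_Perimeter = c(10, 30, 20))
  pr2 <- normalize_profiles(M2, "a")
  expect_equal(pr2$Vn["a", "Cell_Perimeter"], 0)
  expect_equal(pr2$Vn["b", "Cell_Perimeter"], 1)

  # constant feature: degenerate flag, Vn pinned at 0.5
  M3 <- cbind(M, Skel_Width = c(5, 5, 5))
  pr3 <- normalize_profiles(M3, "a")
  expect_true(pr3$degenerate[["Skel_Width"]])
  expect_true(all(pr3$Vn[, "Skel_Width"] == 0.5))

  expect_error(normalize_profiles(M, "zzz"), "not found")
  expect_error(normalize_profiles(M[1, , drop = FALSE], "a"), ">= 2")
})

test_that("normalization is affine-invariant per feature", {
  set.seed(41)
  M <- matrix(runif(12, 1, 9), 4, 3,
              dimnames = list(paste0("c", 1:4),
                              c("Cell_Area", "Skel_Length", "Mito_Length")))
  base <- normalize_profiles(M, "c1")$Vn
  M2 <- M
  M2[, 2] <- 7 * M[, 2] + 100   # affine transform of one feature
  expect_equal(normalize_profiles(M2, "c1")$Vn, base)
})

test_that("significance tiers follow the printed p thresholds", {
  feats <- c("Cell_Area")
  mk_tab <- function(ref_vals, cond_vals) {
    data.frame(condition = rep(c("ref", "trt"),
                               c(length(ref_vals), length(cond_vals))),
               Cell_Area = c(ref_vals, cond_vals))
  }
  # identical groups: p = 1, tier ns
  t1 <- suppressWarnings(
    significance_tiers(mk_tab(c(1, 2, 3), c(1, 2, 3)), "ref", feats))
  expect_equal(t1$p_value, 1)
  expect_equal(t1$tier, "ns")

  # constant separated groups: zero-variance fast path, maximally significant
  t0 <- suppressWarnings(
    significance_tiers(mk_tab(c(5, 5, 5), c(9, 9, 9)), "ref", feats))
  expect_equal(t0$p_value, 0)
  expect_equal(t0$tier, "***")

  # near-separated groups with tiny jitter: *** by the closed-form t
  set.seed(1)
  t3 <- suppressWarnings(significance_tiers(
    mk_tab(rnorm(5, 0, 0.01), rnorm(5, 10, 0.01)), "ref", feats))
  expect_equal(t3$tier, "***")
  expect_equal(t3$direction, 1)

  # tiers are monotone in p across the threshold grid
  tier_for_p <- function(ref, trt) {
    suppressWarnings(significance_tiers(mk_tab(ref, trt), "ref", feats))
  }
  set.seed(2)
  ref <- rnorm(6)
  shifts <- seq(0, 4, by = 0.25)
  res <- lapply(shifts, function(s) tier_for_p(ref, rnorm(6, s, 1)))
  p <- vapply(res, `[[`, numeric(1), "p_value")
  tier_rank <- c(ns = 0, "*" = 1, "**" = 2, "***" = 3)
  r <- tier_rank[vapply(res, `[[`, character(1), "tier")]
  ord <- order(p, decreasing = TRUE)
  expect_true(all(diff(r[ord]) >= 0))
  # tier bands match the thresholds exactly
  expect_equal(unname(r), unname(tier_rank[
    ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                    ifelse(p < 0.05, "*", "ns")))]))

  # per-cell testing warns about independence
  expect_warning(significance_tiers(mk_tab(1:3, 2:4), "ref", feats),
                 "independent")
})

sig_row <- function(feature, direction, tier = "*") {
  data.frame(condition = "trt", feature = feature, p_value = 0.01,
             tier = tier, direction = direction, stringsAsFactors = FALSE)
}
ns_rows <- function() {
  data.frame(condition = "trt", feature = mito_feature_names(),
             p_value = 0.5, tier = "ns", direction = 0,
             stringsAsFactors = FALSE)
}
with_sig <- function(...) {
  tab <- ns_rows()
  for (r in list(...)) {
    i <- match(r$feature, tab$feature)
    tab[i, ] <- r
  }
  tab
}

test_that("sigil classification maps signatures to morphospace codes", {
  # all ns: reference on every axis
  ref <- classify_sigil(ns_rows())
  expect_equal(ref$mito_state, "M1")
  expect_equal(ref$localization, "I1")
  expect_equal(ref$cell_shape, "C1")
  expect_false(any(ref$conflict))

  # swollen: significant Skel_Width increase
  sw <- classify_sigil(with_sig(sig_row("Skel_Width", 1)))
  expect_equal(sw$mito_state, "M7")

  # perinuclear: significant DistToNuclei decrease
  pn <- classify_sigil(with_sig(sig_row("DistToNuclei", -1)))
  expect_equal(pn$localization, "I3")

  # fission pattern
  fi <- classify_sigil(with_sig(sig_row("MitoCluster_Count", 1),
                                sig_row("Mito_Length", -1),
                                sig_row("Mito_Roundness", 1)))
  expect_true("M6" %in% fi$mito_state)

  # branching
  br <- classify_sigil(with_sig(sig_row("Skel_BranchPointsCount", 1),
                                sig_row("Skel_Length", 1)))
  expect_true("M3" %in% br$mito_state)

  # cell retraction vs spreading vs star-like
  expect_equal(classify_sigil(with_sig(sig_row("Cell_Area", -1)))$cell_shape,
               "C2")
  expect_equal(classify_sigil(with_sig(sig_row("Cell_Area", 1)))$cell_shape,
               "C3")
  expect_equal(classify_sigil(with_sig(sig_row("Cell_Perimeter", 1)))$cell_shape,
               "C5")

  # conflicting localization codes are all emitted, with a flag
  both <- classify_sigil(with_sig(sig_row("DistToNuclei", -1),
                                  sig_row("DistToMembrane", -1)))
  expect_setequal(both$localization, c("I2", "I3"))
  expect_true(both$conflict[["localization"]])

  # pure function of (signs, tiers): repeated call identical
  expect_identical(unclass(classify_sigil(ns_rows())),
                   unclass(classify_sigil(ns_rows())))
})

test_that("spider plot renders an SVG with the profile structure", {
  dir <- withr::local_tempdir()
  set.seed(5)
  M <- matrix(runif(62, 1, 10), 2, 31,
              dimnames = list(c("ref", "trt"), mito_feature_names()))
  pr <- normalize_profiles(M, "ref")
  tiers <- ns_rows()
  tiers$tier[1] <- "***"; tiers$p_value[1] <- 1e-5; tiers$direction[1] <- 1
  path <- file.path(dir, "spider.svg")
  render_spider(pr, tiers, path)
  expect_true(file.exists(path))
  svg_txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  expect_match(svg_txt, "<svg", fixed = TRUE)
  expect_gt(nchar(svg_txt), 5000)
  # png device also supported; unknown extension rejected
  render_spider(pr, NULL, file.path(dir, "spider.png"))
  expect_true(file.size(file.path(dir, "spider.png")) > 0)
  expect_error(render_spider(pr, NULL, file.path(dir, "x.pdf")), "svg or")
})
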