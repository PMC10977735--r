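# Condition-level analysis: min-max normalized spider profiles, per-feature
# t-test significance tiers, radar-chart rendering, and the rule-based
# morphospace classifier of mito-cellular configurations.

# Feature order on the spider plot: the five ontology groups
# (Abundance, Shape, Connectivity, Size, Density & Texture).
#' Feature grouping used on the spider plot
#' @return named character vector mapping feature -> ontology group.
#' @export
feature_ontology <- function() {
  c(MitoCluster_Count = "Abundance",
    Cell_Compaction = "Shape", Cell_Roundness = "Shape",
    MitoCluster_Elongation = "Shape", MitoCluster_Compaction = "Shape",
    MitoCluster_Roundness = "Shape", Mito_Compaction = "Shape",
    Mito_Elongation = "Shape", Mito_Roundness = "Shape",
    Skel_BranchPointsCount = "Connectivity", Skel_EndPointsCount = "Connectivity",
    Skel_BranchPointsEndPointsRatio = "Connectivity",
    MitoCluster_EulerNumber = "Connectivity",
    MitoCluster_Fractal2 = "Connectivity", MitoCluster_Fractal8 = "Connectivity",
    MitoCluster_Fractal32 = "Connectivity",
    Cell_Area = "Size", Cell_Perimeter = "Size", MitoCluster_Area = "Size",
    MitoCluster_Perimeter = "Size", Skel_Width = "Size", Skel_Length = "Size",
    Mito_Length = "Size",
    Cell_MeanIntensity = "Density & Texture", Cell_MaxIntensity = "Density & Texture",
    Mito_MeanIntensity = "Density & Texture", Mito_MaxIntensity = "Density & Texture",
    MitoCluster_Solidity = "Density & Texture",
    DistToMembrane = "Density & Texture", DistToNuclei = "Density & Texture",
    RatioDistMemb0Nucl1 = "Density & Texture")
}

#' spider-plot feature order (grouped by ontology class)
#' @noRd
spider_feature_order <- function() {
  ont <- feature_ontology()
  grp <- factor(ont, levels = c("Abundance", "Shape", "Connectivity",
                                "Size", "Density & Texture"))
  names(ont)[order(grp, seq_along(ont))]
}

#' Min-max normalize per-condition feature means into spider profiles
#'
#' Per feature, `Vn = (Vp - Vmin) / (Vmax - Vmin)` with Vmin/Vmax taken
#' over the condition means being compared. When a feature is constant
#' across conditions (`Vmax == Vmin`), Vn is set to 0.5 for every condition
#' and the feature is flagged degenerate.
#'
#' @param condition_means matrix or data.frame of feature means, rows =
#'   conditions (rownames = condition ids), columns = features.
#' @param reference the reference condition id.
#' @return object of class `spider_profile`: list with `Vp`, `Vn`,
#'   `reference`, `degenerate` (logical per feature).
#' @export
normalize_profiles <- function(condition_means, reference) {
  Vp <- as.matrix(condition_means)
  if (nrow(Vp) < 2) stop("need >= 2 conditions to normalize")
  if (!reference %in% rownames(Vp))
    stop(sprintf("reference condition '%s' not found", reference))
  vmin <- apply(Vp, 2, min, na.rm = TRUE)
  vmax <- apply(Vp, 2, max, na.rm = TRUE)
  rng <- vmax - vmin
  degenerate <- is.na(rng) | rng == 0
  Vn <- sweep(Vp, 2, vmin, "-")
  Vn <- sweep(Vn, 2, ifelse(degenerate, 1, rng), "/")
  Vn[, degenerate] <- 0.5
  structure(list(Vp = Vp, Vn = Vn, reference = reference,
                 degenerate = degenerate),
            class = "spider_profile")
}

#' @export
print.spider_profile <- function(x, ...) {
  cat(sprintf("<spider_profile> %d conditions x %d features (reference: %s)\n",
              nrow(x$Vn), ncol(x$Vn), x$reference))
  if (any(x$degenerate))
    cat("  degenerate features:",
        paste(colnames(x$Vn)[x$degenerate], collapse = ", "), "\n")
  invisible(x)
}

#' Per-feature significance tiers versus the reference condition
#'
#' A two-sample t-test (Welch by default) per feature, comparing each
#' condition's per-cell values to the reference; tiers follow the printed
#' thresholds: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001, `ns`
#' otherwise. When replicate structure is supplied (`unit = "experiment"`
#' and an `experiment` column), per-cell values are averaged within each
#' experiment first and the test runs on experiment means.
#'
#' @param cell_table per-cell feature data.frame (as from
#'   [compute_cell_features] / [read_cell_table]) with a `condition` column.
#' @param reference reference condition id.
#' @param features feature columns to test (default: the 31).
#' @param var_equal use Student's pooled-variance t-test instead of Welch.
#' @param unit `"cell"` (default, with a warning: cells within a field are
#'   not independent replicates) or `"experiment"`.
#' @return data.frame: condition, feature, p_value, tier, direction
#'   (sign of condition mean minus reference mean).
#' @export
significance_tiers <- function(cell_table, reference,
                               features = mito_feature_names(),
                               var_equal = FALSE, unit = c("cell", "experiment")) {
  unit <- match.arg(unit)
  if (unit == "experiment") {
    if (!"experiment" %in% names(cell_table))
      stop("unit = 'experiment' requires an 'experiment' column")
    agg <- stats::aggregate(cell_table[features],
                            by = cell_table[c("condition", "experiment")],
                            FUN = mean, na.rm = TRUE)
    cell_table <- agg
  } else {
    warning("testing per-cell values: cells are treated as independent; ",
            "supply replicate structure (unit = 'experiment') when available",
            call. = FALSE)
  }
  conds <- setdiff(unique(cell_table$condition), reference)
  if (!reference %in% cell_table$condition)
    stop(sprintf("reference condition '%s' not found", reference))
  out <- list()
  for (cond in conds) {
    for (f in features) {
      x <- cell_table[cell_table$condition == reference, f]
      y <- cell_table[cell_table$condition == cond, f]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      p <- p_two_sample(x, y, var_equal)
      dirn <- sign(mean(y) - mean(x))
      if (!length(y) || !length(x)) dirn <- 0
      out[[length(out) + 1]] <- data.frame(
        condition = cond, feature = f, p_value = p,
        tier = tier_of(p), direction = dirn, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @noRd
p_two_sample <- function(x, y, var_equal) {
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    # zero-variance fast path: identical groups are maximally insignificant
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  tryCatch(stats::t.test(x, y, var.equal = var_equal)$p.value,
           error = function(e) NA_real_)
}

#' @noRd
tier_of <- function(p) {
  if (is.na(p)) return("ns")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Classify a condition's signature into a morphospace code
#'
#' Rule-based mapping on significantly changed features (tier at least `*`)
#' and their directions, relative to the reference:
#'
#' Mitochondrial state axis (M1 reference):
#' * M2 fusion: `Mito_Length` up with `MitoCluster_Count` or
#'   `Skel_EndPointsCount` down.
#' * M3 branching: `Skel_BranchPointsCount` up with `Skel_Length` up.
#' * M4 compaction: `MitoCluster_Compaction` or `Mito_Compaction` up,
#'   without the full fission pattern.
#' * M5 dislocation: `Skel_Length` down and `Skel_BranchPointsCount` down
#'   with `MitoCluster_Solidity` up.
#' * M6 fission: `MitoCluster_Count` up with `Mito_Length` down and
#'   roundness or compaction up.
#' * M7 swollen: `Skel_Width` up.
#'
#' Localization axis (I1 reference): I2 pericortical when `DistToMembrane`
#' is down, I3 perinuclear when `DistToNuclei` is down.
#'
#' Cell-shape axis (C1 reference): C2 retraction (`Cell_Area` down), C3
#' spreading (`Cell_Area` up), C4 compaction (`Cell_Compaction` or
#' `Cell_Roundness` up), C5 star-like (`Cell_Perimeter` up without
#' `Cell_Area` up), C6 marker intensity (`Cell_MeanIntensity` or
#' `Cell_MaxIntensity` changed).
#'
#' Several codes may fire on one axis (composite states); a conflict flag
#' is raised per axis when they do. With no significant change on an axis
#' the reference code is returned.
#'
#' @param tiers data.frame from [significance_tiers] for one condition.
#' @return object of class `sigil_code`: list with `mito_state`,
#'   `localization`, `cell_shape` (character vectors), `conflict` (named
#'   logical), and `fired` (rule-firing trace).
#' @export
classify_sigil <- function(tiers) {
  stopifnot(all(c("feature", "tier", "direction") %in% names(tiers)))
  if (length(unique(tiers$condition)) > 1)
    stop("classify_sigil expects the tiers of a single condition")
  sig <- tiers$tier != "ns" & !is.na(tiers$p_value)
  up <- function(f) any(sig & tiers$feature == f & tiers$direction > 0)
  down <- function(f) any(sig & tiers$feature == f & tiers$direction < 0)

  fission <- up("MitoCluster_Count") && down("Mito_Length") &&
    (up("Mito_Roundness") || up("MitoCluster_Roundness") ||
       up("Mito_Compaction") || up("MitoCluster_Compaction"))
  rules <- list(
    M2 = up("Mito_Length") &&
      (down("MitoCluster_Count") || down("Skel_EndPointsCount")),
    M3 = up("Skel_BranchPointsCount") && up("Skel_Length"),
    M4 = (up("MitoCluster_Compaction") || up("Mito_Compaction")) && !fission,
    M5 = down("Skel_Length") && down("Skel_BranchPointsCount") &&
      up("MitoCluster_Solidity"),
    M6 = fission,
    M7 = up("Skel_Width"),
    I2 = down("DistToMembrane"),
    I3 = down("DistToNuclei"),
    C2 = down("Cell_Area"),
    C3 = up("Cell_Area"),
    C4 = up("Cell_Compaction") || up("Cell_Roundness"),
    C5 = up("Cell_Perimeter") && !up("Cell_Area"),
    C6 = up("Cell_MeanIntensity") || down("Cell_MeanIntensity") ||
      up("Cell_MaxIntensity") || down("Cell_MaxIntensity"))
  fired <- names(rules)[vapply(rules, isTRUE, logical(1))]
  mito <- intersect(c("M2", "M3", "M4", "M5", "M6", "M7"), fired)
  loc <- intersect(c("I2", "I3"), fired)
  shape <- intersect(c("C2", "C3", "C4", "C5", "C6"), fired)
  structure(list(
    mito_state = if (length(mito)) mito else "M1",
    localization = if (length(loc)) loc else "I1",
    cell_shape = if (length(shape)) shape else "C1",
    conflict = c(mito = length(mito) > 1, localization = length(loc) > 1,
                 cell_shape = length(shape) > 1),
    fired = fired), class = "sigil_code")
}

#' @export
print.sigil_code <- function(x, ...) {
  cat(sprintf("<sigil_code> mito: %s | localization: %s | cell: %s\n",
              paste(x$mito_state, collapse = "+"),
              paste(x$localization, collapse = "+"),
              paste(x$cell_shape, collapse = "+")))
  if (any(x$conflict))
    cat("  composite axes:", paste(names(x$conflict)[x$conflict],
                                   collapse = ", "), "\n")
  invisible(x)
}

#' Render a spider (radar) plot of normalized profiles
#'
#' Reference drawn as a circle at its normalized values' display radius,
#' conditions as closed polylines over the 31 feature axes ordered by
#' ontology group; significance encoded as circles of three sizes at the
#' feature vertices.
#'
#' @param profile a [normalize_profiles] result.
#' @param tiers optional [significance_tiers] result.
#' @param out_path output file; `.svg` or `.png`.
#' @param width,height device size in inches.
#' @return invisibly, `out_path`.
#' @export
render_spider <- function(profile, tiers = NULL, out_path,
                          width = 9, height = 9) {
  stopifnot(inherits(profile, "spider_profile"))
  ext <- tolower(tools::file_ext(out_path))
  if (ext == "svg") {
    grDevices::svg(out_path, width = width, height = height)
  } else if (ext == "png") {
    grDevices::png(out_path, width = width * 100, height = height * 100,
                   res = 100, type = "cairo")
  } else stop("out_path must end in .svg or .png")
  on.exit(grDevices::dev.off())

  ord <- intersect(spider_feature_order(), colnames(profile$Vn))
  Vn <- profile$Vn[, ord, drop = FALSE]
  nf <- length(ord)
  ang <- pi / 2 - 2 * pi * (seq_len(nf) - 1) / nf
  graphics::par(mar = c(1, 1, 2, 1))
  graphics::plot(NA, xlim = c(-1.85, 1.85), ylim = c(-1.85, 1.85),
                 asp = 1, axes = FALSE, xlab = "", ylab = "",
                 main = "Normalized phenotype profile")
  for (rr in c(0.25, 0.5, 0.75, 1))
    graphics::lines(rr * cos(seq(0, 2 * pi, length.out = 181)),
                    rr * sin(seq(0, 2 * pi, length.out = 181)),
                    col = "grey85")
  graphics::segments(0, 0, cos(ang), sin(ang), col = "grey90")
  lab_r <- 1.35
  graphics::text(lab_r * cos(ang), lab_r * sin(ang), ord, cex = 0.45,
                 srt = 0, col = "grey30")
  # display radius: 0.2 + 0.8 * Vn keeps zero-valued features visible
  disp <- function(v) 0.2 + 0.8 * pmin(pmax(v, 0), 1)
  conds <- rownames(Vn)
  cols <- grDevices::hcl.colors(max(3, length(conds)), "Dark 3")
  for (i in seq_along(conds)) {
    r <- disp(Vn[i, ])
    r[!is.finite(r)] <- 0.2
    xx <- r * cos(ang); yy <- r * sin(ang)
    is_ref <- conds[i] == profile$reference
    graphics::polygon(c(xx, xx[1]), c(yy, yy[1]), border = if (is_ref)
      "forestgreen" else cols[i], lwd = if (is_ref) 2.5 else 1.5)
  }
  if (!is.null(tiers)) {
    sz <- c("*" = 0.6, "**" = 1.0, "***" = 1.5)
    for (i in seq_len(nrow(tiers))) {
      f <- tiers$feature[i]
      if (!f %in% ord || tiers$tier[i] == "ns") next
      j <- match(f, ord)
      ci <- match(tiers$condition[i], conds)
      r <- disp(Vn[ci, j])
      graphics::points(r * cos(ang[j]), r * sin(ang[j]),
                       cex = sz[[tiers$tier[i]]], pch = 1, lwd = 2,
                       col = "black")
    }
  }
  graphics::legend("topleft", legend = conds, bty = "n", cex = 0.8,
                   col = ifelse(conds == profile$reference, "forestgreen",
                                cols[seq_along(conds)]), lwd = 2)
  invisible(out_path)
}
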