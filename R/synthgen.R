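# Synthetic three-channel fluorescence fields with ground truth.
#
# The generator emulates flat cultured adherent cells: smooth cell blobs
# tiling part of the frame, one elliptical nucleus each, and mitochondria
# drawn as persistent random-walk tubules whose number, length, width and
# radial placement follow three phenotype knobs (fragmentation, swelling,
# perinuclear bias). Channels are rasterized, blurred by a Gaussian PSF and
# corrupted by Poisson shot noise. Identical seed implies bit-identical
# output.

#' Synthetic-field parameters
#'
#' @param n_cells number of cells placed on a jittered grid.
#' @param image_side image side length in px.
#' @param fragmentation in `[0, 1]`: 0 = few long, branched tubules,
#'   1 = many small round grains (total mitochondrial area held roughly
#'   constant, so the object count rises with fragmentation).
#' @param swelling in `[0, 1]`: tubule width multiplier (diameter
#'   `3 * (1 + 2 * swelling)` px).
#' @param perinuclear_bias in `[0, 1]`: 0 = mitochondria spread through the
#'   cytoplasm, 1 = tightly packed against the nuclear envelope.
#' @param noise_level >= 0 shot-noise scale (0 = noiseless).
#' @param psf_sigma Gaussian point-spread-function sigma in px (0 = none).
#' @param seed RNG seed; the generator uses one local RNG stream and
#'   restores the global seed on exit.
#' @return an object of class `synth_params`.
#' @export
synth_params <- function(n_cells = 4, image_side = 512, fragmentation = 0.3,
                         swelling = 0, perinuclear_bias = 0.2,
                         noise_level = 0.02, psf_sigma = 1, seed = 1) {
  ratios <- c(fragmentation, swelling, perinuclear_bias)
  if (any(ratios < 0 | ratios > 1))
    stop("fragmentation, swelling and perinuclear_bias must lie in [0, 1]")
  if (noise_level < 0) stop("noise_level must be >= 0")
  structure(list(n_cells = as.integer(n_cells),
                 image_side = as.integer(image_side),
                 fragmentation = fragmentation, swelling = swelling,
                 perinuclear_bias = perinuclear_bias,
                 noise_level = noise_level, psf_sigma = psf_sigma,
                 seed = as.integer(seed)),
            class = "synth_params")
}

#' Generate one synthetic field with ground truth
#'
#' @param params a [synth_params].
#' @param field_id,condition identifiers for the generated field.
#' @return list with `field` (a [field_image]) and `truth`: true `nuclei`,
#'   `cells` and `mito` label masks plus a `per_cell` data.frame of true
#'   per-cell counts (mitochondria components; end/branch points of the
#'   true-mask skeleton), total centerline length, mitochondrial area and
#'   mean tubule width.
#' @export
generate_field <- function(params = synth_params(), field_id = "synth",
                           condition = "") {
  stopifnot(inherits(params, "synth_params"))
  with_local_seed(params$seed, {
    side <- params$image_side
    g <- ceiling(sqrt(params$n_cells))
    spacing <- side / g
    R_base <- spacing * 0.40
    if (R_base < 45)
      stop(sprintf(paste0("n_cells = %d is too large for image_side = %d: ",
                          "cells would be too small to host a nucleus"),
                   params$n_cells, side))

    nuc_lab <- matrix(0L, side, side)
    cell_lab <- matrix(0L, side, side)
    mito_lab <- matrix(0L, side, side)
    rowg <- row(nuc_lab); colg <- col(nuc_lab)

    centers <- cell_centers(params$n_cells, g, spacing)
    per_cell <- vector("list", params$n_cells)
    tube_amp <- list()
    label_offset <- 0L

    for (k in seq_len(params$n_cells)) {
      ctr <- centers[k, ]
      R <- R_base * stats::runif(1, 0.92, 1.05)
      blob <- wobbly_blob(rowg, colg, ctr, R)
      cell_lab[blob] <- k

      # nucleus: rotated ellipse at a small offset from the cell center;
      # sized to the 60x imaging scale (~120 px across a real nucleus)
      th <- stats::runif(1, 0, pi)
      ax <- R * stats::runif(1, 0.68, 0.72)
      bx <- R * stats::runif(1, 0.60, 0.63)
      off <- stats::runif(2, -0.04, 0.04) * R
      nmask <- ellipse_mask(rowg, colg, ctr + off, ax, bx, th) & blob
      nuc_lab[nmask] <- k

      tubes <- draw_mitochondria(ctr, R, blob, nmask, params, rowg, colg)
      sel <- tubes$mask & mito_lab == 0L
      mito_lab[sel] <- tubes$labels[sel] + label_offset
      tube_amp[[k]] <- tubes$amps
      label_offset <- label_offset + tubes$n_tubes
      mito_bin_k <- tubes$mask & blob
      comps <- label_components(mito_bin_k & cell_lab == k, 8)
      # true connectivity counts from the skeleton of the true mask (drawn
      # tubes can merge, so nominal per-tube counts overstate the truth)
      tsk <- thin_binary(mito_bin_k)
      tnc <- neighbor_count8(tsk)
      per_cell[[k]] <- data.frame(
        cell = k,
        n_mito = max(comps),
        n_tubes = tubes$n_tubes,
        n_end = sum(tsk & tnc <= 1),
        n_branch = max(label_components(tsk & tnc >= 3, 8)),
        centerline_len = tubes$centerline_len,
        mito_area = sum(mito_bin_k),
        mean_width = if (tubes$centerline_len > 0)
          sum(mito_bin_k) / tubes$centerline_len else NA_real_)
    }

    # render channels: rasterize -> PSF blur -> shot noise
    nuc_img <- 300 + 11700 * (nuc_lab > 0)
    boundary <- cell_boundary_band(cell_lab, width = 2)
    green <- 250 + 2750 * (cell_lab > 0) + 6500 * boundary
    amps <- unlist(tube_amp)
    mito_img <- matrix(200, side, side)
    if (max(mito_lab) > 0) {
      amp_lut <- c(0, amps[seq_len(max(mito_lab))])
      amp_lut[is.na(amp_lut)] <- 10000
      mito_img <- mito_img + amp_lut[mito_lab + 1L]
    }
    if (params$psf_sigma > 0) {
      nuc_img <- gaussian_blur(nuc_img, params$psf_sigma)
      green <- gaussian_blur(green, params$psf_sigma)
      mito_img <- gaussian_blur(mito_img, params$psf_sigma)
    }
    if (params$noise_level > 0) {
      nuc_img <- shot_noise(nuc_img, params$noise_level)
      green <- shot_noise(green, params$noise_level)
      mito_img <- shot_noise(mito_img, params$noise_level)
    }

    field <- field_image(nuc_img, green, mito_img, field_id = field_id,
                         condition = condition)
    truth <- list(nuclei = label_mask(nuc_lab, "nuclei", field_id),
                  cells = label_mask(cell_lab, "cells", field_id),
                  mito = label_mask(compactify_labels(mito_lab), "clusters",
                                    field_id),
                  per_cell = do.call(rbind, per_cell),
                  params = params)
    list(field = field, truth = truth)
  })
}

#' Series of fields differing only in one phenotype knob
#'
#' All levels share the same seed, so the cell layout is identical across
#' the series and only the knob-driven mitochondrial phenotype changes
#' (mirroring a dose series).
#'
#' @param base a [synth_params].
#' @param knob one of `"fragmentation"`, `"swelling"`,
#'   `"perinuclear_bias"`, `"noise_level"`, `"psf_sigma"`.
#' @param values numeric vector of knob values.
#' @param condition_prefix conditions are named `<prefix><value>`.
#' @return list of [generate_field] results, one per value.
#' @export
phenotype_series <- function(base = synth_params(), knob, values,
                             condition_prefix = "") {
  if (!knob %in% setdiff(names(unclass(base)), "seed"))
    stop(sprintf("unknown knob '%s'", knob))
  lapply(values, function(v) {
    p <- unclass(base)
    p[[knob]] <- v
    p <- do.call(synth_params, p)
    generate_field(p, field_id = sprintf("%s%s_%g", condition_prefix, knob, v),
                   condition = sprintf("%s%g", condition_prefix, v))
  })
}

# ---- internals ---------------------------------------------------------

#' run expr with a local RNG stream, restoring the global seed
#' @noRd
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @noRd
cell_centers <- function(n_cells, g, spacing) {
  idx <- seq_len(n_cells) - 1L
  gr <- idx %/% g
  gc <- idx %% g
  jit <- matrix(stats::runif(2 * n_cells, -0.03, 0.03) * spacing, ncol = 2)
  cbind(spacing * (gr + 0.5), spacing * (gc + 0.5)) + jit
}

#' smooth blob: radius modulated by low-frequency sinusoids
#' @noRd
wobbly_blob <- function(rowg, colg, ctr, R) {
  a <- stats::runif(3, 0.03, 0.09)
  ph <- stats::runif(3, 0, 2 * pi)
  dy <- rowg - ctr[1]; dx <- colg - ctr[2]
  th <- atan2(dx, dy)
  rr <- R * (1 + a[1] * sin(2 * th + ph[1]) + a[2] * sin(3 * th + ph[2]) +
               a[3] * sin(5 * th + ph[3]))
  sqrt(dy^2 + dx^2) <= rr
}

#' @noRd
ellipse_mask <- function(rowg, colg, ctr, a, b, theta) {
  dy <- rowg - ctr[1]; dx <- colg - ctr[2]
  u <- dy * cos(theta) + dx * sin(theta)
  v <- -dy * sin(theta) + dx * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' band of pixels within `width` px of each cell's boundary
#' @noRd
cell_boundary_band <- function(cell_lab, width = 2) {
  band <- matrix(FALSE, nrow(cell_lab), ncol(cell_lab))
  for (k in seq_len(max(cell_lab))) {
    m <- cell_lab == k
    band <- band | (m & distmap_padded(m) <= width)
  }
  band
}

#' persistent-random-walk tubules for one cell
#' @noRd
draw_mitochondria <- function(ctr, R, blob, nmask, params, rowg, colg) {
  frag <- params$fragmentation
  w <- 3 * (1 + 2 * params$swelling)
  len <- round(exp((1 - frag) * log(55) + frag * log(4)))
  area_budget <- 1800
  per_area <- len * w + 0.8 * w^2
  n_tubes <- max(1L, round(area_budget / per_area))

  side <- nrow(blob)
  mask <- matrix(FALSE, side, side)
  labs <- matrix(0L, side, side)
  offs <- disk_offsets(w / 2)
  # nucleus ellipse proxy radius for placement
  nuc_r <- sqrt(sum(nmask) / pi)
  r_lo <- nuc_r + 2 + w / 2
  r_hi <- max(r_lo + 2, 0.88 * R - w)
  n_end <- 0L; n_branch <- 0L
  centerline <- 0
  amps <- rep(10000, n_tubes) # aligned with tube label 1..n_tubes

  inside <- function(p) {
    r0 <- round(p[1]); c0 <- round(p[2])
    r0 >= 1 && r0 <= side && c0 >= 1 && c0 <= side &&
      blob[r0, c0] && !nmask[r0, c0]
  }
  stamp <- function(p, id) {
    r0 <- round(p[1]); c0 <- round(p[2])
    rr <- r0 + offs$dr; cc <- c0 + offs$dc
    ok <- rr >= 1 & rr <= side & cc >= 1 & cc <= side
    ii <- cbind(rr[ok], cc[ok])
    keep <- blob[ii]
    ii <- ii[keep, , drop = FALSE]
    mask[ii] <<- TRUE
    labs[ii] <<- id
  }
  walk <- function(start, theta, steps, id) {
    p <- start
    drawn <- 0
    for (s in seq_len(steps)) {
      stamp(p, id)
      drawn <- drawn + 1
      theta <- theta + stats::rnorm(1, 0, 0.15)
      ok <- FALSE
      for (try in 1:8) {
        q <- p + c(cos(theta), sin(theta))
        if (inside(q)) { ok <- TRUE; break }
        theta <- theta + stats::runif(1, -1.4, 1.4)
      }
      if (!ok) break
      p <- q
    }
    list(end = p, drawn = drawn)
  }

  for (t in seq_len(n_tubes)) {
    # radial placement: perinuclear bias skews toward the nuclear envelope
    u <- stats::runif(1)^(1 + 4 * params$perinuclear_bias)
    rpos <- r_lo + u * (r_hi - r_lo)
    phi <- stats::runif(1, 0, 2 * pi)
    start <- ctr + rpos * c(cos(phi), sin(phi))
    tries <- 0
    while (!inside(start) && tries < 20) {
      phi <- stats::runif(1, 0, 2 * pi)
      u <- stats::runif(1)^(1 + 4 * params$perinuclear_bias)
      rpos <- r_lo + u * (r_hi - r_lo)
      start <- ctr + rpos * c(cos(phi), sin(phi))
      tries <- tries + 1
    }
    if (!inside(start)) next
    theta0 <- phi + pi / 2 + stats::rnorm(1, 0, 0.4)
    wk <- walk(start, theta0, len, t)
    centerline <- centerline + wk$drawn
    n_end <- n_end + 2L
    amps[t] <- 10000 * stats::runif(1, 0.85, 1.2)
    if (frag < 0.5 && stats::runif(1) < 0.4 * (1 - frag) && wk$drawn > 6) {
      bstart <- start + (wk$end - start) * stats::runif(1, 0.3, 0.7)
      if (inside(bstart)) {
        wb <- walk(bstart, stats::runif(1, 0, 2 * pi), max(3, len %/% 2), t)
        centerline <- centerline + wb$drawn
        n_end <- n_end + 1L
        n_branch <- n_branch + 1L
      }
    }
  }
  list(mask = mask, labels = labs, n_tubes = n_tubes, n_end = n_end,
       n_branch = n_branch, centerline_len = centerline, amps = amps)
}

#' Poisson shot noise: photon count proportional to intensity
#' @noRd
shot_noise <- function(img, noise_level) {
  q <- 50 * noise_level
  n <- length(img)
  matrix(stats::rpois(n, pmax(img, 0) / q) * q, nrow(img), ncol(img))
}
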