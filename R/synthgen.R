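# Synthetic five-channel immunological-synapse scene generator.
#
# Emulates the planar-lipid-bilayer geometry of a CAR-T synapse image:
# an F-actin ring at each cell's periphery (channel 1), punctate perforin
# and pZeta clusters in the actin-sparse center (channels 2 and 4), a
# central tumor-antigen accumulation (channel 3), and a DIC-like
# transmitted-light image (channel 5). The axial profile of every cell
# signal is a Gaussian in z peaked at the focal slice. Every photon of
# cell signal is confined to the cell's ground-truth mask, so the
# integrated per-cell intensity injected at the focal slice is known
# exactly.

DENSITY_RATES <- c(sparse = 0.12, moderate = 0.35, dense = 0.6)

#' Scene parameters for the synthetic generator
#'
#' @param image_height,image_width image size in pixels.
#' @param n_z number of z slices.
#' @param n_cells integer cell count, or one of `"sparse"`, `"moderate"`,
#'   `"dense"` (count derived from image area).
#' @param cell_radius_range length-2 numeric, base cell radius range in px.
#' @param adhesion_prob probability in `[0, 1]` that a new cell is placed
#'   touching an existing one (masks may abut but never share pixels).
#' @param boundary_contrast in `[0, 1]`; scales cell-versus-background
#'   intensity contrast (low values emulate hard-to-see boundaries).
#' @param impurity_density bright background speckles per 1000 px^2.
#' @param focal_z index (1-based) of the in-focus slice; default middle.
#' @param axial_sigma width (slices) of the axial intensity Gaussian.
#' @param antigen_density relative scale of the channel-3 signal.
#' @param channel_gains length-4 multiplier on channels 1-4 signal
#'   amplitude (cohort-level intensity manipulations).
#' @param noise_sd Gaussian read-noise standard deviation as a fraction of
#'   full scale.
#' @param shot_noise factor on `sqrt(signal)` for signal-dependent noise.
#' @param bit_depth 8 or 16 (default 16, the confocal convention).
#' @param seed integer seed; scenes are bit-reproducible.
#' @return a validated list of class `scene_params`.
#' @export
scene_params <- function(image_height = 192L, image_width = 192L, n_z = 7L,
                         n_cells = "moderate",
                         cell_radius_range = c(10, 18),
                         adhesion_prob = 0.15, boundary_contrast = 0.7,
                         impurity_density = 0.3, focal_z = NULL,
                         axial_sigma = 1.5, antigen_density = 1,
                         channel_gains = c(1, 1, 1, 1),
                         noise_sd = 0.004, shot_noise = 0.3,
                         bit_depth = 16L, seed = 1L) {
  if (is.character(n_cells)) {
    n_cells <- match.arg(n_cells, names(DENSITY_RATES))
    n_cells <- max(1L, round(DENSITY_RATES[[n_cells]] *
                               image_height * image_width / 1000))
  }
  n_cells <- as.integer(n_cells)
  n_z <- as.integer(n_z)
  if (is.null(focal_z)) focal_z <- (n_z + 1L) %/% 2L
  focal_z <- as.integer(focal_z)
  p <- list(image_height = as.integer(image_height),
            image_width = as.integer(image_width), n_z = n_z,
            n_cells = n_cells, cell_radius_range = as.numeric(cell_radius_range),
            adhesion_prob = adhesion_prob, boundary_contrast = boundary_contrast,
            impurity_density = impurity_density, focal_z = focal_z,
            axial_sigma = axial_sigma, antigen_density = antigen_density,
            channel_gains = as.numeric(channel_gains), noise_sd = noise_sd,
            shot_noise = shot_noise, bit_depth = as.integer(bit_depth),
            seed = as.integer(seed))
  if (p$n_cells < 0L) sq_stop("n_cells must be >= 0")
  if (p$n_z < 1L) sq_stop("n_z must be >= 1")
  if (p$focal_z < 1L || p$focal_z > p$n_z)
    sq_stop("focal_z must lie in 1..n_z")
  for (f in c("adhesion_prob", "boundary_contrast")) {
    if (p[[f]] < 0 || p[[f]] > 1) sq_stop("%s must be in [0, 1]", f)
  }
  if (any(p$cell_radius_range <= 0) || diff(p$cell_radius_range) < 0)
    sq_stop("cell_radius_range must be positive and non-decreasing")
  if (length(p$channel_gains) != 4L || any(p$channel_gains < 0))
    sq_stop("channel_gains must be 4 non-negative multipliers")
  if (!p$bit_depth %in% c(8L, 16L)) sq_stop("bit_depth must be 8 or 16")
  structure(p, class = "scene_params")
}

# 8-neighborhood binary dilation by one pixel (used for the adjacency gap).
dilate1 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  vert <- m
  if (h > 1L) {
    vert[-1, ] <- vert[-1, ] | m[-h, ]
    vert[-h, ] <- vert[-h, ] | m[-1, ]
  }
  out <- vert
  if (w > 1L) {
    out[, -1] <- out[, -1] | vert[, -w]
    out[, -w] <- out[, -w] | vert[, -1]
  }
  out
}

# Sample one perturbed-ellipse cell shape; returns a function of pixel
# offsets giving (inside, radial fraction u in [0, 1]).
sample_cell_shape <- function(r_base) {
  aspect <- runif(1, 0.72, 1)
  phi <- runif(1, 0, pi)
  k <- 2:5
  amp <- runif(4, 0, 0.07)
  ph <- runif(4, 0, 2 * pi)
  list(
    r_base = r_base, aspect = aspect,
    radial = function(dx, dy) {
      u <- cos(phi) * dx + sin(phi) * dy
      v <- (-sin(phi) * dx + cos(phi) * dy) / aspect
      rho <- sqrt(u^2 + v^2)
      th <- atan2(v, u)
      rb <- r_base * (1 + amp[1] * cos(2 * th + ph[1]) +
                        amp[2] * cos(3 * th + ph[2]) +
                        amp[3] * cos(4 * th + ph[3]) +
                        amp[4] * cos(5 * th + ph[4]))
      list(inside = rho <= rb, u = pmin(rho / pmax(rb, 1e-9), 1))
    },
    r_max = r_base * (1 + sum(amp))
  )
}

# In-mask intensity templates per channel (fraction of amplitude) given the
# radial fraction u; cluster blobs are sampled per cell.
render_cell_channels <- function(u_vals, dx, dy, r_base, full, gains,
                                 antigen_density, contrast) {
  cf <- 0.25 + 0.75 * contrast
  a_jit <- exp(rnorm(4, 0, 0.12))
  # channel 1: peripheral F-actin ring over a dimmer actin-sparse center
  i1 <- full * 0.55 * cf * gains[1] * a_jit[1] *
    (0.45 + 0.55 * exp(-(u_vals - 0.85)^2 / (2 * 0.09^2)))
  # channels 2/4: central punctate clusters in the actin-sparse center
  cluster <- function(amp) {
    n_cl <- sample(1:3, 1)
    out <- numeric(length(u_vals))
    for (j in seq_len(n_cl)) {
      ang <- runif(1, 0, 2 * pi)
      rad <- runif(1, 0, 0.35) * r_base
      cx <- rad * cos(ang); cy <- rad * sin(ang)
      s <- max(1.2, 0.14 * r_base)
      out <- out + exp(-((dx - cx)^2 + (dy - cy)^2) / (2 * s^2))
    }
    amp * out / n_cl
  }
  i2 <- full * 0.5 * gains[2] * a_jit[2] * (0.04 + cluster(1))
  i4 <- full * 0.45 * gains[4] * a_jit[4] * (0.04 + cluster(1))
  # channel 3: central tumor-antigen accumulation
  i3 <- full * 0.5 * antigen_density * gains[3] * a_jit[3] *
    exp(-u_vals^2 / (2 * 0.35^2))
  # channel 5: DIC-like bright rim (added to a global mid-gray background)
  i5 <- full * 0.25 * exp(-(u_vals - 0.97)^2 / (2 * 0.05^2))
  list(i1, i2, i3, i4, i5)
}

#' Generate one synthetic five-channel Z-stack with exact ground truth
#'
#' Places `n_cells` perturbed-ellipse cells (disjoint masks; adjacency only
#' through adhesion), renders the channel-specific synapse intensity
#' layouts, applies the axial Gaussian amplitude profile peaked at
#' `focal_z`, then adds impurity speckles (background only) and read/shot
#' noise. The per-cell, per-channel signal injected at the focal slice is
#' recorded exactly (pre-noise, post-quantisation).
#'
#' @param params a [scene_params()] object.
#' @return list with `stack` (an [image_stack()]) and `gt` (ground truth:
#'   `masks`, `boxes`, `true_tfi` `[n_cells x 4]`, `focal_z`).
#' @export
generate_stack <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(params$seed, generate_stack_impl(params))
}

generate_stack_impl <- function(p) {
  H <- p$image_height; W <- p$image_width
  full <- 2^p$bit_depth - 1
  occ <- matrix(FALSE, H, W)
  masks <- list()
  centers <- NULL
  radii <- numeric(0)
  # signal accumulators, one float matrix per channel at the focal plane;
  # z-profile is a pure amplitude factor so only the focal-plane render is
  # stored per channel together with per-cell ownership
  sig <- lapply(1:5, function(i) matrix(0, H, W))
  true_tfi <- matrix(0, p$n_cells, 4)

  for (ci in seq_len(p$n_cells)) {
    placed <- FALSE
    for (try in seq_len(80L)) {
      r <- runif(1, p$cell_radius_range[1], p$cell_radius_range[2])
      shape <- sample_cell_shape(r)
      wr <- ceiling(shape$r_max) + 1L
      if (2L * wr + 2L >= min(H, W))
        sq_stop("impossible placement: cells of radius %.1f cannot fit a %dx%d image",
                r, H, W)
      adhere <- length(masks) > 0L && runif(1) < p$adhesion_prob
      if (adhere) {
        k <- sample(length(masks), 1)
        ang <- runif(1, 0, 2 * pi)
        d <- (radii[k] + r) * 0.95
        cx <- round(centers[k, 1] + d * cos(ang))
        cy <- round(centers[k, 2] + d * sin(ang))
        cx <- min(max(cx, wr + 1L), W - wr)
        cy <- min(max(cy, wr + 1L), H - wr)
      } else {
        cx <- sample((wr + 1L):(W - wr), 1)
        cy <- sample((wr + 1L):(H - wr), 1)
      }
      xs <- (cx - wr):(cx + wr)
      ys <- (cy - wr):(cy + wr)
      dx <- matrix(rep(xs - cx, each = length(ys)), length(ys))
      dy <- matrix(rep(ys - cy, times = length(xs)), length(ys))
      rad <- shape$radial(dx, dy)
      sub_occ <- occ[ys, xs]
      sub_gap <- dilate1(sub_occ)
      inside <- rad$inside
      if (adhere) {
        inside <- inside & !sub_occ        # disjoint, adjacency allowed
      } else {
        if (any(inside & sub_gap)) next    # require a >= 1 px gap
      }
      if (sum(inside) < 30L) next
      mask <- matrix(FALSE, H, W)
      mask[ys, xs][inside] <- TRUE
      ch <- render_cell_channels(rad$u[inside], dx[inside], dy[inside],
                                 r, full, p$channel_gains,
                                 p$antigen_density, p$boundary_contrast)
      for (c5 in 1:5) {
        m <- sig[[c5]][ys, xs]
        m[inside] <- m[inside] + ch[[c5]]
        sig[[c5]][ys, xs] <- m
      }
      for (c4 in 1:4) {
        true_tfi[ci, c4] <- sum(round(pmin(pmax(ch[[c4]], 0), full)))
      }
      occ <- occ | mask
      masks[[ci]] <- mask
      centers <- rbind(centers, c(cx, cy))
      radii <- c(radii, r)
      placed <- TRUE
      break
    }
    if (!placed)
      sq_stop("impossible placement: could not place cell %d of %d after bounded retries",
              ci, p$n_cells)
  }

  # impurity speckles on background only (2 px clearance from any cell)
  keep_out <- dilate1(dilate1(occ))
  n_imp <- stats::rpois(1, p$impurity_density * H * W / 1000)
  imp <- lapply(1:5, function(i) matrix(0, H, W))
  if (n_imp > 0) {
    free <- which(!keep_out)
    if (length(free)) {
      pos <- sample(free, min(n_imp, length(free)))
      for (q in pos) {
        ch <- sample(1:5, 1)
        amp <- runif(1, 0.25, 0.7) * full
        iy <- (q - 1L) %% H + 1L
        ix <- (q - 1L) %/% H + 1L
        rr <- sample(0:1, 1)
        yy <- max(1L, iy - rr):min(H, iy + rr)
        xx <- max(1L, ix - rr):min(W, ix + rr)
        blk <- outer(yy - iy, xx - ix, function(a, b) exp(-(a^2 + b^2) / 2))
        sub <- imp[[ch]][yy, xx, drop = FALSE]
        imp[[ch]][yy, xx] <- pmax(sub, amp * blk)
      }
      for (c5 in 1:5) imp[[c5]][keep_out] <- 0
    }
  }

  zw <- exp(-(seq_len(p$n_z) - p$focal_z)^2 / (2 * p$axial_sigma^2))
  vox <- array(0L, dim = c(5L, p$n_z, H, W))
  dic_bg <- 0.45 * full
  for (z in seq_len(p$n_z)) {
    for (c5 in 1:5) {
      s <- sig[[c5]] * zw[z] + imp[[c5]]
      if (c5 == 5L) s <- s + dic_bg
      s <- round(s)
      if (p$noise_sd > 0 || p$shot_noise > 0) {
        s <- s + stats::rnorm(H * W, 0, p$noise_sd * full) +
          stats::rnorm(H * W, 0, p$shot_noise * sqrt(pmax(s, 0)))
      }
      vox[c5, z, , ] <- as.integer(pmin(pmax(round(s), 0), full))
    }
  }

  boxes <- if (length(masks)) {
    as.data.frame(do.call(rbind, lapply(masks, mask_bbox)))
  } else {
    data.frame(x_min = numeric(), y_min = numeric(),
               x_max = numeric(), y_max = numeric())
  }
  stack <- image_stack(vox, bit_depth = p$bit_depth)
  gt <- structure(list(masks = masks, boxes = boxes, true_tfi = true_tfi,
                       focal_z = p$focal_z, params = p),
                  class = "ground_truth")
  list(stack = stack, gt = gt)
}

#' Generate a dataset of independent synthetic scenes
#'
#' Each scene gets its own child seed derived from `seed`, so the dataset
#' is reproducible as a whole and scenes are mutually independent.
#'
#' @param n_images number of scenes (>= 1).
#' @param params a [scene_params()] template; its `seed` field is replaced
#'   per scene.
#' @param seed root seed for the dataset.
#' @return list of `n_images` elements, each `list(stack, gt)`.
#' @export
generate_dataset <- function(n_images, params = scene_params(), seed = 1L) {
  n_images <- as.integer(n_images)
  if (n_images < 1L) sq_stop("n_images must be >= 1")
  seeds <- derive_seeds(seed, n_images, stream = "generator")
  lapply(seq_len(n_images), function(i) {
    p <- params
    p$seed <- seeds[i]
    generate_stack(p)
  })
}
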