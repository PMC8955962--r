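# Shared synthetic-scene fixtures, built in code and cached per test run.

# Small, easy, well-separated scene: the workhorse fixture.
easy_params <- function(seed = 1L, n_cells = 4L, ...) {
  scene_params(image_height = 96L, image_width = 96L, n_z = 5L,
               n_cells = n_cells, cell_radius_range = c(9, 14),
               adhesion_prob = 0, boundary_contrast = 0.9,
               impurity_density = 0.1, noise_sd = 0.002, seed = seed, ...)
}

# Noiseless variant for exact-identity checks.
noiseless_params <- function(seed = 1L, n_cells = 4L, ...) {
  scene_params(image_height = 96L, image_width = 96L, n_z = 5L,
               n_cells = n_cells, cell_radius_range = c(9, 14),
               adhesion_prob = 0, boundary_contrast = 0.9,
               impurity_density = 0, noise_sd = 0, shot_noise = 0,
               seed = seed, ...)
}

fixture_cache <- new.env(parent = emptyenv())

cached_scene <- function(key, params) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- generate_stack(params)
  fixture_cache[[key]]
}

# Ground-truth instances (oracle segmentation bypassed entirely).
gt_instances <- function(gt, scores = NULL) {
  lapply(seq_along(gt$masks), function(i)
    cell_instance(i, gt$masks[[i]],
                  score = if (is.null(scores)) 1 else scores[i]))
}

# Random box generator on an integer grid.
random_boxes <- function(n, lim = 60L, max_side = 25L) {
  x0 <- sample.int(lim, n, replace = TRUE) - 1L
  y0 <- sample.int(lim, n, replace = TRUE) - 1L
  data.frame(x_min = x0, y_min = y0,
             x_max = x0 + sample.int(max_side, n, replace = TRUE),
             y_max = y0 + sample.int(max_side, n, replace = TRUE),
             score = round(runif(n), 3))
}

# Random blob mask in an h x w frame (one connected component).
random_blob <- function(h = 40L, w = 40L, r = NULL) {
  r <- r %||% runif(1, 4, 10)
  cx <- sample(seq(ceiling(r) + 2L, w - ceiling(r) - 2L), 1)
  cy <- sample(seq(ceiling(r) + 2L, h - ceiling(r) - 2L), 1)
  xs <- seq_len(w) - cx
  ys <- seq_len(h) - cy
  dx <- matrix(rep(xs, each = h), h)
  dy <- matrix(rep(ys, times = w), h)
  th <- atan2(dy, dx)
  rb <- r * (1 + 0.2 * runif(1) * cos(2 * th + runif(1, 0, 2 * pi)))
  sqrt(dx^2 + dy^2) <= rb
}

`%||%` <- function(a, b) if (is.null(a)) b else a
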