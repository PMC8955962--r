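# Synthetic scene generator: determinism, geometry and signal contracts.

test_that("empty scene yields background-only stack with zero instances", {
  p <- scene_params(image_height = 48L, image_width = 48L, n_z = 3L,
                    n_cells = 0L, seed = 3L)
  sc <- generate_stack(p)
  expect_length(sc$gt$masks, 0)
  expect_equal(nrow(sc$gt$boxes), 0)
  expect_equal(dim(sc$stack), c(5L, 3L, 48L, 48L))
  # background: no structure brighter than plausible noise + impurities in
  # the signal channels
  expect_lt(mean(sc$stack$voxels[1, , , ]), 0.05 * 65535)
})

test_that("identical params give bit-identical stacks and masks", {
  p <- easy_params(seed = 11L)
  a <- generate_stack(p)
  b <- generate_stack(p)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$gt$masks, b$gt$masks)
  expect_identical(a$gt$true_tfi, b$gt$true_tfi)
})

test_that("adhesion_prob = 0 gives pairwise non-adjacent masks (adjacency scan)", {
  sc <- cached_scene("easy5", easy_params(seed = 21L, n_cells = 5L))
  masks <- sc$gt$masks
  expect_length(masks, 5)
  h <- nrow(masks[[1]]); w <- ncol(masks[[1]])
  # brute-force pixel adjacency scan over all mask pairs
  for (i in 1:4) for (j in (i + 1):5) {
    a <- which(masks[[i]], arr.ind = TRUE)
    bj <- masks[[j]]
    touching <- FALSE
    for (k in seq_len(nrow(a))) {
      rr <- max(1, a[k, 1] - 1):min(h, a[k, 1] + 1)
      cc <- max(1, a[k, 2] - 1):min(w, a[k, 2] + 1)
      if (any(bj[rr, cc])) { touching <- TRUE; break }
    }
    expect_false(touching, label = sprintf("masks %d and %d adjacency", i, j))
  }
})

test_that("masks are disjoint, non-empty, inside bounds, with tight boxes", {
  for (seed in c(2L, 8L)) {
    sc <- generate_stack(scene_params(image_height = 80L, image_width = 96L,
                                      n_z = 3L, n_cells = 6L,
                                      adhesion_prob = 0.5, seed = seed))
    masks <- sc$gt$masks
    ownership <- Reduce(`+`, lapply(masks, function(m) m + 0L))
    expect_lte(max(ownership), 1L)
    for (i in seq_along(masks)) {
      expect_gt(sum(masks[[i]]), 0)
      bb <- sc$gt$boxes[i, ]
      w <- which(masks[[i]], arr.ind = TRUE)
      expect_equal(as.numeric(bb),
                   c(min(w[, 2]) - 1, min(w[, 1]) - 1, max(w[, 2]), max(w[, 1])))
    }
  }
})

test_that("channel-3 slice-mean profile is unimodal with argmax at focal_z", {
  for (seed in c(4L, 9L)) {
    p <- scene_params(image_height = 96L, image_width = 96L, n_z = 9L,
                      n_cells = 5L, focal_z = 4L, seed = seed)
    sc <- generate_stack(p)
    prof <- slice_mean_profile(sc$stack, 3L)
    expect_equal(which.max(prof), 4L)
    expect_true(all(diff(prof[1:4]) > 0))
    expect_true(all(diff(prof[4:9]) < 0))
  }
})

test_that("per-cell injected signal matches masked focal-slice sums within the noise budget", {
  p <- easy_params(seed = 31L, n_cells = 4L)
  sc <- generate_stack(p)
  sigma <- p$noise_sd * 65535
  for (i in seq_along(sc$gt$masks)) {
    area <- sum(sc$gt$masks[[i]])
    for (ch in 1:4) {
      got <- sum(stack_slice(sc$stack, ch, sc$gt$focal_z)[sc$gt$masks[[i]]])
      expect_lt(abs(got - sc$gt$true_tfi[i, ch]), 3 * sigma * area)
    }
  }
})

test_that("impossible placements fail explicitly after bounded retries", {
  p <- scene_params(image_height = 40L, image_width = 40L, n_z = 2L,
                    n_cells = 30L, cell_radius_range = c(10, 12),
                    adhesion_prob = 0, seed = 1L)
  expect_error(generate_stack(p), "impossible placement")
})

test_that("generate_dataset is reproducible, seed-sensitive and sized correctly", {
  p <- easy_params(n_cells = 1L)
  d1 <- generate_dataset(1L, p, seed = 5L)
  expect_length(d1, 1)
  d1b <- generate_dataset(3L, p, seed = 5L)
  d2 <- generate_dataset(3L, p, seed = 6L)
  expect_identical(d1b[[2]]$stack$voxels, generate_dataset(3L, p, seed = 5L)[[2]]$stack$voxels)
  expect_false(identical(d1b[[1]]$stack$voxels, d2[[1]]$stack$voxels))
  expect_error(generate_dataset(0L, p), "n_images")
})

test_that("a 156-image corpus can be generated with five channels throughout", {
  p <- scene_params(image_height = 40L, image_width = 40L, n_z = 2L,
                    n_cells = 1L, cell_radius_range = c(5, 7),
                    impurity_density = 0, seed = 1L)
  ds <- generate_dataset(156L, p, seed = 2L)
  expect_length(ds, 156)
  expect_true(all(vapply(ds, function(s) dim(s$stack)[1] == 5L, TRUE)))
})

test_that("scene parameter invariants are enforced", {
  expect_error(scene_params(n_cells = -1), "n_cells")
  expect_error(scene_params(focal_z = 9, n_z = 7), "focal_z")
  expect_error(scene_params(adhesion_prob = 1.2), "adhesion_prob")
  expect_error(scene_params(channel_gains = c(1, 1)), "channel_gains")
})
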