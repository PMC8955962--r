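# Patch segmentation, contours, border/interior partition, assembly.

test_that("crop_patch / paste_patch round-trip coordinates exactly", {
  img <- matrix(seq_len(100), 10, 10)
  cp <- crop_patch(img, c(2, 2, 6, 6), margin = 0L)
  expect_equal(dim(cp$patch), c(4L, 4L))
  expect_equal(cp$placement$x0, 2)
  expect_equal(cp$patch, img[3:6, 3:6])
  # corner box with margin clipped to the frame
  cc <- crop_patch(img, c(0, 0, 3, 3), margin = 2L)
  expect_equal(cp2 <- dim(cc$patch), c(5L, 5L))
  expect_equal(cc$placement$x0, 0)
  set.seed(31)
  for (k in 1:25) {
    h <- sample(12:40, 1); w <- sample(12:40, 1)
    image <- matrix(runif(h * w), h, w)
    bx <- c(sample(0:(w - 3), 1), sample(0:(h - 3), 1))
    bx <- c(bx, bx[1] + sample.int(w - bx[1], 1), bx[2] + sample.int(h - bx[2], 1))
    cp <- crop_patch(image, bx, margin = sample(0:6, 1))
    mask <- cp$patch > 0.5
    pasted <- paste_patch(mask, cp$placement, c(h, w))
    expect_equal(sum(pasted), sum(mask))
    expect_identical(pasted[(cp$placement$y0 + 1):(cp$placement$y0 + cp$placement$height),
                            (cp$placement$x0 + 1):(cp$placement$x0 + cp$placement$width)],
                     mask)
  }
  expect_error(crop_patch(img, c(20, 20, 30, 30), 0L), "does not intersect")
})

test_that("threshold-oracle segmentation recovers noiseless synthetic cells exactly", {
  sc <- cached_scene("clean4", noiseless_params(seed = 2L))
  img <- stack_slice(sc$stack, 1L, sc$gt$focal_z)
  for (i in seq_along(sc$gt$masks)) {
    cp <- crop_patch(img, as.numeric(sc$gt$boxes[i, ]), margin = 8L)
    m <- segment_patch(cp$patch)
    full <- paste_patch(m, cp$placement, dim(img))
    expect_identical(full, sc$gt$masks[[i]])
  }
})

test_that("an all-background patch may segment to empty", {
  expect_equal(sum(segment_patch(matrix(0, 12, 12))), 0)
  expect_error(segment_patch(matrix(numeric(0), 0, 0)), "empty patch")
})

test_that("contours: single pixel, 3x3 square, and erosion-oracle equality", {
  m1 <- matrix(FALSE, 5, 5); m1[3, 3] <- TRUE
  expect_equal(nrow(mask_to_contour(m1)), 1L)
  m3 <- matrix(FALSE, 7, 7); m3[3:5, 3:5] <- TRUE
  ct3 <- mask_to_contour(m3)
  expect_equal(nrow(ct3), 8L)
  sp3 <- split_border_interior(m3)
  expect_equal(sum(sp3$border), 8)
  expect_equal(sum(sp3$interior), 1)
  set.seed(6)
  for (k in 1:15) {
    blob <- random_blob(36, 36)
    ct <- mask_to_contour(blob)
    expect_false(any(duplicated(ct)))
    # oracle: border = mask minus its 8-neighborhood erosion
    border_idx <- which(blob & !synquant:::erode8(blob))
    contour_idx <- as.integer(ct[, 1] * nrow(blob) + ct[, 2] + 1)
    expect_setequal(contour_idx, border_idx)
    expect_true(all(blob[contour_idx]))  # contour pixels inside the mask
    # consecutive contour pixels are 8-adjacent (ordering is a walk)
    if (nrow(ct) > 3) {
      steps <- pmax(abs(diff(ct[, 1])), abs(diff(ct[, 2])))
      expect_lte(stats::median(steps), 1)
    }
  }
  expect_error(mask_to_contour(matrix(FALSE, 3, 3)), "empty mask")
})

test_that("border/interior is an exact partition; erosion oracle on 5x5 and lines", {
  m5 <- matrix(FALSE, 9, 9); m5[3:7, 3:7] <- TRUE
  sp <- split_border_interior(m5)
  expect_equal(sum(sp$border), 16)
  expect_equal(sum(sp$interior), 9)
  line <- matrix(FALSE, 6, 10); line[3, 2:9] <- TRUE
  spl <- split_border_interior(line)
  expect_equal(sum(spl$border), 8)
  expect_equal(sum(spl$interior), 0)
  set.seed(12)
  for (k in 1:20) {
    blob <- random_blob(30, 30)
    sp <- split_border_interior(blob)
    expect_false(any(sp$border & sp$interior))
    expect_identical(sp$border | sp$interior, blob)
    expect_equal(sum(sp$border) + sum(sp$interior), sum(blob))
  }
})

test_that("assembly resolves overlaps by score and drops emptied instances", {
  shape <- c(30, 30)
  mk <- function(mask) list(mask = mask, placement = list(x0 = 0, y0 = 0,
                                                          height = 30, width = 30))
  a <- matrix(FALSE, 30, 30); a[5:14, 5:14] <- TRUE
  b <- matrix(FALSE, 30, 30); b[20:28, 20:28] <- TRUE
  boxes <- data.frame(x_min = c(4, 19), y_min = c(4, 19), x_max = c(14, 28),
                      y_max = c(14, 28), score = c(0.9, 0.8))
  inst <- assemble_instances(boxes, list(mk(a), mk(b)), shape)
  expect_length(inst, 2)
  expect_identical(inst[[1]]$mask, a)
  expect_identical(inst[[2]]$mask, b)
  # identical masks: all contested pixels to the higher score, loser dropped
  inst2 <- assemble_instances(
    data.frame(x_min = 4, y_min = 4, x_max = 14, y_max = 14,
               score = c(0.9, 0.4)),
    list(mk(a), mk(a)), shape)
  expect_length(inst2, 1)
  expect_equal(inst2[[1]]$score, 0.9)
  expect_identical(inst2[[1]]$mask, a)
})

test_that("random overlapping assemblies keep pixel ownership <= 1", {
  set.seed(44)
  for (k in 1:10) {
    n <- sample(2:5, 1)
    masks <- lapply(seq_len(n), function(i) random_blob(40, 40))
    boxes <- do.call(rbind, lapply(masks, function(m) {
      bb <- as.data.frame(t(mask_bbox(m)))
      bb$score <- round(runif(1), 3)
      bb
    }))
    pm <- lapply(masks, function(m) list(
      mask = m, placement = list(x0 = 0, y0 = 0, height = 40, width = 40)))
    inst <- assemble_instances(boxes, pm, c(40, 40), min_area = 5L)
    if (length(inst) > 0) {
      ownership <- Reduce(`+`, lapply(inst, function(i) i$mask + 0L))
      expect_lte(max(ownership), 1L)
      for (i in inst) {
        expect_gte(sum(i$mask), 5)
        expect_equal(sort(c(i$border, i$interior)), which(i$mask))
      }
    }
  }
})
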