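# Box geometry, Hough voting, grouping, box construction, NMS.

# Rasterize a half-open box on the integer grid and count pixels: the
# IoU reference used throughout.
raster_iou <- function(a, b) {
  lim <- max(a, b) + 2
  g <- function(bx) {
    m <- matrix(FALSE, lim, lim)
    m[(bx[2] + 1):bx[4], (bx[1] + 1):bx[3]] <- TRUE
    m
  }
  sum(g(a) & g(b)) / sum(g(a) | g(b))
}

test_that("box IoU matches identity, disjoint, and rasterized references", {
  expect_equal(box_iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(box_iou(c(0, 0, 10, 10), c(20, 20, 30, 30)), 0)
  expect_equal(box_iou(c(0, 0, 10, 10), c(5, 5, 15, 15)), 25 / 175)
  set.seed(7)
  for (k in 1:50) {
    b <- random_boxes(2L)
    a1 <- as.numeric(b[1, 1:4]); a2 <- as.numeric(b[2, 1:4])
    expect_equal(box_iou(a1, a2), raster_iou(a1, a2))
    expect_equal(box_iou(a1, a2), box_iou(a2, a1))  # symmetry
    expect_gte(box_iou(a1, a2), 0)
    expect_lte(box_iou(a1, a2), 1)
  }
})

test_that("all-zero heatmaps cast no votes; a single peak votes via its offset", {
  maps <- render_keypoint_maps(NULL, shape = c(40, 40), scales = c(8, 16, 32, 64))
  expect_equal(nrow(vote_centers(maps, 1L)), 0L)
  # hand-built single TL peak at (10, 10) with offset (+5, +5)
  maps$heat[[1]][1, 11, 11] <- 1
  maps$offset[[1]][1, 1, 11, 11] <- 5
  maps$offset[[1]][1, 2, 11, 11] <- 5
  v <- vote_centers(maps, 1L)
  expect_equal(nrow(v), 1L)
  expect_equal(v$class, "TL")
  expect_equal(c(v$cx, v$cy), c(15, 15))
})

test_that("maps constructed from a known box vote consistently for its center", {
  b <- data.frame(x_min = 12, y_min = 16, x_max = 44, y_max = 46)
  maps <- render_keypoint_maps(b, shape = c(64, 64), scales = c(16, 32, 64, 128))
  v <- vote_centers(maps, 1L)
  expect_setequal(v$class, c("TL", "TR", "BL", "BR", "C"))
  # all five classes agree on the center within one accumulator cell
  expect_true(all(abs(v$cx - 28) <= 4) && all(abs(v$cy - 31) <= 4))
})

test_that("grouping matches a brute-force transitive distance clustering", {
  v2 <- data.frame(class = c("TL", "BR"), x = c(0, 30), y = c(0, 30),
                   conf = 1, cx = c(15, 15), cy = c(15, 16))
  g <- group_keypoints(v2, cell_size = 8)
  expect_length(g, 1)
  expect_equal(nrow(g[[1]]$members), 2L)
  far <- data.frame(class = c("TL", "BR"), x = 0, y = 0, conf = 1,
                    cx = c(0, 100), cy = c(0, 100))
  expect_length(group_keypoints(far, cell_size = 8), 0)
  # randomized votes vs exhaustive all-pairs clustering
  set.seed(3)
  for (k in 1:20) {
    n <- sample(2:12, 1)
    votes <- data.frame(class = sample(c("TL", "TR", "BL", "BR", "C"), n, TRUE),
                        x = 0, y = 0, conf = runif(n),
                        cx = sample(0:50, n, TRUE), cy = sample(0:50, n, TRUE))
    cs <- sample(4:10, 1)
    # brute force: transitive closure of the pairwise-near relation
    near <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
      max(abs(votes$cx[i] - votes$cx[j]), abs(votes$cy[i] - votes$cy[j])) <= cs))
    reach <- near
    for (r in seq_len(n)) reach <- reach | (reach %*% reach) > 0
    groups <- group_keypoints(votes, cell_size = cs)
    # a component survives iff it spans at least two keypoint classes
    comp_ids <- apply(reach, 1, function(row) min(which(row)))
    surviving <- sapply(split(seq_len(n), comp_ids), function(idx) {
      length(unique(votes$class[idx])) >= 2
    })
    expect_equal(length(groups), sum(surviving))
  }
})

test_that("box construction covers diagonal pairs, 3-point reflection, and failures", {
  mk_group <- function(classes, xs, ys, conf = rep(1, length(classes))) {
    list(members = data.frame(class = classes, x = xs, y = ys, conf = conf,
                              cx = mean(xs), cy = mean(ys)))
  }
  expect_equal(as.numeric(boxes_from_group(
    mk_group(c("TL", "BR"), c(0, 10), c(0, 10)))[1, 1:4]), c(0, 0, 10, 10))
  expect_equal(as.numeric(boxes_from_group(
    mk_group(c("TR", "BL"), c(10, 0), c(0, 10)))[1, 1:4]), c(0, 0, 10, 10))
  b3 <- boxes_from_group(mk_group(c("TL", "TR", "C"), c(0, 10, 5), c(0, 0, 5)))
  expect_equal(as.numeric(b3[1, 1:4]), c(0, 0, 10, 10))
  # brute-force check of the corner constraint system on random boxes
  set.seed(9)
  for (k in 1:20) {
    bx <- random_boxes(1L)[1, 1:4]
    kp <- rbind(TL = c(bx$x_min, bx$y_min), TR = c(bx$x_max, bx$y_min),
                BL = c(bx$x_min, bx$y_max), BR = c(bx$x_max, bx$y_max),
                C = c((bx$x_min + bx$x_max) / 2, (bx$y_min + bx$y_max) / 2))
    picks <- list(c("TL", "BL", "C"), c("TR", "BR", "C"), c("BL", "BR", "C"),
                  c("TL", "TR", "C"), c("TL", "BR"), c("TR", "BL"))
    for (cls in picks) {
      g <- mk_group(cls, kp[cls, 1], kp[cls, 2])
      got <- boxes_from_group(g)
      expect_equal(as.numeric(got[1, 1:4]),
                   as.numeric(bx), label = paste(cls, collapse = "+"))
    }
  }
  # two non-diagonal members -> none; inconsistent geometry -> none
  expect_null(boxes_from_group(mk_group(c("TL", "TR"), c(0, 10), c(0, 0))))
  expect_null(boxes_from_group(mk_group(c("TL", "BR"), c(10, 10), c(0, 0))))
})

test_that("NMS matches an exhaustive reference and is idempotent", {
  one <- data.frame(x_min = 0, y_min = 0, x_max = 5, y_max = 5, score = 0.4)
  expect_equal(nms(one, 0.5), one)
  two <- rbind(one, one)
  two$score <- c(0.9, 0.8)
  expect_equal(nrow(nms(two, 0.5)), 1L)
  expect_equal(nms(two, 0.5)$score, 0.9)
  set.seed(17)
  for (k in 1:10) {
    boxes <- random_boxes(20L)
    boxes$score <- seq(0.95, 0.05, length.out = 20)[sample.int(20)]
    thr <- sample(c(0.3, 0.5, 0.7), 1)
    kept <- nms(boxes, thr)
    # exhaustive O(n^2) reference
    ord <- order(-boxes$score)
    ref_keep <- c()
    for (i in ord) {
      ok <- TRUE
      for (j in ref_keep) {
        if (box_iou(as.numeric(boxes[i, 1:4]), as.numeric(boxes[j, 1:4])) >= thr)
          ok <- FALSE
      }
      if (ok) ref_keep <- c(ref_keep, i)
    }
    expect_equal(kept$score, boxes$score[ref_keep])
    # idempotence, subset, and no kept pair above threshold
    expect_equal(nms(kept, thr), kept)
    if (nrow(kept) > 1) {
      for (i in 1:(nrow(kept) - 1)) for (j in (i + 1):nrow(kept)) {
        expect_lt(box_iou(as.numeric(kept[i, 1:4]), as.numeric(kept[j, 1:4])), thr)
      }
    }
  }
})

test_that("the vote-group-box chain is exact on noiseless constructed maps", {
  set.seed(23)
  for (k in 1:5) {
    n <- sample(2:4, 1)
    boxes <- data.frame(x_min = c(5, 60, 30, 80)[1:n] + sample(0:6, n, TRUE),
                        y_min = c(8, 10, 64, 70)[1:n] + sample(0:6, n, TRUE))
    boxes$x_max <- boxes$x_min + sample(18:30, n, TRUE)
    boxes$y_max <- boxes$y_min + sample(18:30, n, TRUE)
    maps <- render_keypoint_maps(boxes, shape = c(120, 120),
                                 scales = c(12, 24, 48, 96))
    got <- boxes_from_maps(maps)
    expect_equal(nrow(got), n)
    for (i in seq_len(n)) {
      ious <- apply(as.matrix(got[, 1:4]), 1, box_iou, b = as.numeric(boxes[i, 1:4]))
      expect_gte(max(ious), 0.9)
    }
  }
})

test_that("detection on a blank image yields an empty box list", {
  expect_equal(nrow(detect_cells(matrix(0, 40, 40))), 0L)
})
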