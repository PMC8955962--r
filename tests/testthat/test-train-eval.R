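# Splitting, augmentation, matching/AP/IoU metrics, comparison arithmetic.

test_that("split sizes follow floor/floor/remainder and cover the index set", {
  s <- split_dataset(156)
  expect_equal(lengths(s), c(train = 93L, test = 31L, val = 32L))
  s10 <- split_dataset(10)
  expect_equal(lengths(s10), c(train = 6L, test = 2L, val = 2L))
  for (seed in 1:5) {
    n <- sample(6:200, 1)
    sp <- split_dataset(n, seed = seed)
    all_ids <- c(sp$train, sp$test, sp$val)
    expect_equal(sort(all_ids), 1:n)
    expect_equal(anyDuplicated(all_ids), 0L)
  }
  expect_error(split_dataset(3), "too small")
})

test_that("flips are involutions and photometric ops never touch masks", {
  sc <- cached_scene("easy4", easy_params(seed = 1L))
  img <- stack_slice(sc$stack, 1L, sc$gt$focal_z)
  masks <- sc$gt$masks
  f1 <- synquant:::flip_sample(img, masks, horizontal = TRUE)
  f2 <- synquant:::flip_sample(f1$image, f1$masks, horizontal = TRUE)
  expect_identical(f2$image, img)
  expect_identical(f2$masks, masks)
  ph <- synquant:::adjust_sample(img, masks, brightness = 0.05, contrast = 1.2)
  expect_identical(ph$masks, masks)
  expect_false(identical(ph$image, img))
})

test_that("crops map every surviving mask pixel to its pre-image pixel", {
  sc <- cached_scene("easy4", easy_params(seed = 1L))
  img <- stack_slice(sc$stack, 1L, sc$gt$focal_z)
  masks <- sc$gt$masks
  set.seed(2)
  for (k in 1:10) {
    x0 <- sample(0:20, 1); y0 <- sample(0:20, 1)
    wd <- ncol(img) - x0 - sample(0:10, 1)
    ht <- nrow(img) - y0 - sample(0:10, 1)
    cr <- synquant:::crop_sample(img, masks, x0, y0, wd, ht)
    for (j in seq_along(cr$masks)) {
      orig <- masks[[cr$transform$kept[j]]]
      px <- which(cr$masks[[j]], arr.ind = TRUE)
      for (q in seq_len(nrow(px))) {
        expect_true(orig[px[q, 1] + y0, px[q, 2] + x0])
      }
      # and the crop loses no pixel inside the window
      expect_equal(sum(cr$masks[[j]]),
                   sum(orig[(y0 + 1):(y0 + ht), (x0 + 1):(x0 + wd)]))
    }
  }
})

test_that("augmented samples keep geometry aligned between image and masks", {
  sc <- cached_scene("easy4", easy_params(seed = 1L))
  masks <- sc$gt$masks
  indicator <- Reduce(`|`, masks) * 1000
  for (seed in 1:6) {
    aug <- augment_sample(indicator, masks, ops = c("expand", "crop", "flip"),
                          seed = seed)
    expect_true(length(aug$masks) >= 1)
    union_aug <- Reduce(`|`, aug$masks)
    expect_identical(aug$image > 500, union_aug)
    expect_true(all(vapply(aug$masks, is.logical, TRUE)))
  }
})

test_that("mask IoU matches pixel-count brute force", {
  a <- random_blob(20, 20, r = 6)
  expect_equal(mask_iou(a, a), 1)
  b <- matrix(FALSE, 20, 20); b[1:2, 1:2] <- TRUE
  expect_equal(mask_iou(a & !a, b & !b), 0)
  set.seed(8)
  for (k in 1:25) {
    a <- random_blob(24, 24); b <- random_blob(24, 24)
    inter <- 0; uni <- 0
    for (i in seq_along(a)) {
      if (a[i] && b[i]) inter <- inter + 1
      if (a[i] || b[i]) uni <- uni + 1
    }
    expect_equal(mask_iou(a, b), if (uni == 0) 0 else inter / uni)
  }
  expect_error(mask_iou(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)), "shapes differ")
})

ann_set <- function(boxes, masks = NULL) list(boxes = boxes, masks = masks)

test_that("greedy matching: perfect predictions, misses, and tie-breaks", {
  gt <- random_boxes(3L)[, 1:4]
  preds <- ann_set(cbind(gt, score = c(0.9, 0.8, 0.7)))
  m <- match_predictions(preds, ann_set(gt), 0.5, "box")
  expect_true(all(m$tp))
  expect_equal(attr(m, "fn"), 0L)
  none <- ann_set(data.frame(x_min = numeric(), y_min = numeric(),
                             x_max = numeric(), y_max = numeric(),
                             score = numeric()))
  m0 <- match_predictions(none, ann_set(gt), 0.5, "box")
  expect_equal(nrow(m0), 0L)
  expect_equal(attr(m0, "fn"), 3L)
  # crafted 3-pred / 2-gt case against exhaustive greedy enumeration
  gts <- data.frame(x_min = c(0, 20), y_min = c(0, 0),
                    x_max = c(10, 30), y_max = c(10, 10))
  prd <- data.frame(x_min = c(1, 21, 40), y_min = c(1, 0, 40),
                    x_max = c(11, 31, 50), y_max = c(11, 10, 50),
                    score = c(0.95, 0.9, 0.85))
  mm <- match_predictions(ann_set(prd), ann_set(gts), 0.5, "box")
  expect_equal(mm$tp, c(TRUE, TRUE, FALSE))
  expect_equal(mm$gt[1:2], c(1L, 2L))
})

test_that("AP reproduces hand-enumerated PR curves and edge cases", {
  gt <- data.frame(x_min = c(0, 20), y_min = 0, x_max = c(10, 30), y_max = 10)
  perfect <- ann_set(cbind(gt, score = c(0.9, 0.8)))
  expect_equal(average_precision(perfect, ann_set(gt), 0.5, "box"), 100)
  none <- ann_set(empty_pred <- data.frame(x_min = numeric(), y_min = numeric(),
                                           x_max = numeric(), y_max = numeric(),
                                           score = numeric()))
  expect_equal(average_precision(none, ann_set(gt), 0.5, "box"), 0)
  expect_warning(ap_nog <- average_precision(perfect, ann_set(gt[0, ]), 0.5, "box"),
                 "without ground truth")
  expect_true(is.na(ap_nog))
  # ranked (TP, FP, TP): all-point area = 0.5 * 1 + 0.5 * 2/3
  preds <- ann_set(data.frame(
    x_min = c(0, 50, 20), y_min = c(0, 50, 0),
    x_max = c(10, 60, 30), y_max = c(10, 60, 10),
    score = c(0.9, 0.8, 0.7)))
  expect_equal(average_precision(preds, ann_set(gt), 0.5, "box"),
               100 * (0.5 + 0.5 * 2 / 3), tolerance = 1e-9)
})

test_that("AP is monotone under added false positives and bounded in [0, 100]", {
  set.seed(14)
  gt <- random_boxes(4L)[, 1:4]
  preds <- cbind(gt, score = runif(4, 0.5, 1))
  base <- average_precision(ann_set(preds), ann_set(gt), 0.5, "box")
  worse <- rbind(preds, data.frame(x_min = 200, y_min = 200, x_max = 220,
                                   y_max = 220, score = 0.99))
  withfp <- average_precision(ann_set(worse), ann_set(gt), 0.5, "box")
  expect_lte(withfp, base)
  expect_gte(withfp, 0)
  expect_lte(base, 100)
})

test_that("matched IoU means respect the threshold gate", {
  a <- matrix(FALSE, 20, 20); a[2:11, 2:11] <- TRUE   # 100 px
  b <- matrix(FALSE, 20, 20); b[2:11, 2:9] <- TRUE    # 80 px inside a
  gts <- ann_set(as.data.frame(t(mask_bbox(a))), list(a))
  preds <- ann_set(cbind(as.data.frame(t(mask_bbox(b))), score = 1), list(b))
  expect_equal(mean_matched_iou(preds, gts, 0.5), 80)
  expect_warning(v <- mean_matched_iou(preds, gts, 0.9), "no matched pairs")
  expect_equal(v, 0)
  perfect <- ann_set(cbind(as.data.frame(t(mask_bbox(a))), score = 1), list(a))
  expect_equal(mean_matched_iou(perfect, gts, 0.7), 100)
})

test_that("comparison arithmetic: self-comparison, missing cells, bundled table", {
  tab <- method_table()
  self <- compare_methods(tab, "DCAN", "DCAN", method_cells("bbox"))
  expect_true(all(self$deltas$delta == 0))
  expect_equal(self$average, 0)
  expect_error(compare_methods(tab, "InstSeg", "DCAN", "bbox:AP@0.9:100"),
               "AP@0.9")
  expect_error(compare_methods(tab, "InstSeg", "NoSuch", "bbox:AP@0.5:100"),
               "NoSuch")
})
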