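# Dataset splitting, augmentation, and accuracy analysis: box/mask AP,
# matched IoU, and method-comparison arithmetic on printed score tables.

#' Split a dataset into train / test / validation indices
#'
#' Sizes are `floor(f1 * n)`, `floor(f2 * n)` and the remainder, after a
#' seeded shuffle: a 156-image corpus under the default 60/20/20
#' fractions yields 93 / 31 / 32.
#'
#' @param n number of items.
#' @param fractions length-3 fractions summing to 1 (train, test, val).
#' @param seed shuffle seed.
#' @return list of integer index vectors `train`, `test`, `val`
#'   (disjoint, covering `1..n`).
#' @export
split_dataset <- function(n, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  n <- as.integer(n)
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-9)
  n_train <- floor(fractions[1L] * n)
  n_test <- floor(fractions[2L] * n)
  n_val <- n - n_train - n_test
  if (n_train < 1L || n_test < 1L || n_val < 1L)
    sq_stop("n = %d too small for non-empty %s splits", n,
            paste(fractions, collapse = "/"))
  perm <- with_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[n_train + seq_len(n_test)]),
       val = sort(perm[n_train + n_test + seq_len(n_val)]))
}

# ---- augmentation ----------------------------------------------------------

# Pure geometric/photometric transforms of one (image, masks) sample.
# Geometric ops transform image and masks identically and record the
# coordinate map; photometric ops touch the image only.

flip_sample <- function(image, masks, horizontal = TRUE) {
  fl <- function(m) if (horizontal) m[, rev(seq_len(ncol(m))), drop = FALSE]
                    else m[rev(seq_len(nrow(m))), , drop = FALSE]
  list(image = fl(image), masks = lapply(masks, fl),
       transform = list(op = "flip", horizontal = horizontal))
}

crop_sample <- function(image, masks, x0, y0, width, height) {
  H <- nrow(image); W <- ncol(image)
  stopifnot(x0 >= 0, y0 >= 0, x0 + width <= W, y0 + height <= H,
            width >= 1, height >= 1)
  cr <- function(m) m[(y0 + 1):(y0 + height), (x0 + 1):(x0 + width),
                      drop = FALSE]
  masks <- lapply(masks, cr)
  keep <- vapply(masks, function(m) any(m), TRUE)
  list(image = cr(image), masks = masks[keep],
       transform = list(op = "crop", x0 = x0, y0 = y0,
                        width = width, height = height, kept = which(keep)))
}

expand_sample <- function(image, masks, pad, fill = 0) {
  H <- nrow(image); W <- ncol(image)
  big <- matrix(fill, H + 2L * pad, W + 2L * pad)
  big[pad + seq_len(H), pad + seq_len(W)] <- image
  grow <- function(m) {
    bm <- matrix(FALSE, H + 2L * pad, W + 2L * pad)
    bm[pad + seq_len(H), pad + seq_len(W)] <- m
    bm
  }
  list(image = big, masks = lapply(masks, grow),
       transform = list(op = "expand", pad = pad))
}

adjust_sample <- function(image, masks, brightness = 0, contrast = 1,
                          full_scale = 65535) {
  img <- (image - mean(image)) * contrast + mean(image) + brightness * full_scale
  img <- pmin(pmax(img, 0), full_scale)
  list(image = img, masks = masks,
       transform = list(op = "photometric", brightness = brightness,
                        contrast = contrast))
}

#' Randomly augment one training sample
#'
#' Applies a random subset of the configured operations: random
#' expansion, cropping, flipping, contrast distortion and brightness
#' distortion. Geometric operations transform masks identically to the
#' image; photometric operations leave masks untouched. A crop that
#' would eliminate every instance is resampled up to `k` times, after
#' which the sample is returned unaugmented (with a message).
#'
#' @param image numeric matrix.
#' @param masks list of logical matrices.
#' @param ops subset of `c("expand", "crop", "flip", "contrast",
#'   "brightness")`.
#' @param seed integer seed for the augmentation draw.
#' @param full_scale gray-value full scale for photometric clamping.
#' @param k crop retry budget (default 5).
#' @return list with `image`, `masks`, and `transforms` (the applied
#'   operation records, in order).
#' @export
augment_sample <- function(image, masks,
                           ops = c("expand", "crop", "flip", "contrast",
                                   "brightness"),
                           seed = 1L, full_scale = 65535, k = 5L) {
  ops <- match.arg(ops, several.ok = TRUE)
  with_seed(seed, {
    cur <- list(image = image, masks = masks)
    transforms <- list()
    push <- function(res) {
      cur$image <<- res$image
      cur$masks <<- res$masks
      transforms[[length(transforms) + 1L]] <<- res$transform
    }
    if ("expand" %in% ops && runif(1) < 0.5) {
      pad <- sample(4:16, 1)
      push(expand_sample(cur$image, cur$masks, pad,
                         fill = stats::median(cur$image)))
    }
    if ("crop" %in% ops && runif(1) < 0.5 && length(cur$masks)) {
      H <- nrow(cur$image); W <- ncol(cur$image)
      done <- FALSE
      for (tr in seq_len(k)) {
        fw <- runif(1, 0.6, 0.95); fh <- runif(1, 0.6, 0.95)
        width <- max(8L, floor(W * fw)); height <- max(8L, floor(H * fh))
        x0 <- sample.int(W - width + 1L, 1) - 1L
        y0 <- sample.int(H - height + 1L, 1) - 1L
        res <- crop_sample(cur$image, cur$masks, x0, y0, width, height)
        if (length(res$masks)) { push(res); done <- TRUE; break }
      }
      if (!done) message("augment: crop retries exhausted, sample left uncropped")
    }
    if ("flip" %in% ops && runif(1) < 0.5) {
      push(flip_sample(cur$image, cur$masks, horizontal = runif(1) < 0.5))
    }
    if ("contrast" %in% ops && runif(1) < 0.5) {
      push(adjust_sample(cur$image, cur$masks,
                         contrast = runif(1, 0.7, 1.3),
                         full_scale = full_scale))
    }
    if ("brightness" %in% ops && runif(1) < 0.5) {
      push(adjust_sample(cur$image, cur$masks,
                         brightness = runif(1, -0.08, 0.08),
                         full_scale = full_scale))
    }
    list(image = cur$image, masks = cur$masks, transforms = transforms)
  })
}

# ---- metrics ---------------------------------------------------------------

#' Intersection-over-union of two masks
#'
#' @param a,b logical matrices in the same frame.
#' @return `|a & b| / |a | b|`; 0 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    sq_stop("mask shapes differ: %s vs %s",
            paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

# Pairwise pred x gt IoU matrix at the requested level. preds/gts are
# annotation sets: list(boxes = data.frame, masks = list or NULL).
iou_matrix <- function(preds, gts, level) {
  np <- nrow(preds$boxes); ng <- nrow(gts$boxes)
  m <- matrix(0, np, ng)
  if (np == 0L || ng == 0L) return(m)
  if (level == "box") {
    pb <- as.matrix(preds$boxes[, c("x_min", "y_min", "x_max", "y_max")])
    gb <- as.matrix(gts$boxes[, c("x_min", "y_min", "x_max", "y_max")])
    for (i in seq_len(np)) for (j in seq_len(ng)) {
      m[i, j] <- box_iou(pb[i, ], gb[j, ])
    }
  } else {
    for (i in seq_len(np)) for (j in seq_len(ng)) {
      m[i, j] <- mask_iou(preds$masks[[i]], gts$masks[[j]])
    }
  }
  m
}

#' Greedily match predictions to ground truth
#'
#' Predictions are visited in descending score order; each is matched to
#' the not-yet-matched ground truth of highest IoU provided that IoU
#' reaches the threshold (ties break to the lower ground-truth index).
#'
#' @param preds annotation set: `list(boxes, masks)`, `boxes` a
#'   data.frame with a `score` column, `masks` a list (mask level only).
#' @param gts annotation set for the ground truth.
#' @param iou_threshold match threshold.
#' @param level `"box"` or `"mask"`.
#' @return data.frame with one row per prediction (descending score):
#'   `pred`, `gt` (NA for false positives), `iou`, `tp`; the number of
#'   false negatives is in `attr(, "fn")`.
#' @export
match_predictions <- function(preds, gts, iou_threshold, level = c("box", "mask")) {
  level <- match.arg(level)
  np <- nrow(preds$boxes); ng <- nrow(gts$boxes)
  iou <- iou_matrix(preds, gts, level)
  ord <- order(-preds$boxes$score)
  gt_used <- logical(ng)
  rows <- lapply(ord, function(i) {
    best <- NA_integer_; best_iou <- 0
    for (j in seq_len(ng)) {
      if (!gt_used[j] && iou[i, j] >= iou_threshold && iou[i, j] > best_iou) {
        best <- j; best_iou <- iou[i, j]
      }
    }
    if (!is.na(best)) gt_used[best] <<- TRUE
    data.frame(pred = i, gt = best, iou = if (is.na(best)) 0 else best_iou,
               tp = !is.na(best))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pred = integer(), gt = integer(), iou = numeric(),
               tp = logical())
  attr(out, "fn") <- sum(!gt_used)
  out
}

#' Average precision at one IoU threshold
#'
#' Area under the all-point-interpolated precision-recall curve built
#' from the greedy match labels, as a percentage.
#'
#' @inheritParams match_predictions
#' @return AP in `[0, 100]`; `NA` (with a warning) when there is no
#'   ground truth to recall.
#' @export
average_precision <- function(preds, gts, iou_threshold, level = c("box", "mask")) {
  level <- match.arg(level)
  ng <- nrow(gts$boxes)
  if (ng == 0L) {
    warning("average precision undefined without ground truth")
    return(NA_real_)
  }
  if (nrow(preds$boxes) == 0L) return(0)
  m <- match_predictions(preds, gts, iou_threshold, level)
  tp <- cumsum(m$tp)
  fp <- cumsum(!m$tp)
  precision <- tp / (tp + fp)
  recall <- tp / ng
  # all-point interpolation: precision envelope from the right
  env <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  100 * sum((recall - r_prev) * env)
}

#' Mean IoU over matched pairs at one threshold
#'
#' The mask-level companion of AP: the mean IoU of true-positive
#' matches, as a percentage; 0 (with a warning) when nothing matches.
#'
#' @inheritParams match_predictions
#' @return percentage in `[0, 100]`.
#' @export
mean_matched_iou <- function(preds, gts, iou_threshold, level = "mask") {
  m <- match_predictions(preds, gts, iou_threshold, level)
  if (!any(m$tp)) {
    warning("no matched pairs at IoU threshold ", iou_threshold)
    return(0)
  }
  100 * mean(m$iou[m$tp])
}

#' Evaluate predicted instances against ground-truth masks
#'
#' Computes box AP, mask AP and matched mask IoU at every configured
#' threshold.
#'
#' @param instances list of `cell_instance` predictions.
#' @param gt_masks list of ground-truth logical masks.
#' @param thresholds IoU thresholds (default `c(0.5, 0.7)`).
#' @return object of class `eval_result`: data.frame with `metric`,
#'   `threshold`, `value` (percent).
#' @export
evaluate_instances <- function(instances, gt_masks, thresholds = c(0.5, 0.7)) {
  stopifnot(all(thresholds > 0 & thresholds < 1))
  preds <- list(
    boxes = if (length(instances)) {
      cbind(as.data.frame(do.call(rbind, lapply(instances, `[[`, "box"))),
            score = vapply(instances, `[[`, 0, "score"))
    } else {
      empty_boxes()
    },
    masks = lapply(instances, `[[`, "mask"))
  gts <- list(
    boxes = if (length(gt_masks)) {
      as.data.frame(do.call(rbind, lapply(gt_masks, mask_bbox)))
    } else {
      empty_boxes()[, 1:4]
    },
    masks = gt_masks)
  rows <- list()
  for (t in thresholds) {
    rows[[length(rows) + 1L]] <- data.frame(
      metric = c("box_ap", "mask_ap", "mask_iou"), threshold = t,
      value = c(average_precision(preds, gts, t, "box"),
                average_precision(preds, gts, t, "mask"),
                mean_matched_iou(preds, gts, t)))
  }
  structure(do.call(rbind, rows), class = c("eval_result", "data.frame"))
}

#' @export
print.eval_result <- function(x, ...) {
  cat("<eval_result>\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %s@%.1f = %.2f%%\n", x$metric[i], x$threshold[i], x$value[i]))
  }
  invisible(x)
}

# ---- method-comparison arithmetic ------------------------------------------

#' Published method-comparison table
#'
#' The printed box- and mask-level AP/IoU percentages of the compared
#' architectures (the multi-scale instance-segmentation model, DCAN,
#' CosineEmbedding, Mask R-CNN) at 50/75/100% of the training data,
#' consumed as data by [compare_methods()].
#'
#' @return data.frame with columns `section, method, fraction, metric,
#'   value`.
#' @export
method_table <- function() {
  path <- system.file("extdata", "method_comparison.csv", package = "synquant")
  if (path == "") path <- file.path("inst", "extdata", "method_comparison.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Cell keys are "section:metric:fraction", e.g. "bbox:AP@0.5:100".
parse_cells <- function(cells) {
  parts <- strsplit(cells, ":", fixed = TRUE)
  bad <- vapply(parts, length, 0L) != 3L
  if (any(bad)) sq_stop("malformed cell key: %s", cells[bad][1L])
  data.frame(section = vapply(parts, `[[`, "", 1L),
             metric = vapply(parts, `[[`, "", 2L),
             fraction = as.numeric(vapply(parts, `[[`, "", 3L)))
}

#' Build cell keys for a block of the method table
#'
#' @param section `"bbox"` or `"segmentation"`.
#' @param metrics metric names, e.g. `c("AP@0.5", "AP@0.7")`.
#' @param fractions data fractions, e.g. `c(50, 75, 100)`.
#' @return character vector of `section:metric:fraction` keys.
#' @export
method_cells <- function(section, metrics = c("AP@0.5", "AP@0.7"),
                         fractions = c(50, 75, 100)) {
  grid <- expand.grid(fraction = fractions, metric = metrics,
                      stringsAsFactors = FALSE)
  sprintf("%s:%s:%g", section, grid$metric, grid$fraction)
}

#' Pairwise method comparison over selected table cells
#'
#' For each selected cell computes `a - b`, and the arithmetic mean over
#' the selection; both rounded half-up to 2 decimals (reproducing the
#' printed pairwise deltas and scenario averages).
#'
#' @param table a [method_table()]-shaped data.frame.
#' @param method_a,method_b method names present in the table.
#' @param cells character vector of `section:metric:fraction` keys.
#' @return list with `deltas` (data.frame per cell) and `average`.
#' @export
compare_methods <- function(table, method_a, method_b, cells) {
  sel <- parse_cells(cells)
  lookup <- function(method, s, met, fr) {
    v <- table$value[table$section == s & table$method == method &
                       table$metric == met & table$fraction == fr]
    if (length(v) != 1L)
      sq_stop("cell %s:%s:%g missing for method %s", s, met, fr, method)
    v
  }
  a <- mapply(lookup, method_a, sel$section, sel$metric, sel$fraction)
  b <- mapply(lookup, method_b, sel$section, sel$metric, sel$fraction)
  deltas <- data.frame(cell = cells, a = a, b = b,
                       delta = round_half_up(a - b, 2))
  rownames(deltas) <- NULL
  list(deltas = deltas, average = round_half_up(mean(deltas$delta), 2))
}
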