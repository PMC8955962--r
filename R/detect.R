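# Bounding-box generation: keypoint heatmaps + offset maps -> multi-scale
# Hough voting -> keypoint groups -> box construction -> NMS.
#
# Boxes are half-open, 0-based: [x_min, x_max) x [y_min, y_max); pixel
# (x, y) lives at matrix position [y + 1, x + 1]. Five keypoint classes
# describe a box: its four corners and its center.

KP_CLASSES <- c("TL", "TR", "BL", "BR", "C")
DEFAULT_SCALES <- c(16, 32, 64, 128)

#' Intersection-over-union of two boxes
#'
#' Boxes are half-open `[x_min, x_max) x [y_min, y_max)`, so areas are
#' exact products of side lengths.
#'
#' @param a,b numeric vectors `c(x_min, y_min, x_max, y_max)`.
#' @return IoU ratio in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  stopifnot(a[3] > a[1], a[4] > a[2], b[3] > b[1], b[4] > b[2])
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

empty_boxes <- function() {
  data.frame(x_min = numeric(), y_min = numeric(), x_max = numeric(),
             y_max = numeric(), score = numeric())
}

#' Greedy non-maximum suppression
#'
#' Standard greedy NMS: iterate boxes by descending score, keep a box if
#' its IoU with every already-kept box is below `iou_threshold`, suppress
#' it otherwise. Idempotent; output is a subset of the input rows.
#'
#' @param boxes data.frame with columns `x_min, y_min, x_max, y_max, score`.
#' @param iou_threshold boxes with IoU >= this to a kept box are suppressed.
#' @return the kept rows, in descending score order.
#' @export
nms <- function(boxes, iou_threshold = 0.5) {
  if (is.null(boxes) || nrow(boxes) == 0L) return(empty_boxes())
  ord <- order(-boxes$score)
  boxes <- boxes[ord, , drop = FALSE]
  m <- as.matrix(boxes[, c("x_min", "y_min", "x_max", "y_max")])
  keep <- logical(nrow(boxes))
  for (i in seq_len(nrow(boxes))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (box_iou(m[i, ], m[j, ]) >= iou_threshold) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  out <- boxes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- keypoint maps ---------------------------------------------------------

# Keypoint positions of one box, in pixel coordinates.
box_keypoints <- function(b) {
  rbind(TL = c(b[1], b[2]), TR = c(b[3], b[2]),
        BL = c(b[1], b[4]), BR = c(b[3], b[4]),
        C = c((b[1] + b[3]) / 2, (b[2] + b[4]) / 2))
}

# Assign each box to the scale whose disk radius best matches half its
# longer side.
assign_scale <- function(boxes, scales) {
  half <- pmax(boxes$x_max - boxes$x_min, boxes$y_max - boxes$y_min) / 2
  vapply(half, function(h) which.min(abs(scales - h)), 0L)
}

#' Render keypoint heatmaps and offset maps from boxes
#'
#' Builds the supervision/inference targets of the detection head: for
#' each scale, five heatmaps (Gaussian peaks inside a disk of the scale
#' radius around each keypoint of every box assigned to that scale) and
#' per-class two-channel offset maps holding the displacement from each
#' pixel to the box center. This is both the ground-truth encoder for
#' training and the bridge from predicted objects to Hough voting.
#'
#' @param boxes data.frame `x_min, y_min, x_max, y_max` and optional
#'   `score` (peak heat amplitude, default 1).
#' @param shape `c(height, width)` of the image frame.
#' @param scales disk radii of the detection scales (strictly increasing).
#' @return object of class `keypoint_maps`: list with `scales`, `shape`,
#'   `heat` (per scale, array `[5, H, W]` in `[0, 1]`) and `offset` (per
#'   scale, array `[5, 2, H, W]`, channels = horizontal, vertical).
#' @export
render_keypoint_maps <- function(boxes, shape, scales = DEFAULT_SCALES) {
  stopifnot(length(scales) >= 1L, all(diff(scales) > 0), all(scales > 0))
  H <- shape[1L]; W <- shape[2L]
  heat <- lapply(scales, function(s) array(0, dim = c(5L, H, W)))
  offs <- lapply(scales, function(s) array(0, dim = c(5L, 2L, H, W)))
  if (!is.null(boxes) && nrow(boxes) > 0L) {
    conf <- if ("score" %in% names(boxes)) boxes$score else rep(1, nrow(boxes))
    si <- assign_scale(boxes, scales)
    for (i in seq_len(nrow(boxes))) {
      b <- as.numeric(boxes[i, c("x_min", "y_min", "x_max", "y_max")])
      kps <- box_keypoints(b)
      cen <- kps["C", ]
      s <- scales[si[i]]
      sigma <- max(1.5, s / 6)
      for (k in seq_len(5L)) {
        kp <- kps[k, ]
        xs <- max(0, floor(kp[1] - s)):min(W - 1, ceiling(kp[1] + s))
        ys <- max(0, floor(kp[2] - s)):min(H - 1, ceiling(kp[2] + s))
        if (!length(xs) || !length(ys)) next
        dx <- matrix(rep(xs - kp[1], each = length(ys)), length(ys))
        dy <- matrix(rep(ys - kp[2], times = length(xs)), length(ys))
        d2 <- dx^2 + dy^2
        g <- conf[i] * exp(-d2 / (2 * sigma^2))
        g[d2 > s^2] <- 0
        sub <- heat[[si[i]]][k, ys + 1, xs + 1]
        upd <- g > sub
        if (any(upd)) {
          sub[upd] <- g[upd]
          heat[[si[i]]][k, ys + 1, xs + 1] <- sub
          ox <- offs[[si[i]]][k, 1L, ys + 1, xs + 1]
          oy <- offs[[si[i]]][k, 2L, ys + 1, xs + 1]
          px <- matrix(rep(xs, each = length(ys)), length(ys))
          py <- matrix(rep(ys, times = length(xs)), length(ys))
          ox[upd] <- (cen[1] - px)[upd]
          oy[upd] <- (cen[2] - py)[upd]
          offs[[si[i]]][k, 1L, ys + 1, xs + 1] <- ox
          offs[[si[i]]][k, 2L, ys + 1, xs + 1] <- oy
        }
      }
    }
  }
  structure(list(scales = scales, shape = c(H, W), heat = heat,
                 offset = offs), class = "keypoint_maps")
}

# 3x3 neighborhood maximum of a matrix (replicated borders).
maxfilter3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  shift <- function(dr, dc) {
    rs <- pmin(pmax(seq_len(h) + dr, 1L), h)
    cs <- pmin(pmax(seq_len(w) + dc, 1L), w)
    m[rs, cs, drop = FALSE]
  }
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr || dc) out <- pmax(out, shift(dr, dc))
  }
  out
}

#' Extract keypoint votes for object centers at one scale
#'
#' Local maxima (3x3 neighborhood) of each keypoint heatmap above
#' `heat_threshold` each cast a vote for their object's center at
#' position + offset.
#'
#' @param maps a [render_keypoint_maps()] object (or model output).
#' @param scale_index which scale to read (1-based).
#' @param heat_threshold minimum heat for a local maximum to vote.
#' @return data.frame `class, x, y, conf, cx, cy` (positions and voted
#'   centers in pixel coordinates); zero rows if nothing votes.
#' @export
vote_centers <- function(maps, scale_index, heat_threshold = 0.1) {
  stopifnot(inherits(maps, "keypoint_maps"),
            scale_index >= 1L, scale_index <= length(maps$scales))
  H <- maps$shape[1L]; W <- maps$shape[2L]
  out <- list()
  for (k in seq_len(5L)) {
    hm <- matrix(maps$heat[[scale_index]][k, , ], H, W)
    mx <- maxfilter3(hm)
    is_peak <- hm >= heat_threshold & hm >= mx
    idx <- which(is_peak, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    x <- idx[, 2L] - 1L
    y <- idx[, 1L] - 1L
    ox <- maps$offset[[scale_index]][k, 1L, , ][idx]
    oy <- maps$offset[[scale_index]][k, 2L, , ][idx]
    out[[k]] <- data.frame(class = KP_CLASSES[k], x = x, y = y,
                           conf = hm[idx], cx = x + ox, cy = y + oy)
  }
  if (!length(out)) {
    return(data.frame(class = character(), x = numeric(), y = numeric(),
                      conf = numeric(), cx = numeric(), cy = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group center votes into keypoint groups
#'
#' Votes whose voted centers agree at the accumulator-cell granularity
#' (Chebyshev distance <= `cell_size`, transitively linked) form one
#' group. Within a group only the highest-confidence vote of each
#' keypoint class is retained; groups with fewer than 2 members are
#' discarded.
#'
#' @param votes data.frame from [vote_centers()].
#' @param cell_size accumulator cell size in pixels.
#' @return list of groups, each `list(members, voted_center)`.
#' @export
group_keypoints <- function(votes, cell_size) {
  if (is.null(votes) || nrow(votes) == 0L) return(list())
  n <- nrow(votes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (max(abs(votes$cx[i] - votes$cx[j]),
            abs(votes$cy[i] - votes$cy[j])) <= cell_size) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  groups <- list()
  for (r in unique(roots)) {
    mem <- votes[roots == r, , drop = FALSE]
    # one vote per class: keep the most confident
    mem <- mem[order(-mem$conf), , drop = FALSE]
    mem <- mem[!duplicated(mem$class), , drop = FALSE]
    if (nrow(mem) < 2L) next
    groups[[length(groups) + 1L]] <-
      list(members = mem, voted_center = c(mean(mem$cx), mean(mem$cy)))
  }
  groups
}

#' Construct a bounding box from one keypoint group
#'
#' A diagonal corner pair (TL+BR, else TR+BL) spans the box directly.
#' Otherwise a group of >= 3 members is solved by letting each present
#' corner fix its own coordinates and reflecting known corners through
#' the center C to impute the missing diagonal; coordinate estimates
#' from real corners take precedence over imputed ones. The box score is
#' the mean confidence of the contributing keypoints. Geometrically
#' inconsistent groups yield `NULL`.
#'
#' @param group one element of [group_keypoints()] output.
#' @return one-row data.frame `x_min, y_min, x_max, y_max, score`, or
#'   `NULL`.
#' @export
boxes_from_group <- function(group) {
  mem <- group$members
  get <- function(cls) {
    i <- match(cls, mem$class)
    if (is.na(i)) NULL else c(mem$x[i], mem$y[i])
  }
  tl <- get("TL"); tr <- get("TR"); bl <- get("BL"); br <- get("BR")
  ce <- get("C")
  score <- mean(mem$conf)
  mk <- function(x1, y1, x2, y2) {
    if (!is.finite(x1) || !is.finite(x2) || !is.finite(y1) || !is.finite(y2) ||
        x1 >= x2 || y1 >= y2) {
      return(NULL)
    }
    data.frame(x_min = x1, y_min = y1, x_max = x2, y_max = y2, score = score)
  }
  if (!is.null(tl) && !is.null(br)) return(mk(tl[1], tl[2], br[1], br[2]))
  if (!is.null(tr) && !is.null(bl)) return(mk(bl[1], tr[2], tr[1], bl[2]))
  if (nrow(mem) < 3L || is.null(ce)) return(NULL)
  # estimates: real corner coordinates first, else reflections through C
  refl <- function(p) if (is.null(p)) NULL else 2 * ce - p
  est <- function(real, imputed) {
    real <- unlist(real); imputed <- unlist(imputed)
    if (length(real)) mean(real) else if (length(imputed)) mean(imputed) else NA_real_
  }
  x_min <- est(list(tl[1], bl[1]), list(refl(tr)[1], refl(br)[1]))
  x_max <- est(list(tr[1], br[1]), list(refl(tl)[1], refl(bl)[1]))
  y_min <- est(list(tl[2], tr[2]), list(refl(bl)[2], refl(br)[2]))
  y_max <- est(list(bl[2], br[2]), list(refl(tl)[2], refl(tr)[2]))
  mk(x_min, y_min, x_max, y_max)
}

#' Full Hough-voting chain: keypoint maps to boxes
#'
#' Runs vote extraction, center grouping and box construction at every
#' scale, merges the per-scale candidates and applies NMS.
#'
#' @param maps a `keypoint_maps` object.
#' @param heat_threshold local-maximum threshold (default 0.1).
#' @param nms_iou NMS IoU threshold (default 0.5).
#' @param cell_frac accumulator cell size as a fraction of the scale
#'   radius (default 1/4).
#' @return data.frame of boxes with scores, NMS-filtered.
#' @export
boxes_from_maps <- function(maps, heat_threshold = 0.1, nms_iou = 0.5,
                            cell_frac = 0.25) {
  cand <- list()
  for (si in seq_along(maps$scales)) {
    votes <- vote_centers(maps, si, heat_threshold)
    groups <- group_keypoints(votes, cell_size = maps$scales[si] * cell_frac)
    for (g in groups) {
      b <- boxes_from_group(g)
      if (!is.null(b)) cand[[length(cand) + 1L]] <- b
    }
  }
  if (!length(cand)) return(empty_boxes())
  nms(do.call(rbind, cand), nms_iou)
}
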