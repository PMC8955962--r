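# Patch-wise instance segmentation and mask decomposition.
#
# Segmentation operates on patches cut around detected boxes (plus a
# context margin) so neighboring cells do not interfere. Two paths share
# one contract: the learned per-pixel classifier (see fit_synapse_model)
# and a deterministic threshold-oracle path (Otsu + largest component)
# that is exact on noiseless synthetic data and serves as a CPU-cheap
# reference for end-to-end testing.

#' Otsu threshold of a grayscale image
#'
#' Maximizes between-class variance over a 256-bin histogram.
#'
#' @param img numeric matrix or vector.
#' @return threshold value; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(img) {
  v <- as.numeric(img)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  brk <- seq(lo, hi, length.out = 257L)
  h <- tabulate(findInterval(v, brk, rightmost.closed = TRUE), 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (brk[-1L] + brk[-257L]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[256L]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  brk[which.max(sigma_b) + 1L]
}

# Connected-component labelling, 8-connectivity, BFS per seed.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  fg <- which(mask)
  if (!length(fg)) return(lab)
  cur <- 0L
  for (seed in fg) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    frontier <- seed
    lab[seed] <- cur
    while (length(frontier)) {
      r0 <- (frontier - 1L) %% h + 1L
      c0 <- (frontier - 1L) %/% h + 1L
      nb <- integer(0)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        r <- r0 + dr; cc <- c0 + dc
        ok <- r >= 1L & r <= h & cc >= 1L & cc <= w
        if (any(ok)) nb <- c(nb, (cc[ok] - 1L) * h + r[ok])
      }
      nb <- unique(nb)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab
}

# Largest connected component of a mask (empty in, empty out).
largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}

# 8-neighborhood erosion with FALSE padding (image edge counts as outside).
erode8 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  out <- matrix(TRUE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    out <- out & pad[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc]
  }
  out
}

#' Crop a patch around a box with a context margin
#'
#' @param image numeric matrix (one channel, one slice).
#' @param box numeric `c(x_min, y_min, x_max, y_max)`, half-open 0-based.
#' @param margin context margin in pixels (default 8).
#' @return list with `patch` (matrix) and `placement` (`x0`, `y0` 0-based
#'   offsets of the patch in the image frame) allowing exact paste-back.
#' @export
crop_patch <- function(image, box, margin = 8L) {
  H <- nrow(image); W <- ncol(image)
  x0 <- max(0, floor(box[1]) - margin)
  y0 <- max(0, floor(box[2]) - margin)
  x1 <- min(W, ceiling(box[3]) + margin)
  y1 <- min(H, ceiling(box[4]) + margin)
  if (x1 <= x0 || y1 <= y0)
    sq_stop("box [%s) does not intersect a %dx%d image",
            paste(round(box, 1), collapse = ","), H, W)
  list(patch = image[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE],
       placement = list(x0 = x0, y0 = y0, height = y1 - y0, width = x1 - x0))
}

#' Paste a patch-frame mask back into the image frame
#'
#' @param patch_mask logical matrix in patch coordinates.
#' @param placement placement record from [crop_patch()].
#' @param shape `c(height, width)` of the image frame.
#' @return logical matrix in the image frame.
#' @export
paste_patch <- function(patch_mask, placement, shape) {
  if (nrow(patch_mask) != placement$height || ncol(patch_mask) != placement$width)
    sq_stop("patch mask %dx%d does not match placement %dx%d",
            nrow(patch_mask), ncol(patch_mask), placement$height, placement$width)
  out <- matrix(FALSE, shape[1L], shape[2L])
  out[(placement$y0 + 1):(placement$y0 + placement$height),
      (placement$x0 + 1):(placement$x0 + placement$width)] <- patch_mask
  out
}

#' Segment one patch into a binary cell mask
#'
#' With `model = NULL` the deterministic threshold-oracle path is used:
#' Otsu threshold, then the largest connected component. With a fitted
#' [fit_synapse_model()] the learned per-pixel classifier is applied.
#' Either way an empty mask is a legal outcome (the instance is dropped
#' downstream).
#'
#' @param patch numeric matrix.
#' @param model `NULL` (threshold oracle) or a `synapse_model`.
#' @return logical matrix, largest foreground component only.
#' @export
segment_patch <- function(patch, model = NULL) {
  if (length(patch) == 0L) sq_stop("empty patch")
  prob <- if (is.null(model)) {
    thr <- otsu_threshold(patch)
    (patch > thr) * 1
  } else {
    predict_prob(model, patch, head = "segmenter")
  }
  largest_component(prob > 0.5)
}

#' Ordered outer contour of a mask
#'
#' Moore boundary tracing around the largest component, post-completed so
#' that the contour pixel set equals the mask's 1-px border (mask minus
#' its 8-neighborhood erosion).
#'
#' @param mask non-empty logical matrix.
#' @return integer matrix with columns `x, y` (0-based), ordered along
#'   the boundary.
#' @export
mask_to_contour <- function(mask) {
  if (!any(mask)) sq_stop("empty mask has no contour")
  m <- largest_component(mask)
  h <- nrow(m); w <- ncol(m)
  border <- m & !erode8(m)
  # start: topmost, then leftmost border pixel (row-major scan)
  bw <- which(border, arr.ind = TRUE)
  start <- bw[order(bw[, 1L], bw[, 2L])[1L], ]
  # Moore neighborhood in clockwise order starting at W
  moore <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
                 c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  inside <- function(r, c) r >= 1L && r <= h && c >= 1L && c <= w && m[r, c]
  path <- matrix(start, 1L, 2L)
  if (sum(m) > 1L) {
    p <- start
    enter <- 1L  # direction index of the backtrack pixel relative to p
    first_move <- NULL
    for (step in seq_len(8L * sum(border) + 8L)) {
      found <- FALSE
      for (k in 0:7) {
        di <- (enter + k - 1L) %% 8L + 1L
        r <- p[1L] + moore[di, 1L]; c <- p[2L] + moore[di, 2L]
        if (inside(r, c)) {
          # new backtrack: the neighbor checked just before the hit
          prev <- (di - 2L) %% 8L + 1L
          came <- c(p[1L] + moore[prev, 1L], p[2L] + moore[prev, 2L])
          p <- c(r, c)
          # enter index: direction from new p back toward `came`
          rel <- c(came[1L] - r, came[2L] - c)
          enter <- which(moore[, 1L] == rel[1L] & moore[, 2L] == rel[2L])
          found <- TRUE
          break
        }
      }
      if (!found) break
      mv <- c(p, enter)
      if (is.null(first_move)) {
        first_move <- mv
      } else if (all(p == start) && all(mv == first_move)) {
        break
      }
      path <- rbind(path, p)
      if (all(p == start) && !is.null(first_move) &&
          nrow(path) > 2L && all(path[2L, ] == c(first_move[1L], first_move[2L]))) {
        # completed the loop; drop the duplicated start
        path <- path[-nrow(path), , drop = FALSE]
        break
      }
    }
    path <- path[!duplicated(path), , drop = FALSE]
  }
  # complete with any border pixels the trace skipped (diagonal notches)
  traced <- (path[, 2L] - 1L) * h + path[, 1L]
  missed <- setdiff(which(border), traced)
  for (q in missed) {
    r <- (q - 1L) %% h + 1L; c <- (q - 1L) %/% h + 1L
    d <- pmax(abs(path[, 1L] - r), abs(path[, 2L] - c))
    at <- which.min(d)
    path <- rbind(path[seq_len(at), , drop = FALSE], c(r, c),
                  if (at < nrow(path)) path[(at + 1L):nrow(path), , drop = FALSE])
  }
  out <- cbind(x = path[, 2L] - 1L, y = path[, 1L] - 1L)
  rownames(out) <- NULL
  out
}

#' Split a mask into its 1-px border and its interior
#'
#' Border pixels have at least one 8-neighbor outside the mask (image
#' edges count as outside); the interior is the remainder. The two sets
#' partition the mask exactly.
#'
#' @param mask non-empty logical matrix.
#' @return list with `border` and `interior`, logical matrices.
#' @export
split_border_interior <- function(mask) {
  if (!any(mask)) sq_stop("empty mask cannot be split")
  interior <- erode8(mask)
  list(border = mask & !interior, interior = interior)
}

#' Assemble detected boxes and patch masks into cell instances
#'
#' Masks are pasted back to the image frame; pixels claimed by several
#' instances go to the highest-scoring one; instances falling below
#' `min_area` are dropped; final masks are pairwise disjoint. Each
#' surviving instance gets its contour and border/interior split.
#'
#' @param boxes data.frame of detection boxes with `score`.
#' @param patch_masks list (one per box) of `list(mask, placement)`.
#' @param image_shape `c(height, width)`.
#' @param min_area smallest viable instance area in px (default 20).
#' @return list of `cell_instance` objects.
#' @export
assemble_instances <- function(boxes, patch_masks, image_shape, min_area = 20L) {
  n <- if (is.null(boxes)) 0L else nrow(boxes)
  if (length(patch_masks) != n)
    sq_stop("need one patch mask per box (%d boxes, %d masks)",
            n, length(patch_masks))
  if (n == 0L) return(list())
  frames <- lapply(seq_len(n), function(i) {
    pm <- patch_masks[[i]]
    paste_patch(pm$mask, pm$placement, image_shape)
  })
  # ownership: highest score wins contested pixels
  ord <- order(-boxes$score)
  owner <- matrix(0L, image_shape[1L], image_shape[2L])
  for (i in ord) {
    free <- frames[[i]] & owner == 0L
    owner[free] <- i
  }
  out <- list()
  for (i in seq_len(n)) {
    mask <- owner == i
    if (sum(mask) < min_area) next
    out[[length(out) + 1L]] <- cell_instance(
      cell_id = length(out) + 1L, mask = mask, score = boxes$score[i])
  }
  out
}

#' Construct a cell instance from a final mask
#'
#' Computes the tight box, ordered contour and border/interior partition.
#'
#' @param cell_id integer identifier.
#' @param mask non-empty logical matrix in the image frame.
#' @param score detection confidence in `[0, 1]`.
#' @return object of class `cell_instance`.
#' @export
cell_instance <- function(cell_id, mask, score = 1) {
  parts <- split_border_interior(mask)
  structure(list(cell_id = as.integer(cell_id),
                 box = mask_bbox(mask),
                 mask = mask,
                 contour = mask_to_contour(mask),
                 border = which(parts$border),
                 interior = which(parts$interior),
                 score = as.numeric(score)),
            class = "cell_instance")
}

#' @export
print.cell_instance <- function(x, ...) {
  cat(sprintf("<cell_instance> id %d, area %d px (border %d + interior %d), score %.3f\n",
              x$cell_id, sum(x$mask), length(x$border), length(x$interior),
              x$score))
  invisible(x)
}

#' Segment every detected box of an image and assemble instances
#'
#' Convenience wrapper: crops a patch per box, segments it (learned or
#' threshold-oracle path), and assembles disjoint instances.
#'
#' @param image numeric matrix (reference channel at the focal slice).
#' @param boxes detection boxes data.frame.
#' @param model `NULL` for the threshold oracle or a `synapse_model`.
#' @param margin patch context margin (default 8).
#' @param min_area minimum instance area (default 20).
#' @return list of `cell_instance` objects.
#' @export
segment_instances <- function(image, boxes, model = NULL, margin = 8L,
                              min_area = 20L) {
  if (is.null(boxes) || nrow(boxes) == 0L) return(list())
  pm <- lapply(seq_len(nrow(boxes)), function(i) {
    cp <- crop_patch(image, as.numeric(boxes[i, c("x_min", "y_min",
                                                  "x_max", "y_max")]),
                     margin = margin)
    list(mask = segment_patch(cp$patch, model), placement = cp$placement)
  })
  assemble_instances(boxes, pm, dim(image), min_area = min_area)
}
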