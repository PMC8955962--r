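# The learned detection/segmentation model.
#
# Two independent per-pixel classifiers (small one-hidden-layer MLPs on
# multi-scale image features, trained with Adam) stand in for the deep
# backbone: the detector head scores F-actin foreground on the focal
# slice, and its thresholded components are converted to keypoint
# heatmaps + offset maps so that boxes always flow through the
# multi-scale Hough-voting chain; the segmenter head scores foreground
# on per-box patches and deliberately shares no weights with the
# detector. The inference contract (keypoint maps in, boxes out;
# patches in, masks out) is fixed; the backbone behind it is a
# configuration choice sized for CPU training.

#' Training configuration
#'
#' @param learning_rate initial Adam learning rate (default 1e-4).
#' @param epochs training epochs (default 100).
#' @param hidden hidden units of each MLP head (default 16).
#' @param batch minibatch size in pixels (default 1024).
#' @param augmentations augmentation ops applied per epoch; `character(0)`
#'   disables augmentation.
#' @param margin segmentation patch margin in px (default 8).
#' @param scales detection disk radii (default `c(16, 32, 64, 128)`).
#' @param max_pixels_per_image cap on training pixels sampled per image.
#' @param seed root seed (weights init, sampling, augmentation).
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 100L, hidden = 16L,
                         batch = 1024L,
                         augmentations = c("expand", "crop", "flip",
                                           "contrast", "brightness"),
                         margin = 8L, scales = DEFAULT_SCALES,
                         max_pixels_per_image = 6000L, seed = 1L) {
  if (epochs < 1L) sq_stop("epochs must be >= 1")
  if (learning_rate <= 0) sq_stop("learning_rate must be positive")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 hidden = as.integer(hidden), batch = as.integer(batch),
                 augmentations = augmentations, margin = as.integer(margin),
                 scales = scales,
                 max_pixels_per_image = as.integer(max_pixels_per_image),
                 seed = as.integer(seed)),
            class = "train_config")
}

# ---- tiny MLP with Adam ----------------------------------------------------

mlp_init <- function(n_in, n_hidden) {
  list(W1 = matrix(stats::rnorm(n_in * n_hidden, 0, sqrt(2 / n_in)),
                   n_in, n_hidden),
       b1 = rep(0, n_hidden),
       W2 = matrix(stats::rnorm(n_hidden, 0, sqrt(1 / n_hidden)), n_hidden, 1L),
       b2 = 0)
}

mlp_forward <- function(par, X) {
  A <- tanh(sweep(X %*% par$W1, 2L, par$b1, `+`))
  z <- as.vector(A %*% par$W2) + par$b2
  list(A = A, p = 1 / (1 + exp(-z)))
}

mlp_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

mlp_grad <- function(par, X, y, fwd) {
  n <- length(y)
  dz2 <- matrix((fwd$p - y) / n, ncol = 1L)
  dW2 <- t(fwd$A) %*% dz2
  db2 <- sum(dz2)
  dA <- (dz2 %*% t(par$W2)) * (1 - fwd$A^2)
  dW1 <- t(X) %*% dA
  db1 <- colSums(dA)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(par)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grad[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

# Balanced pixel sample for one head: all foreground (capped) plus twice
# as much background.
balanced_sample <- function(y, cap) {
  fg <- which(y > 0.5); bg <- which(y <= 0.5)
  if (length(fg) > cap %/% 3L) fg <- sample(fg, cap %/% 3L)
  n_bg <- min(length(bg), 2L * max(length(fg), 50L))
  if (length(bg) > n_bg) bg <- sample(bg, n_bg)
  sample(c(fg, bg))
}

# ---- fitting ---------------------------------------------------------------

#' Fit the detection + segmentation model
#'
#' Trains the two per-pixel heads on labelled scenes (stacks with
#' ground-truth instance masks). Per epoch, each training image is
#' (optionally) augmented, features are extracted from the F-actin
#' channel at the focal slice, and both heads take Adam minibatch steps:
#' the detector on whole-image foreground labels, the segmenter on
#' per-instance patches in which neighboring cells count as background.
#' Training is fully reproducible from the config seed. Divergence
#' (non-finite loss) aborts with a diagnostic.
#'
#' @param dataset list of `list(stack, gt)` scenes (e.g. from
#'   [generate_dataset()]) used for training.
#' @param config a [train_config()].
#' @param val optional validation scenes; adds a per-epoch validation
#'   loss to the loss curve.
#' @return an object of class `synapse_model` with components
#'   `detector`, `segmenter` (MLP weights), `loss` (per-epoch curve) and
#'   `config`; see [predict.synapse_model()].
#' @export
fit_synapse_model <- function(dataset, config = train_config(), val = NULL) {
  stopifnot(inherits(config, "train_config"), length(dataset) >= 1L)
  with_seed(config$seed, fit_synapse_model_impl(dataset, config, val))
}

fit_synapse_model_impl <- function(dataset, config, val) {
  n_feat <- length(FEATURE_NAMES)
  det <- mlp_init(n_feat, config$hidden)
  seg <- mlp_init(n_feat, config$hidden)
  det_state <- adam_init(det)
  seg_state <- adam_init(seg)
  full <- 2^dataset[[1L]]$stack$bit_depth - 1

  sample_xy <- function(scene, augment_seed = NULL) {
    z <- select_focal_slice(scene$stack)$z_index
    img <- stack_slice(scene$stack, 1L, z)
    masks <- scene$gt$masks
    if (!is.null(augment_seed) && length(config$augmentations)) {
      aug <- augment_sample(img, masks, ops = config$augmentations,
                            seed = augment_seed, full_scale = full)
      img <- aug$image; masks <- aug$masks
    }
    X <- pixel_features(img, full)
    fg <- Reduce(`|`, masks, matrix(FALSE, nrow(img), ncol(img)))
    # segmenter pixels: per-instance patches, neighbors are negatives
    seg_idx <- integer(0); seg_y <- numeric(0)
    for (m in masks) {
      bb <- mask_bbox(m)
      cp <- crop_patch(img, bb, margin = config$margin)
      pl <- cp$placement
      rows <- (pl$y0 + 1):(pl$y0 + pl$height)
      cols <- (pl$x0 + 1):(pl$x0 + pl$width)
      lin <- as.vector(outer(rows, (cols - 1L) * nrow(img), `+`))
      seg_idx <- c(seg_idx, lin)
      seg_y <- c(seg_y, as.numeric(m[rows, cols]))
    }
    list(X = X, det_y = as.numeric(fg), seg_idx = seg_idx, seg_y = seg_y)
  }

  epoch_pass <- function(scenes, train, aug_seeds = NULL) {
    det_losses <- c(); seg_losses <- c()
    for (i in seq_along(scenes)) {
      s <- sample_xy(scenes[[i]],
                     augment_seed = if (is.null(aug_seeds)) NULL else aug_seeds[i])
      cap <- config$max_pixels_per_image
      di <- balanced_sample(s$det_y, cap)
      si <- if (length(s$seg_idx)) {
        keep <- balanced_sample(s$seg_y, cap)
        keep
      } else {
        integer(0)
      }
      run_head <- function(par, state, X, y) {
        nb <- max(1L, ceiling(nrow(X) / config$batch))
        losses <- numeric(nb)
        for (b in seq_len(nb)) {
          sel <- ((b - 1L) * config$batch + 1L):min(b * config$batch, nrow(X))
          fwd <- mlp_forward(par, X[sel, , drop = FALSE])
          losses[b] <- mlp_loss(fwd$p, y[sel])
          if (train) {
            g <- mlp_grad(par, X[sel, , drop = FALSE], y[sel], fwd)
            st <- adam_step(par, g, state, config$learning_rate)
            par <- st$par; state <- st$state
          }
        }
        list(par = par, state = state, loss = mean(losses))
      }
      r <- run_head(det, det_state, s$X[di, , drop = FALSE], s$det_y[di])
      det <- r$par; det_state <- r$state; det_losses <- c(det_losses, r$loss)
      if (length(si)) {
        r <- run_head(seg, seg_state, s$X[s$seg_idx[si], , drop = FALSE],
                      s$seg_y[si])
        seg <- r$par; seg_state <- r$state; seg_losses <- c(seg_losses, r$loss)
      }
    }
    det <<- det; det_state <<- det_state
    seg <<- seg; seg_state <<- seg_state
    c(det = mean(det_losses),
      seg = if (length(seg_losses)) mean(seg_losses) else NA_real_)
  }

  loss <- data.frame(epoch = integer(), train_detector = numeric(),
                     train_segmenter = numeric(), val_detector = numeric(),
                     val_segmenter = numeric())
  aug_seed_mat <- matrix(sample.int(.Machine$integer.max - 1L,
                                    config$epochs * length(dataset)),
                         config$epochs, length(dataset))
  for (ep in seq_len(config$epochs)) {
    tr <- epoch_pass(dataset, train = TRUE, aug_seeds = aug_seed_mat[ep, ])
    if (!all(is.finite(tr[!is.na(tr)])))
      sq_stop("training diverged at epoch %d (non-finite loss)", ep)
    vl <- c(det = NA_real_, seg = NA_real_)
    if (!is.null(val) && length(val)) vl <- epoch_pass(val, train = FALSE)
    loss <- rbind(loss, data.frame(epoch = ep, train_detector = tr[["det"]],
                                   train_segmenter = tr[["seg"]],
                                   val_detector = vl[["det"]],
                                   val_segmenter = vl[["seg"]]))
  }

  strip <- function(h) {
    dimnames(h$W1) <- NULL; dimnames(h$W2) <- NULL
    names(h$b1) <- NULL
    h
  }
  det <- strip(det); seg <- strip(seg)
  structure(list(detector = det, segmenter = seg, loss = loss,
                 config = config, full_scale = full,
                 n_train = length(dataset)),
            class = "synapse_model")
}

#' Train detector and segmenter models
#'
#' Harness-style alias of [fit_synapse_model()]: returns the two weight
#' sets and the loss curve as separate components.
#'
#' @inheritParams fit_synapse_model
#' @return list with `detector`, `segmenter`, `loss_curve`, and the full
#'   `model` object.
#' @export
train_models <- function(dataset, config = train_config(), val = NULL) {
  m <- fit_synapse_model(dataset, config, val)
  list(detector = m$detector, segmenter = m$segmenter, loss_curve = m$loss,
       model = m)
}

# Per-pixel foreground probability of one head over an image/patch.
predict_prob <- function(model, img, head = c("detector", "segmenter")) {
  head <- match.arg(head)
  if (!inherits(model, "synapse_model"))
    sq_stop("not a fitted synapse_model (got %s)", class(img)[1L])
  X <- pixel_features(img, model$full_scale)
  matrix(mlp_forward(model[[head]], X)$p, nrow(img), ncol(img))
}

#' Detect cells in one grayscale image
#'
#' Full detection chain: per-pixel foreground inference (learned model,
#' or Otsu threshold-oracle when `model` is `NULL`), conversion of the
#' predicted objects to keypoint heatmaps/offset maps, then multi-scale
#' Hough voting, box construction and NMS. Deterministic given the model
#' weights and input.
#'
#' @param image numeric matrix (F-actin channel at the focal slice).
#' @param model a fitted `synapse_model`, or `NULL` for the
#'   threshold-oracle path.
#' @param scales detection disk radii (defaults to the model's, else
#'   `DEFAULT_SCALES`).
#' @param min_area smallest component fed to box generation.
#' @param heat_threshold,nms_iou Hough-chain parameters.
#' @return data.frame of scored boxes.
#' @export
detect_cells <- function(image, model = NULL, scales = NULL, min_area = 20L,
                         heat_threshold = 0.1, nms_iou = 0.5) {
  if (!is.null(model) && !inherits(model, "synapse_model"))
    sq_stop("model must be NULL or a fitted synapse_model")
  scales <- scales %||% (if (!is.null(model)) model$config$scales
                         else DEFAULT_SCALES)
  prob <- if (is.null(model)) {
    thr <- otsu_threshold(image)
    (image > thr) * 1
  } else {
    predict_prob(model, image, "detector")
  }
  bin <- prob > 0.5
  lab <- label_components(bin)
  nlab <- max(lab)
  if (nlab == 0L) return(empty_boxes())
  boxes <- list()
  for (k in seq_len(nlab)) {
    m <- lab == k
    if (sum(m) < min_area) next
    bb <- mask_bbox(m)
    boxes[[length(boxes) + 1L]] <-
      data.frame(x_min = bb[["x_min"]], y_min = bb[["y_min"]],
                 x_max = bb[["x_max"]], y_max = bb[["y_max"]],
                 score = mean(prob[m]))
  }
  if (!length(boxes)) return(empty_boxes())
  maps <- render_keypoint_maps(do.call(rbind, boxes), dim(image), scales)
  boxes_from_maps(maps, heat_threshold = heat_threshold, nms_iou = nms_iou)
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.synapse_model <- function(x, ...) {
  cat(sprintf("<synapse_model> %d-feature MLP heads (%d hidden units)\n",
              nrow(x$detector$W1), ncol(x$detector$W1)))
  cat(sprintf("  trained %d epochs on %d scenes, lr %g\n",
              max(x$loss$epoch), x$n_train, x$config$learning_rate))
  cat(sprintf("  final loss: detector %.4f, segmenter %.4f\n",
              utils::tail(x$loss$train_detector, 1),
              utils::tail(x$loss$train_segmenter, 1)))
  invisible(x)
}

#' @export
summary.synapse_model <- function(object, ...) {
  cat("Synapse detection/segmentation model\n")
  print(object)
  cat("  scales (disk radii px):",
      paste(object$config$scales, collapse = ", "), "\n")
  cat("  augmentations:",
      if (length(object$config$augmentations))
        paste(object$config$augmentations, collapse = ", ") else "none", "\n")
  invisible(object$loss)
}

#' @export
coef.synapse_model <- function(object, ...) {
  list(detector = object$detector, segmenter = object$segmenter)
}

#' Plot training/validation loss curves
#' @param x a `synapse_model`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.synapse_model <- function(x, ...) {
  l <- x$loss
  cols <- c("train_detector", "train_segmenter", "val_detector",
            "val_segmenter")
  keep <- cols[colSums(!is.na(l[cols])) > 0]
  graphics::matplot(l$epoch, as.matrix(l[keep]), type = "l", lty = 1,
                    xlab = "epoch", ylab = "binary cross-entropy",
                    main = "training loss", ...)
  graphics::legend("topright", legend = keep, lty = 1,
                   col = seq_along(keep), bty = "n")
  invisible(x)
}

#' Predict cell instances on a new image or stack
#'
#' Runs focal-slice selection (stacks), detection and patch-wise
#' segmentation with the fitted model.
#'
#' @param object a fitted `synapse_model`.
#' @param newdata an [image_stack()] or a plain numeric matrix (already
#'   the reference-channel focal slice).
#' @param type `"instances"` (default), `"boxes"`, or `"prob"` (the raw
#'   detector probability map).
#' @param ... unused.
#' @return per `type`: list of `cell_instance`, a box data.frame, or a
#'   probability matrix.
#' @export
predict.synapse_model <- function(object, newdata,
                                  type = c("instances", "boxes", "prob"),
                                  ...) {
  type <- match.arg(type)
  img <- if (inherits(newdata, "image_stack")) {
    z <- select_focal_slice(newdata)$z_index
    stack_slice(newdata, 1L, z)
  } else {
    as.matrix(newdata)
  }
  if (type == "prob") return(predict_prob(object, img, "detector"))
  boxes <- detect_cells(img, object)
  if (type == "boxes") return(boxes)
  segment_instances(img, boxes, model = object,
                    margin = object$config$margin)
}
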