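# Stack, annotation and table I/O: the five-channel data contract.

CHANNEL_ROLES <- c("F-actin", "perforin", "tumor antigen", "pZeta", "DIC")

#' Construct a five-channel image stack
#'
#' The raw input of the pipeline: a five-channel, multi-Z grayscale voxel
#' array. Channels are, by convention, 1 F-actin, 2 perforin, 3 tumor
#' antigen, 4 pZeta, 5 DIC; quantification uses channels 1-4 only.
#'
#' @param voxels integer array with dimensions `[channel, z, y, x]`;
#'   exactly 5 channels, non-negative intensities.
#' @param channel_roles character vector of length 5 naming each channel.
#' @param bit_depth 8 or 16.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(voxels, channel_roles = CHANNEL_ROLES, bit_depth = 16L) {
  if (length(dim(voxels)) != 4L)
    sq_stop("voxels must be a 4-D [channel, z, y, x] array, got %d dims",
            length(dim(voxels)))
  if (dim(voxels)[1L] != 5L)
    sq_stop("image stack must have exactly 5 channels, got %d (channel axis)",
            dim(voxels)[1L])
  if (any(voxels < 0)) sq_stop("intensities must be non-negative")
  if (!bit_depth %in% c(8L, 16L)) sq_stop("bit_depth must be 8 or 16")
  stopifnot(length(channel_roles) == 5L)
  structure(list(voxels = voxels,
                 channel_roles = as.character(channel_roles),
                 bit_depth = as.integer(bit_depth)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> 5 channels x %d z x %d x %d px, %d-bit\n",
              d[2L], d[3L], d[4L], x$bit_depth))
  cat("  channels:", paste(seq_len(5L), x$channel_roles, sep = ":",
                           collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' Extract one z-slice of one channel
#'
#' @param stack an [image_stack()].
#' @param channel channel index in 1..5.
#' @param z slice index (1-based).
#' @return numeric y-by-x matrix.
#' @export
stack_slice <- function(stack, channel, z) {
  d <- dim(stack$voxels)
  if (channel < 1L || channel > 5L) sq_stop("channel must be in 1..5")
  if (z < 1L || z > d[2L]) sq_stop("z out of range 1..%d", d[2L])
  matrix(stack$voxels[channel, z, , ], d[3L], d[4L])
}

#' Write an image stack to a multi-page TIFF
#'
#' Pages are ordered channel-major (all z of channel 1, then channel 2, ...),
#' i.e. CZYX axis order. Channel roles, bit depth and the z count are stored
#' as JSON in the first page's ImageDescription tag.
#'
#' @param stack an [image_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  pages <- vector("list", d[1L] * d[2L])
  k <- 0L
  for (ch in seq_len(d[1L])) for (z in seq_len(d[2L])) {
    k <- k + 1L
    pages[[k]] <- stack_slice(stack, ch, z)
  }
  meta <- jsonlite::toJSON(list(axes = "CZYX", n_channels = d[1L],
                                n_z = d[2L], bit_depth = stack$bit_depth,
                                channel_roles = stack$channel_roles),
                           auto_unbox = TRUE)
  write_tiff(pages, path, bit_depth = stack$bit_depth,
             description = as.character(meta))
  invisible(path)
}

#' Read a five-channel image stack from TIFF
#'
#' Expects the CZYX page layout written by [write_stack()]. If the metadata
#' tag is missing, the page count must be divisible by 5 and channels are
#' assigned positionally with the default roles.
#'
#' @param path TIFF file path.
#' @return an [image_stack()].
#' @export
read_stack <- function(path) {
  tf <- read_tiff(path)
  n_pages <- length(tf$pages)
  meta <- NULL
  if (!is.null(tf$description)) {
    meta <- tryCatch(jsonlite::fromJSON(tf$description), error = function(e) NULL)
  }
  if (!is.null(meta) && !is.null(meta$n_channels)) {
    n_ch <- as.integer(meta$n_channels)
    n_z <- as.integer(meta$n_z)
    roles <- meta$channel_roles %||% CHANNEL_ROLES
  } else {
    if (n_pages %% 5L != 0L)
      sq_stop("cannot infer channels: %d pages not divisible by 5 (channel axis)",
              n_pages)
    n_ch <- 5L
    n_z <- n_pages %/% 5L
    roles <- CHANNEL_ROLES
  }
  if (n_ch != 5L)
    sq_stop("image stack must have exactly 5 channels, got %d (channel axis)", n_ch)
  if (n_ch * n_z != n_pages)
    sq_stop("page count %d does not match %d channels x %d z", n_pages, n_ch, n_z)
  h <- nrow(tf$pages[[1L]]); w <- ncol(tf$pages[[1L]])
  vox <- array(0L, dim = c(n_ch, n_z, h, w))
  k <- 0L
  for (ch in seq_len(n_ch)) for (z in seq_len(n_z)) {
    k <- k + 1L
    vox[ch, z, , ] <- tf$pages[[k]]
  }
  image_stack(vox, channel_roles = roles, bit_depth = tf$bit_depth)
}

# ---- COCO-style annotations ------------------------------------------------

# Uncompressed RLE over the mask flattened in column-major (Fortran) order,
# counts alternating runs of 0s and 1s and starting with the 0-run, as in
# the COCO annotation dialect.
rle_encode <- function(mask) {
  v <- as.integer(mask)
  r <- rle(v)
  counts <- r$lengths
  if (r$values[1L] == 1L) counts <- c(0L, counts)
  list(size = c(nrow(mask), ncol(mask)), counts = as.integer(counts))
}

rle_decode <- function(rle) {
  counts <- as.integer(rle$counts)
  vals <- rep(c(0L, 1L), length.out = length(counts))
  v <- rep(vals, counts)
  size <- as.integer(rle$size)
  if (length(v) != prod(size)) sq_stop("RLE counts do not cover mask size")
  matrix(as.logical(v), size[1L], size[2L])
}

#' Tight bounding box of a mask
#'
#' Half-open, 0-based `c(x_min, y_min, x_max, y_max)` hull of a logical
#' mask. Errors on empty masks.
#'
#' @param mask logical matrix.
#' @return named numeric vector of length 4.
#' @export
mask_bbox <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) sq_stop("empty mask has no bounding box")
  c(x_min = min(w[, 2L]) - 1, y_min = min(w[, 1L]) - 1,
    x_max = max(w[, 2L]), y_max = max(w[, 1L]))
}

#' Write instance annotations as COCO-like JSON
#'
#' Each instance carries an uncompressed column-major RLE `segmentation`,
#' its tight `bbox` as `[x, y, w, h]` (0-based), and an optional `score`.
#'
#' @param masks list of logical matrices in the image frame.
#' @param path output JSON path.
#' @param image_id identifier recorded for the image.
#' @param scores optional numeric vector in `[0, 1]`, one per mask.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(masks, path, image_id = "image_1", scores = NULL) {
  stopifnot(is.list(masks))
  if (!is.null(scores)) {
    stopifnot(length(scores) == length(masks), all(scores >= 0 & scores <= 1))
  }
  h <- if (length(masks)) nrow(masks[[1L]]) else NA_integer_
  w <- if (length(masks)) ncol(masks[[1L]]) else NA_integer_
  anns <- lapply(seq_along(masks), function(i) {
    bb <- mask_bbox(masks[[i]])
    a <- list(id = i, image_id = image_id,
              segmentation = rle_encode(masks[[i]]),
              bbox = c(bb[["x_min"]], bb[["y_min"]],
                       bb[["x_max"]] - bb[["x_min"]],
                       bb[["y_max"]] - bb[["y_min"]]),
              area = sum(masks[[i]]))
    if (!is.null(scores)) a$score <- scores[i]
    a
  })
  doc <- list(images = list(list(id = image_id, height = h, width = w)),
              annotations = anns)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read COCO-like instance annotations
#'
#' @param path JSON path written by [write_annotations()].
#' @return list with `image_id`, `masks` (list of logical matrices), `boxes`
#'   (data.frame `x_min, y_min, x_max, y_max, score`).
#' @export
read_annotations <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  anns <- doc$annotations
  masks <- lapply(anns, function(a)
    rle_decode(list(size = unlist(a$segmentation$size),
                    counts = unlist(a$segmentation$counts))))
  boxes <- do.call(rbind, lapply(anns, function(a) {
    bb <- unlist(a$bbox)
    data.frame(x_min = bb[1L], y_min = bb[2L], x_max = bb[1L] + bb[3L],
               y_max = bb[2L] + bb[4L],
               score = if (is.null(a$score)) NA_real_ else a$score)
  }))
  if (is.null(boxes)) {
    boxes <- data.frame(x_min = numeric(), y_min = numeric(),
                        x_max = numeric(), y_max = numeric(),
                        score = numeric())
  }
  list(image_id = doc$images[[1L]]$id, masks = masks, boxes = boxes)
}

#' Write instance masks as a 16-bit label image
#'
#' Pixel value k marks membership of instance k; 0 is background. Instances
#' must be disjoint.
#'
#' @param masks list of logical matrices.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(masks, path) {
  stopifnot(is.list(masks), length(masks) <= 65535L)
  if (length(masks) == 0L) sq_stop("no masks to write")
  lab <- matrix(0L, nrow(masks[[1L]]), ncol(masks[[1L]]))
  for (i in seq_along(masks)) {
    if (any(lab[masks[[i]]] != 0L)) sq_stop("masks overlap at label image write")
    lab[masks[[i]]] <- i
  }
  write_tiff(list(lab), path, bit_depth = 16L,
             description = '{"kind":"label_image"}')
  invisible(path)
}

#' Read a label image back into instance masks
#'
#' @param path TIFF path written by [write_label_image()].
#' @return list of logical masks, ordered by label.
#' @export
read_label_image <- function(path) {
  lab <- read_tiff(path)$pages[[1L]]
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  lapply(ids, function(i) lab == i)
}

# ---- TFI tables ------------------------------------------------------------

tfi_table_cols <- c("image_id", "cell_id", "channel", "area_px", "tfi",
                    "border_intensity", "interior_intensity")

#' Write a per-cell, per-channel intensity table to CSV
#'
#' One row per (cell, channel). An empty record list yields a header-only
#' file.
#'
#' @param records data.frame with columns `image_id, cell_id, channel,
#'   area_px, tfi, border_intensity, interior_intensity`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tfi_table <- function(records, path) {
  if (is.null(records) || nrow(records) == 0L) {
    records <- as.data.frame(setNames(rep(list(numeric(0)),
                                          length(tfi_table_cols)),
                                      tfi_table_cols))
    records$image_id <- character(0)
  }
  missing_cols <- setdiff(tfi_table_cols, names(records))
  if (length(missing_cols))
    sq_stop("TFI records missing columns: %s", paste(missing_cols, collapse = ", "))
  utils::write.csv(records[tfi_table_cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a TFI table written by [write_tfi_table()]
#' @param path CSV path.
#' @return data.frame of TFI records.
#' @export
read_tfi_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
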