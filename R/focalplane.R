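# Focal-plane selection from the tumor-antigen channel.
#
# The synapse forms where the tumor antigen clusters on the bilayer, so
# the in-focus slice is the one maximising the per-slice mean intensity of
# channel 3. The mean (not the per-slice maximum pixel) is used because a
# single bright impurity speckle would otherwise dominate the choice.

#' Per-slice mean intensity profile of one channel
#'
#' @param stack an [image_stack()].
#' @param channel channel index in 1..5 (default 3, tumor antigen).
#' @return numeric vector of length `n_z`; element z is the arithmetic
#'   mean over all pixels of that channel at slice z.
#' @export
slice_mean_profile <- function(stack, channel = 3L) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  if (channel < 1L || channel > 5L) sq_stop("channel must be in 1..5")
  if (any(d[3:4] == 0L)) sq_stop("empty stack has no intensity profile")
  vapply(seq_len(d[2L]), function(z) mean(stack$voxels[channel, z, , ]), 0)
}

#' Select the in-focus z slice
#'
#' Returns the slice with maximal per-slice mean intensity in the probed
#' channel; ties break to the lowest index.
#'
#' @param stack an [image_stack()].
#' @param channel channel to probe (default 3, tumor antigen).
#' @return object of class `focal_plane`: list with `z_index` (1-based)
#'   and `profile`.
#' @export
select_focal_slice <- function(stack, channel = 3L) {
  profile <- slice_mean_profile(stack, channel)
  structure(list(z_index = which.max(profile), profile = profile,
                 channel = as.integer(channel)),
            class = "focal_plane")
}

#' @export
print.focal_plane <- function(x, ...) {
  cat(sprintf("<focal_plane> z = %d of %d (channel %d)\n",
              x$z_index, length(x$profile), x$channel))
  cat("  profile:", paste(sprintf("%.1f", x$profile), collapse = " "), "\n")
  invisible(x)
}
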