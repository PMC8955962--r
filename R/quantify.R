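# Per-cell fluorescence quantification and population statistics.
#
# Contours derived from the F-actin channel at the focal slice define
# each cell's ROI; the same mask is applied to channels 1-4 (DIC is
# never quantified) to obtain raw integrated gray values: the total
# fluorescence intensity (TFI), split into its border and interior
# contributions. No background subtraction or normalization is applied.

#' Total fluorescence intensity of one cell in one channel slice
#'
#' @param channel_slice numeric matrix (one channel at the focal slice).
#' @param instance a `cell_instance` in the same frame.
#' @return list with `area`, `tfi`, `border_intensity`,
#'   `interior_intensity`; `tfi` is always the sum of the latter two.
#' @export
total_fluorescence_intensity <- function(channel_slice, instance) {
  stopifnot(inherits(instance, "cell_instance"))
  if (!all(dim(channel_slice) == dim(instance$mask)))
    sq_stop("slice and mask frames differ")
  if (!any(instance$mask)) sq_stop("empty mask has no intensity")
  border <- sum(channel_slice[instance$border])
  interior <- sum(channel_slice[instance$interior])
  list(area = sum(instance$mask), tfi = border + interior,
       border_intensity = border, interior_intensity = interior)
}

#' Per-cell, per-channel intensity table at the focal slice
#'
#' One record per instance per channel 1-4, all measured at the same z.
#' Channel 5 (DIC) is excluded by design.
#'
#' @param stack an [image_stack()].
#' @param z a `focal_plane` object or a 1-based slice index.
#' @param instances list of `cell_instance` (from the F-actin channel at
#'   slice z).
#' @param image_id identifier carried into the records.
#' @return data.frame of TFI records (columns `image_id, cell_id,
#'   channel, area_px, tfi, border_intensity, interior_intensity`).
#' @export
per_cell_channel_table <- function(stack, z, instances, image_id = "image_1") {
  if (inherits(z, "focal_plane")) z <- z$z_index
  rows <- list()
  for (inst in instances) {
    for (ch in 1:4) {
      sl <- stack_slice(stack, ch, z)
      v <- total_fluorescence_intensity(sl, inst)
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = image_id, cell_id = inst$cell_id, channel = ch,
        area_px = v$area, tfi = v$tfi,
        border_intensity = v$border_intensity,
        interior_intensity = v$interior_intensity)
    }
  }
  if (!length(rows)) {
    return(data.frame(image_id = character(), cell_id = integer(),
                      channel = integer(), area_px = numeric(),
                      tfi = numeric(), border_intensity = numeric(),
                      interior_intensity = numeric()))
  }
  do.call(rbind, rows)
}

#' Summary statistics of one group of measurements
#'
#' Sample mean, unbiased variance and standard error; a single
#' observation yields variance 0 by convention.
#'
#' @param values numeric vector, length >= 1.
#' @return list of class `group_stats`: `n`, `mean`, `variance`, `sem`.
#' @export
summarize_group <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) sq_stop("cannot summarize an empty group")
  n <- length(values)
  v <- if (n > 1L) stats::var(values) else 0
  structure(list(n = n, mean = mean(values), variance = v,
                 sem = sqrt(v / n)),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("<group_stats> n = %d, mean = %.1f +/- %.1f (SEM), variance = %.3g\n",
              x$n, x$mean, x$sem, x$variance))
  invisible(x)
}

#' Two-tailed independent two-sample t-test
#'
#' Pooled-variance Student test of identical means (the classical
#' two-sided test for two independent i.i.d. samples); Welch's variant
#' is available via `var_equal = FALSE`. Degenerate inputs are defined:
#' both samples constant and equal gives t = 0, p = 1; zero pooled
#' variance with unequal means gives infinite t, p = 0 (flagged).
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param var_equal pooled-variance Student test if `TRUE` (default).
#' @return list of class `t_test_result`: `t`, `p`, `df`, `degenerate`.
#' @export
ttest_two_sided <- function(a, b, var_equal = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    sq_stop("both samples need n >= 2")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  dm <- mean(a) - mean(b)
  if (var_equal) {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- if (se > 0) se^4 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
          else na + nb - 2
  }
  degenerate <- FALSE
  if (se == 0) {
    degenerate <- TRUE
    if (dm == 0) {
      t <- 0; p <- 1
    } else {
      t <- sign(dm) * Inf; p <- 0
      warning("zero pooled variance with unequal means; p -> 0 sentinel")
    }
  } else {
    t <- dm / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(t = t, p = p, df = df, degenerate = degenerate),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("<t_test> t = %.3f, df = %.1f, two-sided p = %.3g%s\n",
              x$t, x$df, x$p, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Histogram and empirical cumulative distribution of a sample
#'
#' @param values numeric vector, length >= 1.
#' @param n_bins number of equal-width histogram bins (>= 1).
#' @return list with `histogram` (`counts`, `edges`; counts sum to n)
#'   and `ecdf` (`x` sorted sample points, `p` right-continuous
#'   cumulative probabilities ending at 1).
#' @export
distribution_summaries <- function(values, n_bins = 30L) {
  values <- as.numeric(values)
  if (!length(values)) sq_stop("empty sample has no distribution")
  if (n_bins < 1L) sq_stop("n_bins must be >= 1")
  lo <- min(values); hi <- max(values)
  if (hi <= lo) { lo <- lo - 0.5; hi <- hi + 0.5 }
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- tabulate(findInterval(values, edges, rightmost.closed = TRUE),
                     n_bins)
  xs <- sort(unique(values))
  p <- stats::ecdf(values)(xs)
  list(histogram = list(counts = counts, edges = edges),
       ecdf = list(x = xs, p = p))
}

#' Compare two cell populations in one channel
#'
#' Extracts the TFI column of the requested channel from both tables and
#' runs [summarize_group()] plus [ttest_two_sided()], exactly as if
#' called on the extracted vectors.
#'
#' @param table_a,table_b TFI record tables (see
#'   [per_cell_channel_table()]).
#' @param channel channel index in 1..4.
#' @param var_equal passed to [ttest_two_sided()].
#' @return list with `stats_a`, `stats_b` (`group_stats`) and `test`
#'   (`t_test_result`).
#' @export
compare_groups <- function(table_a, table_b, channel, var_equal = TRUE) {
  pick <- function(tb, nm) {
    v <- tb$tfi[tb$channel == channel]
    if (!length(v)) sq_stop("channel %s absent from table %s", channel, nm)
    v
  }
  a <- pick(table_a, "a"); b <- pick(table_b, "b")
  list(stats_a = summarize_group(a), stats_b = summarize_group(b),
       test = ttest_two_sided(a, b, var_equal = var_equal))
}
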