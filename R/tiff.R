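# Minimal multi-page grayscale TIFF codec (uncompressed, little-endian).
#
# The imaging stack contract is plain baseline TIFF: one page per
# (channel, z) plane, 8- or 16-bit unsigned grayscale, a single strip per
# page, and a JSON ImageDescription tag on the first page carrying the
# channel-role metadata. No general-purpose TIFF reader exists in the
# package's dependency budget, so only this baseline subset is supported;
# compressed or tiled files are rejected explicitly.

TIFF_TAG <- list(width = 256L, length = 257L, bits = 258L, compression = 259L,
                 photometric = 262L, description = 270L, strip_offsets = 273L,
                 samples = 277L, rows_per_strip = 278L, strip_bytes = 279L)

u16_raw <- function(v) {
  v <- as.integer(v)
  as.raw(rbind(v %% 256L, v %/% 256L))
}

u32_raw <- function(v) {
  v <- as.numeric(v)
  as.raw(rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
               (v %/% 16777216) %% 256))
}

rd_u16 <- function(r, pos, n = 1L) {
  b <- as.integer(r[pos:(pos + 2L * n - 1L)])
  b[seq(1L, 2L * n, 2L)] + 256L * b[seq(2L, 2L * n, 2L)]
}

rd_u32 <- function(r, pos, n = 1L) {
  b <- as.numeric(as.integer(r[pos:(pos + 4L * n - 1L)]))
  i <- seq(1L, 4L * n, 4L)
  b[i] + 256 * b[i + 1L] + 65536 * b[i + 2L] + 16777216 * b[i + 3L]
}

# One 12-byte IFD entry. `value` is either an inline value or an offset.
tiff_entry <- function(tag, type, count, value, inline_short = FALSE) {
  val <- if (inline_short) c(u16_raw(value), as.raw(c(0L, 0L))) else u32_raw(value)
  c(u16_raw(tag), u16_raw(type), u32_raw(count), val)
}

#' Write a multi-page grayscale TIFF
#'
#' @param pages list of integer matrices (rows = y, cols = x), all the same
#'   size, values in `[0, 2^bit_depth - 1]`.
#' @param path output file path.
#' @param bit_depth 8 or 16.
#' @param description optional character scalar stored in the first page's
#'   ImageDescription tag.
#' @return `path`, invisibly.
#' @keywords internal
write_tiff <- function(pages, path, bit_depth = 16L, description = NULL) {
  stopifnot(is.list(pages), length(pages) >= 1L, bit_depth %in% c(8L, 16L))
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  bpp <- bit_depth / 8L
  n <- length(pages)
  strip_bytes <- h * w * bpp

  # layout: 8-byte header | page data | description | IFDs
  data_off <- 8
  strip_offsets <- data_off + strip_bytes * (seq_len(n) - 1)
  desc_raw <- NULL
  desc_off <- data_off + strip_bytes * n
  if (!is.null(description)) {
    desc_raw <- c(charToRaw(description), as.raw(0L))
    if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))
  }
  ifd0_off <- desc_off + length(desc_raw)

  ifd_raw_for <- function(i, next_off) {
    entries <- list(
      tiff_entry(TIFF_TAG$width, 4L, 1L, w),
      tiff_entry(TIFF_TAG$length, 4L, 1L, h),
      tiff_entry(TIFF_TAG$bits, 3L, 1L, bit_depth, inline_short = TRUE),
      tiff_entry(TIFF_TAG$compression, 3L, 1L, 1L, inline_short = TRUE),
      tiff_entry(TIFF_TAG$photometric, 3L, 1L, 1L, inline_short = TRUE)
    )
    if (i == 1L && !is.null(desc_raw)) {
      entries <- c(entries, list(
        tiff_entry(TIFF_TAG$description, 2L, length(desc_raw), desc_off)))
    }
    entries <- c(entries, list(
      tiff_entry(TIFF_TAG$strip_offsets, 4L, 1L, strip_offsets[i]),
      tiff_entry(TIFF_TAG$samples, 3L, 1L, 1L, inline_short = TRUE),
      tiff_entry(TIFF_TAG$rows_per_strip, 4L, 1L, h),
      tiff_entry(TIFF_TAG$strip_bytes, 4L, 1L, strip_bytes)
    ))
    entries <- entries[order(vapply(entries, function(e) rd_u16(e, 1L), 0))]
    c(u16_raw(length(entries)), unlist(entries), u32_raw(next_off))
  }

  # IFD sizes differ (description tag on page 1 only); compute offsets first
  n_entries <- c(if (!is.null(desc_raw)) 10L else 9L, rep(9L, n - 1L))
  ifd_sizes <- 2 + 12 * n_entries + 4
  ifd_offs <- ifd0_off + cumsum(c(0, ifd_sizes[-n]))
  next_offs <- c(ifd_offs[-1L], 0)

  encode_page <- function(m) {
    v <- as.integer(t(m))
    if (any(is.na(v)) || any(v < 0L) || any(v > 2^bit_depth - 1))
      sq_stop("pixel values out of range for %d-bit TIFF", bit_depth)
    if (bpp == 1L) as.raw(v) else as.raw(rbind(v %% 256L, v %/% 256L))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), as.raw(c(42L, 0L)), u32_raw(ifd_offs[1L])), con)
  for (m in pages) {
    stopifnot(nrow(m) == h, ncol(m) == w)
    writeBin(encode_page(m), con)
  }
  if (!is.null(desc_raw)) writeBin(desc_raw, con)
  for (i in seq_len(n)) writeBin(ifd_raw_for(i, next_offs[i]), con)
  invisible(path)
}

#' Read a multi-page grayscale TIFF written by [write_tiff()]
#'
#' Baseline uncompressed little-endian grayscale only.
#'
#' @param path file path.
#' @return list with `pages` (list of integer matrices), `bit_depth`, and
#'   `description` (string or `NULL`).
#' @keywords internal
read_tiff <- function(path) {
  if (!file.exists(path)) sq_stop("file not found: %s", path)
  r <- readBin(path, "raw", file.info(path)$size)
  if (length(r) < 8L || rawToChar(r[1:2]) != "II" || rd_u16(r, 3L) != 42L)
    sq_stop("not a little-endian TIFF file: %s", path)
  off <- rd_u32(r, 5L)
  pages <- list()
  description <- NULL
  while (off != 0) {
    n_ent <- rd_u16(r, off + 1L)
    tags <- list()
    for (k in seq_len(n_ent)) {
      e <- off + 2L + 12L * (k - 1L)
      tag <- rd_u16(r, e + 1L)
      type <- rd_u16(r, e + 3L)
      count <- rd_u32(r, e + 5L)
      inline <- (type %in% c(3L, 1L) && count <= 2L) || (type == 4L && count == 1L)
      val <- if (type == 3L && count <= 2L) rd_u16(r, e + 9L, count)
             else rd_u32(r, e + 9L)
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        value = val, inline = inline)
    }
    need <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) {
        if (is.null(default)) sq_stop("TIFF missing required tag %d", tag)
        return(default)
      }
      t$value
    }
    comp <- need(TIFF_TAG$compression, 1L)
    if (comp != 1L) sq_stop("unsupported TIFF compression %d", comp)
    bits <- need(TIFF_TAG$bits, 8L)
    if (!bits %in% c(8L, 16L)) sq_stop("unsupported bit depth %d", bits)
    if (need(TIFF_TAG$samples, 1L) != 1L)
      sq_stop("only single-sample grayscale TIFF supported")
    w <- need(TIFF_TAG$width); h <- need(TIFF_TAG$length)
    so <- tags[[as.character(TIFF_TAG$strip_offsets)]]
    sb <- tags[[as.character(TIFF_TAG$strip_bytes)]]
    if (is.null(so) || is.null(sb)) sq_stop("TIFF missing strip layout")
    strip_offs <- if (so$count == 1L) so$value
                  else rd_u32(r, so$value + 1L, so$count)
    strip_lens <- if (sb$count == 1L) sb$value
                  else rd_u32(r, sb$value + 1L, sb$count)
    buf <- unlist(lapply(seq_along(strip_offs), function(i) {
      r[(strip_offs[i] + 1L):(strip_offs[i] + strip_lens[i])]
    }))
    vals <- if (bits == 8L) as.integer(buf)
            else readBin(buf, "integer", n = length(buf) / 2L, size = 2L,
                         signed = FALSE, endian = "little")
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    d <- tags[[as.character(TIFF_TAG$description)]]
    if (!is.null(d) && is.null(description)) {
      dr <- r[(d$value + 1L):(d$value + d$count)]
      description <- rawToChar(dr[dr != as.raw(0L)])
    }
    attr(pages[[length(pages)]], "bits") <- bits
    off <- rd_u32(r, off + 2L + 12L * n_ent + 1L)
  }
  bit_depth <- attr(pages[[1L]], "bits")
  pages <- lapply(pages, function(p) { attr(p, "bits") <- NULL; p })
  list(pages = pages, bit_depth = bit_depth, description = description)
}
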