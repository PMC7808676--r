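# Minimal baseline TIFF codec: uncompressed grayscale multi-page stacks,
# 8/16-bit unsigned, little- or big-endian, strip-organized.  Covers the
# files this package writes plus ImageJ/tifffile-style grayscale stacks.
# Voxel spacing is carried ImageJ-style: dz as "spacing=" in the
# ImageDescription, dx/dy as X/YResolution rationals (pixels per micron),
# with full-precision "dx="/"dy=" description keys as the primary source.

u16_raw <- function(v) {
  v <- as.integer(round(v))
  as.raw(as.vector(rbind(v %% 256L, v %/% 256L)))
}
u32_raw <- function(v) {
  v <- as.numeric(v)
  b0 <- v %% 256; v <- v %/% 256
  b1 <- v %% 256; v <- v %/% 256
  b2 <- v %% 256; v <- v %/% 256
  b3 <- v %% 256
  as.raw(as.vector(rbind(b0, b1, b2, b3)))
}
raw_uint <- function(r, size, le = TRUE) {
  m <- matrix(as.integer(r), nrow = size)
  pw <- if (le) 256^(seq_len(size) - 1) else 256^(size - seq_len(size))
  as.numeric(pw %*% m)
}

tiff_tag <- function(id, type, count, value_raw4) {
  c(u16_raw(id), u16_raw(type), u32_raw(count), value_raw4)
}

#' Write a multi-channel z-stack as a multi-page TIFF
#'
#' Pages are stored channel-fastest (page = channel + n_channels * (z - 1)),
#' 16-bit unsigned, uncompressed. Spacing metadata is embedded so that
#' [read_stack()] round-trips it exactly.
#'
#' @param channels a [voxel_grid()] or list of them (same shape and spacing).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(channels, path) {
  if (inherits(channels, "voxel_grid")) channels <- list(channels)
  if (!length(channels)) stop("no channels to write")
  sp <- voxel_spacing(channels[[1]])
  d <- dim(channels[[1]])
  for (ch in channels) {
    if (!identical(dim(ch), d)) stop("channels must share one shape")
    if (max(abs(voxel_spacing(ch) - sp)) > 0) stop("channels must share spacing")
  }
  nz <- d[1]; ny <- d[2]; nx <- d[3]; nc <- length(channels)
  npage <- nz * nc

  desc <- sprintf(paste0(
    "ImageJ=1.53t\nimages=%d\nchannels=%d\nslices=%d\nhyperstack=true\n",
    "unit=micron\nspacing=%.17g\ndy=%.17g\ndx=%.17g\n"),
    npage, nc, nz, sp[1], sp[2], sp[3])
  desc_raw <- c(charToRaw(desc), as.raw(0))
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0))

  # layout: header | description | 2 rationals | page strips | IFDs
  off_desc <- 8
  off_xres <- off_desc + length(desc_raw)
  off_yres <- off_xres + 8
  strip_nbytes <- ny * nx * 2
  off_data <- off_yres + 8
  page_off <- off_data + (seq_len(npage) - 1) * strip_nbytes
  off_ifd0 <- off_data + npage * strip_nbytes
  ntag <- 13L
  ifd_size <- 2 + 12 * ntag + 4
  ifd_off <- off_ifd0 + (seq_len(npage) - 1) * ifd_size

  # resolution = pixels per micron, as a rational with 1e-7 um granularity
  res_rational <- function(dpix) c(u32_raw(1e7), u32_raw(round(dpix * 1e7)))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), u16_raw(42), u32_raw(ifd_off[1])), con)
  writeBin(desc_raw, con)
  writeBin(res_rational(sp[3]), con)  # XResolution <- dx
  writeBin(res_rational(sp[2]), con)  # YResolution <- dy
  for (z in seq_len(nz)) for (ci in seq_len(nc)) {
    plane <- channels[[ci]][z, , ]                 # ny x nx
    v <- round(pmin(pmax(t(plane), 0), 65535))     # clamp to uint16
    writeBin(u16_raw(as.vector(v)), con)           # rows (y) outer, x fastest
  }
  for (p in seq_len(npage)) {
    tags <- c(
      tiff_tag(256, 4, 1, u32_raw(nx)),            # ImageWidth
      tiff_tag(257, 4, 1, u32_raw(ny)),            # ImageLength
      tiff_tag(258, 3, 1, c(u16_raw(16), as.raw(c(0, 0)))),  # BitsPerSample
      tiff_tag(259, 3, 1, c(u16_raw(1), as.raw(c(0, 0)))),   # Compression=none
      tiff_tag(262, 3, 1, c(u16_raw(1), as.raw(c(0, 0)))),   # BlackIsZero
      tiff_tag(270, 2, length(desc_raw), u32_raw(off_desc)), # ImageDescription
      tiff_tag(273, 4, 1, u32_raw(page_off[p])),   # StripOffsets
      tiff_tag(277, 3, 1, c(u16_raw(1), as.raw(c(0, 0)))),   # SamplesPerPixel
      tiff_tag(278, 4, 1, u32_raw(ny)),            # RowsPerStrip
      tiff_tag(279, 4, 1, u32_raw(strip_nbytes)),  # StripByteCounts
      tiff_tag(282, 5, 1, u32_raw(off_xres)),      # XResolution
      tiff_tag(283, 5, 1, u32_raw(off_yres)),      # YResolution
      tiff_tag(296, 3, 1, c(u16_raw(1), as.raw(c(0, 0)))))   # unit: none
    nxt <- if (p < npage) ifd_off[p + 1] else 0
    writeBin(c(u16_raw(ntag), tags, u32_raw(nxt)), con)
  }
  invisible(path)
}

# parse one IFD; returns list of tags and offset of next IFD
read_ifd <- function(r, off, le) {
  n <- raw_uint(r[off + 1:2], 2, le)
  tags <- vector("list", n)
  for (i in seq_len(n)) {
    b <- off + 2 + (i - 1) * 12
    id <- raw_uint(r[b + 1:2], 2, le)
    type <- raw_uint(r[b + 3:4], 2, le)
    count <- raw_uint(r[b + 5:8], 4, le)
    val_raw <- r[b + 9:12]
    elt_size <- c(1, 1, 2, 4, 8)[type]
    nbytes <- elt_size * count
    data_raw <- if (!is.na(nbytes) && nbytes > 4) {
      doff <- raw_uint(val_raw, 4, le)
      r[doff + seq_len(nbytes)]
    } else val_raw[seq_len(max(nbytes, 1))]
    value <- switch(as.character(type),
      "1" = raw_uint(data_raw, 1, le),
      "2" = rawToChar(data_raw[data_raw != as.raw(0)]),
      "3" = raw_uint(data_raw, 2, le)[seq_len(count)],
      "4" = raw_uint(data_raw, 4, le)[seq_len(count)],
      "5" = {
        u <- raw_uint(data_raw, 4, le)
        u[seq(1, 2 * count, 2)] / u[seq(2, 2 * count, 2)]
      },
      NULL)
    tags[[i]] <- list(id = id, value = value)
  }
  nxt <- raw_uint(r[off + 2 + n * 12 + 1:4], 4, le)
  list(tags = tags, next_off = nxt)
}

tag_value <- function(tags, id, default = NULL) {
  for (t in tags) if (t$id == id) return(t$value)
  default
}

desc_key <- function(desc, key) {
  m <- regmatches(desc, regexec(sprintf("(?:^|\n)%s=([0-9.eE+-]+)", key), desc))[[1]]
  if (length(m) == 2) as.numeric(m[2]) else NA_real_
}

#' Read one channel of a multi-page TIFF stack
#'
#' @param path TIFF file path.
#' @param channel 1-based channel index.
#' @param spacing optional `(dz, dy, dx)` override in micrometres; takes
#'   precedence over any spacing found in the file metadata.
#' @return A [voxel_grid()].
#' @export
read_stack <- function(path, channel = 1L, spacing = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  r <- readBin(path, "raw", file.size(path))
  byte_order <- rawToChar(r[1:2])
  le <- identical(byte_order, "II")
  if (!le && !identical(byte_order, "MM")) stop("not a TIFF file")
  if (raw_uint(r[3:4], 2, le) != 42) stop("not a TIFF file")

  off <- raw_uint(r[5:8], 4, le)
  pages <- list()
  desc <- ""
  xres <- NA_real_; yres <- NA_real_
  while (off != 0) {
    ifd <- read_ifd(r, off, le)
    tags <- ifd$tags
    w <- tag_value(tags, 256); h <- tag_value(tags, 257)
    bits <- tag_value(tags, 258, 1)
    comp <- tag_value(tags, 259, 1)
    spp <- tag_value(tags, 277, 1)
    if (comp != 1) stop("only uncompressed TIFF is supported")
    if (spp != 1) stop("only single-sample (grayscale) TIFF is supported")
    if (!bits %in% c(8, 16)) stop("only 8- and 16-bit TIFF are supported")
    so <- tag_value(tags, 273); sb <- tag_value(tags, 279)
    strip_raw <- unlist(lapply(seq_along(so),
                               function(i) r[so[i] + seq_len(sb[i])]))
    v <- raw_uint(strip_raw, bits / 8, le)
    pages[[length(pages) + 1]] <- matrix(v, nrow = h, ncol = w, byrow = TRUE)
    d <- tag_value(tags, 270)
    if (!is.null(d) && nchar(desc) == 0) desc <- d
    if (is.na(xres)) xres <- tag_value(tags, 282, NA_real_)
    if (is.na(yres)) yres <- tag_value(tags, 283, NA_real_)
    off <- ifd$next_off
  }
  npage <- length(pages)
  if (npage == 0) stop("TIFF contains no pages")

  nc <- desc_key(desc, "channels"); if (is.na(nc)) nc <- 1
  nz <- desc_key(desc, "slices"); if (is.na(nz)) nz <- npage / nc
  if (nc * nz != npage) stop("page count inconsistent with channels/slices")
  channel <- as.integer(channel)
  if (channel < 1 || channel > nc)
    stop(sprintf("channel %d out of range (file has %d channel%s)",
                 channel, nc, if (nc == 1) "" else "s"))

  if (is.null(spacing)) {
    dz <- desc_key(desc, "spacing")
    dy <- desc_key(desc, "dy")
    dx <- desc_key(desc, "dx")
    if (is.na(dy) && !is.na(yres) && yres > 0) dy <- 1 / yres
    if (is.na(dx) && !is.na(xres) && xres > 0) dx <- 1 / xres
    if (anyNA(c(dz, dy, dx)))
      stop("no voxel spacing in file metadata; supply `spacing` explicitly")
    spacing <- c(dz, dy, dx)
  }
  nzz <- as.integer(nz)
  arr <- array(0, dim = c(nzz, nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_len(nzz)) arr[z, , ] <- pages[[(z - 1) * nc + channel]]
  voxel_grid(arr, spacing)
}
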