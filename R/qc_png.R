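# Tiny deterministic PNG encoder (8-bit RGB), used for QC overlays so that
# output does not depend on the availability or build flags of a graphics
# device in headless containers.  IDAT is a zlib stream via memCompress();
# chunk CRCs are computed with a table-driven CRC-32.

.crc32_table <- local({
  poly <- -306674912L  # 0xEDB88320 as a signed 32-bit integer
  vapply(0:255, function(n) {
    c <- as.integer(n)
    for (k in 1:8)
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(bitwShiftR(c, 1L), poly)
           else bitwShiftR(c, 1L)
    c
  }, integer(1))
})

crc32_raw <- function(r) {
  crc <- -1L
  tab <- .crc32_table
  for (b in as.integer(r))
    crc <- bitwXor(bitwShiftR(crc, 8L), tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  bitwXor(crc, -1L)
}

u32be_raw <- function(v) {
  v <- as.numeric(v); if (v < 0) v <- v + 2^32
  as.raw(c(v %/% 2^24, (v %/% 2^16) %% 256, (v %/% 256) %% 256, v %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be_raw(length(data)), body, u32be_raw(crc32_raw(body)))
}

# r, g, b: numeric matrices (rows = y, cols = x) with values in 0..255
write_png_rgb <- function(r, g, b, path) {
  h <- nrow(r); w <- ncol(r)
  px <- array(0L, dim = c(3, w, h))
  px[1, , ] <- t(as.integer(round(r)))
  px[2, , ] <- t(as.integer(round(g)))
  px[3, , ] <- t(as.integer(round(b)))
  scan <- as.raw(rbind(0L, matrix(as.vector(px), nrow = 3 * w)))  # filter 0
  ihdr <- c(u32be_raw(w), u32be_raw(h),
            as.raw(c(8, 2, 0, 0, 0)))  # 8-bit, truecolor RGB
  idat <- memCompress(as.vector(scan), type = "gzip")  # zlib stream
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}
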