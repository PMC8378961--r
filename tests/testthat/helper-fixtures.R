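# Small shared fixtures, built in code at test time.

tiny_config <- function(...) {
  model_config(scale = 2L, base_channels = 16L, n_ud_stages = 1L, ...)
}

# a smooth deterministic test image in [0,1]
wave_image <- function(h, w = h) {
  i <- matrix(seq_len(h), h, w)
  j <- matrix(seq_len(w), h, w, byrow = TRUE)
  0.5 + 0.4 * sin(i / 3) * cos(j / 4)
}

# --- independent PNG writer --------------------------------------------------
# Builds a PNG byte-by-byte in R (stored-deflate blocks, hand-computed CRC32
# and Adler-32), fully independent of the package's C++ codec, so it can act
# as an oracle for the reader.  8-bit only; color type 0 (gray) or 2 (RGB).

crc32_r <- function(bytes) {
  tab <- local({
    t <- integer(256)
    for (n in 0:255) {
      c <- n
      for (k in 1:8)
        c <- if (bitwAnd(c, 1L) == 1L) bitwXor(-306674912L, bitwShiftR(c, 1))
             else bitwShiftR(c, 1)
      t[n + 1] <- c
    }
    t
  })
  crc <- -1L
  for (b in as.integer(bytes))
    crc <- bitwXor(tab[bitwAnd(bitwXor(crc, b), 255L) + 1L],
                   bitwShiftR(crc, 8) |> bitwAnd(16777215L))
  bitwXor(crc, -1L)
}

u32_be <- function(x) {
  x <- as.numeric(x) %% 2^32
  as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 2^8) %% 256, x %% 256))
}

adler32_r <- function(bytes) {
  a <- 1; b <- 0
  for (v in as.integer(bytes)) {
    a <- (a + v) %% 65521
    b <- (b + a) %% 65521
  }
  b * 65536 + a
}

# raw zlib stream with stored (uncompressed) deflate blocks
zlib_stored <- function(bytes) {
  out <- as.raw(c(0x78, 0x01))
  n <- length(bytes)
  at <- 0L
  repeat {
    take <- min(65535L, n - at)
    final <- if (at + take >= n) 0x01 else 0x00
    out <- c(out, as.raw(final),
             as.raw(c(take %% 256, take %/% 256)),
             as.raw(c(255 - take %% 256, 255 - take %/% 256)),
             bytes[seq_len(take) + at])
    at <- at + take
    if (at >= n) break
  }
  c(out, u32_be(adler32_r(bytes)))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- crc32_r(body)
  c(u32_be(length(data)), body, u32_be(as.numeric(crc) %% 2^32))
}

# img: H x W matrix (gray) or H x W x 3 array (RGB), integer levels 0..255
write_png_oracle <- function(img, path) {
  d <- dim(img)
  rgb <- length(d) == 3
  H <- d[1]; W <- d[2]
  ctype <- if (rgb) 2L else 0L
  rows <- lapply(seq_len(H), function(i) {
    px <- if (rgb) as.integer(t(matrix(img[i, , ], W, 3)))
          else as.integer(img[i, ])
    as.raw(c(0L, px))
  })
  raw_data <- do.call(c, rows)
  bytes <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
             png_chunk("IHDR", c(u32_be(W), u32_be(H),
                                 as.raw(c(8L, ctype, 0L, 0L, 0L)))),
             png_chunk("IDAT", zlib_stored(raw_data)),
             png_chunk("IEND", raw()))
  writeBin(bytes, path)
  invisible(path)
}
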