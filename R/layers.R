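#' @title Network primitives
#' @description Thin R wrappers over the C++ convolution engine plus the
#'   activation, pooling, and pixel-rearrangement primitives the network is
#'   assembled from.  Feature maps are numeric arrays laid out
#'   `(H, W, C)` or `(H, W, C, B)`.
#' @name mcrn-primitives
NULL

dim4 <- function(x) {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    abort_shape("feature maps must be 3-D (H,W,C) or 4-D (H,W,C,B) arrays")
  if (length(d) == 3L) c(d, 1L) else d
}

#' 2-D convolution
#'
#' @param x feature array `(H,W,C[,B])`
#' @param w weights `(k,k,Cin,Cout)`
#' @param b optional bias of length `Cout`
#' @param stride,pad,dil stride, zero-padding and dilation
#' @return convolved feature array
#' @export
conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, dil = 1L) {
  cpp_conv2d(x, w, b, as.integer(stride), as.integer(pad), as.integer(dil))
}

#' Transposed 2-D convolution (deconvolution)
#'
#' Output side length is `(n-1)*stride + k - 2*pad`; with the
#' [scale_spec] geometry `k - 2*pad = stride` this is exactly `stride * n`.
#'
#' @inheritParams conv2d
#' @return upsampled feature array
#' @export
deconv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  cpp_deconv2d(x, w, b, as.integer(stride), as.integer(pad))
}

# parametric rectifier with one learnable slope per channel
prelu_fw <- function(z, a) {
  d <- dim4(z)
  slope <- rep(a, each = d[1] * d[2])
  pmax(z, 0) + slope * pmin(z, 0)
}

prelu_bw <- function(gy, z, a) {
  d <- dim4(z)
  slope <- rep(a, each = d[1] * d[2])
  neg <- z < 0
  gx <- gy * ifelse(neg, slope, 1)
  t <- gy * z * neg
  dim(t) <- c(d[1] * d[2], d[3] * d[4])
  ga <- rowSums(matrix(colSums(t), d[3], d[4]))
  list(gx = array(gx, dim(z)), ga = ga)
}

#' Subpixel rearrangement (pixel shuffle)
#'
#' Rearranges an `(h, w, r^2 * c)` map into `(r*h, r*w, c)`: channel
#' `c*r^2 + di*r + dj` lands at output position `(r*i + di, r*j + dj)`.
#' A pure permutation of the values; [pixel_unshuffle] is its exact inverse.
#'
#' @param x feature array `(H,W,r^2*C[,B])`
#' @param r integer upsampling factor
#' @return rearranged array `(r*H, r*W, C[,B])`
#' @export
pixel_shuffle <- function(x, r) {
  r <- as.integer(r)
  d0 <- dim(x); was3d <- length(d0) == 3L
  d <- dim4(x)
  if (d[3] %% (r * r) != 0L)
    abort_shape(sprintf("channel count %d is not divisible by r^2 = %d", d[3], r * r))
  C <- d[3] %/% (r * r)
  y <- x
  dim(y) <- c(d[1], d[2], r, r, C, d[4])      # (i, j, dj, di, c, b)
  y <- aperm(y, c(4, 1, 3, 2, 5, 6))          # (di, i, dj, j, c, b)
  dim(y) <- c(r * d[1], r * d[2], C, d[4])
  if (was3d) dim(y) <- c(r * d[1], r * d[2], C)
  y
}

#' Inverse subpixel rearrangement
#'
#' @param y feature array `(r*H, r*W, C[,B])`
#' @param r integer factor
#' @return array `(H, W, r^2*C[,B])`
#' @export
pixel_unshuffle <- function(y, r) {
  r <- as.integer(r)
  d0 <- dim(y); was3d <- length(d0) == 3L
  d <- dim4(y)
  if (d[1] %% r != 0L || d[2] %% r != 0L)
    abort_shape("spatial dimensions are not divisible by r")
  H <- d[1] %/% r; W <- d[2] %/% r
  x <- y
  dim(x) <- c(r, H, r, W, d[3], d[4])         # (di, i, dj, j, c, b)
  x <- aperm(x, c(2, 4, 3, 1, 5, 6))          # (i, j, dj, di, c, b)
  dim(x) <- c(H, W, r * r * d[3], d[4])
  if (was3d) dim(x) <- c(H, W, r * r * d[3])
  x
}

# concatenate feature arrays along the channel axis (3-D in -> 3-D out)
cat_channels <- function(lst) {
  d <- dim4(lst[[1]])
  was3d <- all(vapply(lst, function(x) length(dim(x)) == 3L, TRUE))
  cs <- vapply(lst, function(x) dim4(x)[3], 0L)
  for (x in lst) {
    dx <- dim4(x)
    if (dx[1] != d[1] || dx[2] != d[2] || dx[4] != d[4])
      abort_shape("feature maps to concatenate have mismatched spatial or batch dims")
  }
  out <- array(0, c(d[1], d[2], sum(cs), d[4]))
  at <- 0L
  for (i in seq_along(lst)) {
    x <- lst[[i]]
    dim(x) <- dim4(x)
    out[, , (at + 1):(at + cs[i]), ] <- x
    at <- at + cs[i]
  }
  if (was3d) dim(out) <- c(d[1], d[2], sum(cs))
  out
}

# split a channel-gradient back into same-width chunks
split_channels <- function(g, widths) {
  d <- dim4(g)
  dim(g) <- d
  out <- vector("list", length(widths))
  at <- 0L
  for (i in seq_along(widths)) {
    out[[i]] <- g[, , (at + 1):(at + widths[i]), , drop = FALSE]
    at <- at + widths[i]
  }
  out
}
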