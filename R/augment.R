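#' 16-fold corpus augmentation
#'
#' Each input image is emitted in the cross product of four rotations
#' (identity, 90, 180, 270 degrees) and four bicubic rescalings (factors
#' 1.0, 0.9, 0.8, 0.7), so `n` images become exactly `16 n` images.  The
#' emission order is deterministic: input order outermost, then scales,
#' with rotations varying fastest.
#'
#' @param images list of [image_gray] (may be empty)
#' @return list of [image_gray] of length `16 * length(images)`
#' @export
augment_corpus <- function(images) {
  if (!is.list(images)) abort_param("images must be a list")
  out <- vector("list", 16L * length(images))
  t <- 0L
  for (img in images) {
    for (sc in c(1, 0.9, 0.8, 0.7)) {
      base <- if (sc == 1) img else bicubic_resize(img, sc)
      for (k in 0:3) {
        t <- t + 1L
        out[[t]] <- if (k == 0L) base else rotate_image(base, k)
      }
    }
  }
  out
}

#' Paired low/high-resolution training patches
#'
#' The high-resolution image is cropped to the largest size divisible by
#' `scale`, degraded to its low-resolution counterpart by bicubic
#' downsampling, and tiled into co-located patch pairs on a 0-based,
#' row-major grid with the given stride (half-open windows).
#'
#' @param hr an [image_gray] (or matrix) high-resolution image
#' @param scale integer super-resolution factor
#' @param lr_patch low-resolution patch side in pixels
#' @param stride step between successive low-resolution patch origins
#' @return list of `patch_pair` objects, each with fields `lr` (p x p),
#'   `hr` (scale*p x scale*p), `scale`, and `hr_origin` (0-based row, col);
#'   empty if a patch does not fit
#' @export
extract_patch_pairs <- function(hr, scale, lr_patch, stride) {
  scale <- as.integer(scale)
  if (scale < 1) abort_param("scale must be a positive integer")
  if (lr_patch < 1 || stride < 1) abort_param("lr_patch and stride must be positive")
  m <- as_pixels(hr)
  depth <- if (inherits(hr, "image_gray")) hr$source_depth else 8L
  hh <- (nrow(m) %/% scale) * scale
  ww <- (ncol(m) %/% scale) * scale
  if (hh < 1 || ww < 1) return(list())
  m <- m[seq_len(hh), seq_len(ww), drop = FALSE]
  lr <- bicubic_resize(m, 1 / scale)
  hl <- nrow(lr); wl <- ncol(lr)
  if (lr_patch > hl || lr_patch > wl) return(list())
  r0 <- seq(0L, hl - lr_patch, by = stride)
  c0 <- seq(0L, wl - lr_patch, by = stride)
  out <- vector("list", length(r0) * length(c0))
  t <- 0L
  for (r in r0) for (cc in c0) {
    t <- t + 1L
    lp <- lr[(r + 1):(r + lr_patch), (cc + 1):(cc + lr_patch), drop = FALSE]
    hp <- m[(scale * r + 1):(scale * (r + lr_patch)),
            (scale * cc + 1):(scale * (cc + lr_patch)), drop = FALSE]
    out[[t]] <- structure(list(lr = image_gray(lp, depth),
                               hr = image_gray(hp, depth),
                               scale = scale,
                               hr_origin = c(scale * r, scale * cc)),
                          class = "patch_pair")
  }
  out
}
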