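#' @title Bicubic resampling
#' @description Separable bicubic interpolation with the Catmull-Rom-family
#'   kernel (a = -0.5), symmetric (reflect-with-edge) padding at the borders,
#'   and kernel widening (antialiasing) when downscaling -- the convention
#'   used throughout the super-resolution literature for producing
#'   low-resolution inputs from high-resolution references.
#' @name bicubic
NULL

# round half away from zero
rhaz <- function(x) sign(x) * floor(abs(x) + 0.5)

cubic_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# symmetric reflection of 0-based indices into [0, n)
reflect_index <- function(j, n) {
  if (n == 1L) return(rep(0L, length(j)))
  p <- 2L * n
  j <- j %% p
  ifelse(j >= n, p - 1L - j, j)
}

# dense (m x n) row-resampling matrix mapping length-n signals to length-m
resize_matrix <- function(n, m) {
  scale <- m / n
  ss <- min(scale, 1)            # kernel is widened by 1/scale when shrinking
  radius <- 2 / ss
  W <- matrix(0, m, n)
  for (i in seq_len(m) - 1L) {
    src <- (i + 0.5) / scale - 0.5
    j <- seq(ceiling(src - radius), floor(src + radius))
    w <- cubic_kernel((src - j) * ss) * ss
    keep <- w != 0
    j <- j[keep]; w <- w[keep]
    w <- w / sum(w)
    jj <- reflect_index(j, n) + 1L
    for (t in seq_along(jj)) W[i + 1L, jj[t]] <- W[i + 1L, jj[t]] + w[t]
  }
  W
}

#' Resize an image by bicubic interpolation
#'
#' Output dimensions are `round(dim * factor)` (half away from zero); values
#' are clipped back into \[0,1\].
#'
#' @param img an [image_gray] or numeric matrix
#' @param factor positive scale factor (e.g. `2`, `1/2`, `0.9`)
#' @return same type as `img`, resized
#' @export
bicubic_resize <- function(img, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) || factor <= 0)
    abort_param("factor must be a single positive number")
  m <- as_pixels(img)
  h <- nrow(m); w <- ncol(m)
  ho <- as.integer(rhaz(h * factor)); wo <- as.integer(rhaz(w * factor))
  if (ho < 1 || wo < 1)
    abort_param("requested output dimensions are below 1 pixel")
  out <- resize_matrix(h, ho) %*% m %*% t(resize_matrix(w, wo))
  out[out < 0] <- 0; out[out > 1] <- 1
  if (inherits(img, "image_gray")) image_gray(out, img$source_depth) else out
}

#' Rotate an image by multiples of 90 degrees
#'
#' @param img an [image_gray] or numeric matrix
#' @param k number of clockwise quarter turns (0-3)
#' @return same type as `img`, rotated
#' @export
rotate_image <- function(img, k) {
  m <- as_pixels(img)
  k <- as.integer(k) %% 4L
  out <- switch(k + 1L,
    m,
    t(m[nrow(m):1, , drop = FALSE]),                  # 90 cw
    m[nrow(m):1, ncol(m):1, drop = FALSE],            # 180
    t(m)[ncol(m):1, , drop = FALSE])                  # 270 cw
  if (inherits(img, "image_gray")) image_gray(out, img$source_depth) else out
}
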