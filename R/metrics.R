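#' Evaluation convention
#'
#' Pins every free choice of the scoring protocol: the intensity data range
#' L (255 for 8-bit scoring), the border shave removed from each side before
#' scoring (the super-resolution benchmark convention shaves `scale` pixels),
#' and the histogram bin count used by the entropy metric.
#'
#' @param data_range maximum intensity L (default 255)
#' @param border_shave pixels removed from each side before scoring
#' @param histogram_bins number of gray-level histogram bins
#' @return an `eval_convention` list
#' @export
eval_convention <- function(data_range = 255, border_shave = 0L,
                            histogram_bins = 256L) {
  if (border_shave < 0) abort_param("border_shave must be non-negative")
  if (data_range <= 0) abort_param("data_range must be positive")
  structure(list(data_range = data_range,
                 border_shave = as.integer(border_shave),
                 histogram_bins = as.integer(histogram_bins)),
            class = "eval_convention")
}

#' Remove a border from an image
#'
#' @param img an [image_gray] or matrix
#' @param shave pixels removed from each of the four sides
#' @return same type as `img`; shaving must leave at least 8x8 pixels
#' @export
shave_border <- function(img, shave) {
  if (shave == 0) return(img)
  m <- as_pixels(img)
  h <- nrow(m); w <- ncol(m)
  if (h - 2 * shave < 8 || w - 2 * shave < 8)
    abort_shape("border shave leaves fewer than 8x8 pixels")
  out <- m[(shave + 1):(h - shave), (shave + 1):(w - shave), drop = FALSE]
  if (inherits(img, "image_gray")) image_gray(out, img$source_depth) else out
}

# quantize a canonical [0,1] image to integer gray levels 0..L
quantize_levels <- function(img, L = 255) rhaz(as_pixels(img) * L)

metric_input <- function(ref, test, conv) {
  r <- as_pixels(ref); t <- as_pixels(test)
  if (!identical(dim(r), dim(t)))
    abort_shape("reference and test images have different dimensions")
  r <- shave_border(r, conv$border_shave)
  t <- shave_border(t, conv$border_shave)
  list(ref = rhaz(r * conv$data_range), test = rhaz(t * conv$data_range))
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(L^2 / MSE)` on quantized gray levels after border shave;
#' identical images score `Inf`.
#'
#' @param ref,test [image_gray] objects or matrices of equal size
#' @param conv an [eval_convention]
#' @return PSNR in decibels
#' @export
psnr <- function(ref, test, conv = eval_convention()) {
  q <- metric_input(ref, test, conv)
  mse <- mean((q$ref - q$test)^2)
  if (mse == 0) return(Inf)
  10 * log10(conv$data_range^2 / mse)
}

# 1-D Gaussian window, normalized
gauss_win <- function(size = 11L, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# valid-region windowed local mean via the separable Gaussian
ssim_filter <- function(m, g) {
  k <- length(g)
  w <- array(outer(g, g), c(k, k, 1L, 1L))
  x <- m; dim(x) <- c(nrow(m), ncol(m), 1L)
  y <- cpp_conv2d(x, w, NULL, 1L, 0L, 1L)
  matrix(y, dim(y)[1], dim(y)[2])
}

#' Structural similarity index
#'
#' Mean over 11x11 Gaussian-weighted (sigma = 1.5) local windows of the
#' luminance/contrast/structure product with stabilizers
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, computed on quantized gray levels
#' after border shave.
#'
#' @inheritParams psnr
#' @return SSIM score in \[-1, 1\]
#' @export
ssim <- function(ref, test, conv = eval_convention()) {
  q <- metric_input(ref, test, conv)
  if (nrow(q$ref) < 11 || ncol(q$ref) < 11)
    abort_shape("image is smaller than the 11x11 SSIM window")
  L <- conv$data_range
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  g <- gauss_win()
  muH <- ssim_filter(q$ref, g); muS <- ssim_filter(q$test, g)
  sH2 <- ssim_filter(q$ref^2, g) - muH^2
  sS2 <- ssim_filter(q$test^2, g) - muS^2
  sHS <- ssim_filter(q$ref * q$test, g) - muH * muS
  smap <- ((2 * muH * muS + C1) * (2 * sHS + C2)) /
    ((muH^2 + muS^2 + C1) * (sH2 + sS2 + C2))
  mean(smap)
}

#' Shannon entropy of the gray-level histogram
#'
#' `-sum(p * log2(p))` over the 256-bin histogram of the quantized image
#' (0 log 0 taken as 0), in bits.
#'
#' @param img an [image_gray] or matrix
#' @param conv an [eval_convention]
#' @return entropy in bits
#' @export
shannon_entropy <- function(img, conv = eval_convention()) {
  q <- quantize_levels(as_pixels(img), conv$data_range)
  counts <- tabulate(as.integer(q) + 1L, nbins = conv$histogram_bins)
  p <- counts[counts > 0] / length(q)
  -sum(p * log2(p))
}

#' Average gradient (sharpness proxy)
#'
#' Mean over the valid `(H-1) x (W-1)` region of
#' `sqrt((dx^2 + dy^2) / 2)` with forward differences, on the raw
#' intensities supplied.
#'
#' @param img an [image_gray] or matrix with at least 2x2 pixels
#' @return mean local gradient magnitude, intensity per pixel
#' @export
average_gradient <- function(img) {
  m <- as_pixels(img)
  h <- nrow(m); w <- ncol(m)
  if (h < 2 || w < 2) abort_shape("image must be at least 2x2")
  dx <- m[1:(h - 1), 2:w] - m[1:(h - 1), 1:(w - 1)]
  dy <- m[2:h, 1:(w - 1)] - m[1:(h - 1), 1:(w - 1)]
  mean(sqrt((dx^2 + dy^2) / 2))
}

#' Score one reference/test image pair
#'
#' Applies border shave and 8-bit quantization once, then computes PSNR,
#' SSIM, the Shannon entropy of the test image, and its average gradient
#' (the latter two on the quantized test image mapped back to \[0,1\], so
#' they match [shannon_entropy] and [average_gradient] invoked on the same
#' preprocessed image).  A pure function of its inputs.
#'
#' @inheritParams psnr
#' @return a `metrics_report` list: `psnr_db`, `ssim`, `entropy_bits`,
#'   `avg_gradient`
#' @export
evaluate_pair <- function(ref, test, conv = eval_convention()) {
  q <- metric_input(ref, test, conv)
  mse <- mean((q$ref - q$test)^2)
  p <- if (mse == 0) Inf else 10 * log10(conv$data_range^2 / mse)
  tq <- q$test / conv$data_range
  structure(list(
    psnr_db = p,
    ssim = ssim(ref, test, conv),
    entropy_bits = shannon_entropy(tq, eval_convention(conv$data_range, 0L,
                                                       conv$histogram_bins)),
    avg_gradient = average_gradient(tq)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("PSNR %.4f dB | SSIM %.4f | entropy %.4f bits | avg gradient %.6f\n",
              x$psnr_db, x$ssim, x$entropy_bits, x$avg_gradient))
  invisible(x)
}
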