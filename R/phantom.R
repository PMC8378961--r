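#' Parameters of the synthetic short-axis cardiac phantom
#'
#' The phantom emulates a bright-blood cine short-axis slice: a bright
#' circular blood pool inside a darker myocardial ring over a textured
#' background, with additive noise.  It is a stand-in for real cardiac MR
#' training data so the whole pipeline is exercisable without downloads.
#'
#' All radii and the ring center are expressed as fractions of the image
#' size; intensities live in \[0,1\].  The seed drives the noise only: a
#' phantom with `noise_sigma = 0` is seed-independent (the background texture
#' is a fixed deterministic pattern).
#'
#' @param seed integer noise seed
#' @param size image side length in pixels (square)
#' @param ring_center (row, col) center as fractions of size
#' @param outer_radius,inner_radius myocardial ring radii, fractions of size,
#'   with `0 < inner < outer < 0.5`
#' @param blood_intensity,myocardium_intensity,background_intensity tissue
#'   intensities in \[0,1\]; bright-blood convention requires blood > myocardium
#' @param texture_amplitude amplitude of the deterministic background texture
#' @param noise_sigma standard deviation of the additive noise
#' @param noise_model `"gaussian"` (default) or `"rician"` (magnitude-MR noise)
#' @return a `phantom_params` list
#' @export
phantom_params <- function(seed = 1L, size = 128L, ring_center = c(0.5, 0.5),
                           outer_radius = 0.3, inner_radius = 0.2,
                           blood_intensity = 0.85, myocardium_intensity = 0.35,
                           background_intensity = 0.15,
                           texture_amplitude = 0.05, noise_sigma = 0.02,
                           noise_model = c("gaussian", "rician")) {
  noise_model <- match.arg(noise_model)
  if (!(inner_radius > 0 && inner_radius < outer_radius && outer_radius < 0.5))
    abort_param("radii must satisfy 0 < inner_radius < outer_radius < 0.5")
  if (!(blood_intensity > myocardium_intensity))
    abort_param("bright-blood convention requires blood_intensity > myocardium_intensity")
  ints <- c(blood_intensity, myocardium_intensity, background_intensity)
  if (any(ints < 0 | ints > 1)) abort_param("intensities must lie in [0,1]")
  if (size < 8) abort_param("size must be at least 8 pixels")
  if (noise_sigma < 0 || texture_amplitude < 0)
    abort_param("noise_sigma and texture_amplitude must be non-negative")
  structure(list(seed = as.integer(seed), size = as.integer(size),
                 ring_center = ring_center, outer_radius = outer_radius,
                 inner_radius = inner_radius, blood_intensity = blood_intensity,
                 myocardium_intensity = myocardium_intensity,
                 background_intensity = background_intensity,
                 texture_amplitude = texture_amplitude,
                 noise_sigma = noise_sigma, noise_model = noise_model),
            class = "phantom_params")
}

# evaluate a local RNG expression without disturbing the caller's stream
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# fixed smooth texture pattern over unit-square coordinates, range ~[-1,1]
phantom_texture <- function(x, y) {
  (sin(2 * pi * (7 * x) + 1.3) * sin(2 * pi * (5 * y) + 0.7) +
     sin(2 * pi * 3 * (x + y) + 0.4)) / 2
}

#' Generate a synthetic cardiac phantom
#'
#' @param params a [phantom_params] object
#' @return an [image_gray] of side `params$size`
#' @export
generate_phantom <- function(params) {
  if (!inherits(params, "phantom_params"))
    params <- do.call(phantom_params, as.list(params))
  n <- params$size
  fr <- (seq_len(n) - 0.5) / n
  x <- matrix(fr, n, n, byrow = TRUE)   # column fraction
  y <- matrix(fr, n, n)                 # row fraction
  img <- params$background_intensity +
    params$texture_amplitude * phantom_texture(x, y)
  d2 <- (y - params$ring_center[1])^2 + (x - params$ring_center[2])^2
  img[d2 < params$outer_radius^2] <- params$myocardium_intensity
  img[d2 < params$inner_radius^2] <- params$blood_intensity
  if (params$noise_sigma > 0) {
    img <- with_local_seed(params$seed, {
      if (params$noise_model == "gaussian") {
        img + matrix(stats::rnorm(n * n, sd = params$noise_sigma), n, n)
      } else {
        n1 <- matrix(stats::rnorm(n * n, sd = params$noise_sigma), n, n)
        n2 <- matrix(stats::rnorm(n * n, sd = params$noise_sigma), n, n)
        sqrt((img + n1)^2 + n2^2)
      }
    })
  }
  image_gray(img, source_depth = 8L, clip = TRUE)
}

#' Generate a corpus of randomized phantoms
#'
#' Geometry and intensities are jittered per phantom from a deterministic
#' per-index seed derived from `seed`, so the corpus is reproducible and
#' individual phantoms differ in ring position, radii, contrast, and noise
#' realization.
#'
#' @param n number of phantoms
#' @param size image side length in pixels
#' @param seed corpus seed
#' @param noise_sigma noise level passed to every phantom
#' @return list of [image_gray]
#' @export
phantom_corpus <- function(n, size = 128L, seed = 1L, noise_sigma = 0.02) {
  lapply(seq_len(n), function(i) {
    si <- as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
    p <- with_local_seed(si, {
      outer <- stats::runif(1, 0.24, 0.34)
      phantom_params(
        seed = si, size = size,
        ring_center = c(stats::runif(1, 0.4, 0.6), stats::runif(1, 0.4, 0.6)),
        outer_radius = outer,
        inner_radius = outer * stats::runif(1, 0.55, 0.75),
        blood_intensity = stats::runif(1, 0.75, 0.95),
        myocardium_intensity = stats::runif(1, 0.25, 0.45),
        background_intensity = stats::runif(1, 0.08, 0.22),
        texture_amplitude = stats::runif(1, 0.02, 0.08),
        noise_sigma = noise_sigma)
    })
    generate_phantom(p)
  })
}
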