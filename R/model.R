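#' Scale-factor geometry
#'
#' The paired deconvolution/convolution geometry that realizes an exact
#' spatial factor s: kernel - 2*pad = stride = s, so a deconvolution of an
#' h x w map yields s*h x s*w and the paired convolution inverts the shape.
#' Factor 2 uses kernel 4 / stride 2 / pad 1; factors 3 and 4 follow the
#' standard back-projection convention (7/3/2 and 8/4/2).
#'
#' @param s integer scale factor, one of 2, 3, 4
#' @return list with fields `s`, `kernel`, `stride`, `pad`
#' @export
scale_spec <- function(s) {
  s <- as.integer(s)
  geom <- switch(as.character(s),
                 "2" = c(4L, 2L, 1L),
                 "3" = c(7L, 3L, 2L),
                 "4" = c(8L, 4L, 2L),
                 abort_config(sprintf("scale factor %s is not supported (need 2, 3 or 4)", s)))
  list(s = s, kernel = geom[1], stride = geom[2], pad = geom[3])
}

#' Network architecture configuration
#'
#' @param scale integer super-resolution factor (2, 3 or 4)
#' @param base_channels width of the feature maps (default 64)
#' @param n_ud_stages number of up/down back-projection stages (default 3)
#' @param n_rab number of residual attention blocks in the RA module
#' @param dilation_rates strictly increasing dilation rates of the
#'   multichannel feature-extraction branches
#' @param attention_channels bottleneck width of the channel-attention
#'   squeeze; defaults to `base_channels / 16` (at least 1)
#' @return a `model_config` list
#' @export
model_config <- function(scale = 2L, base_channels = 64L, n_ud_stages = 3L,
                         n_rab = 3L, dilation_rates = c(1L, 3L, 5L),
                         attention_channels = NULL) {
  sp <- scale_spec(scale)
  base_channels <- as.integer(base_channels)
  n_ud_stages <- as.integer(n_ud_stages)
  n_rab <- as.integer(n_rab)
  dilation_rates <- as.integer(dilation_rates)
  if (base_channels < 1) abort_config("base_channels must be positive")
  if (n_ud_stages < 1) abort_config("n_ud_stages must be at least 1")
  if (n_rab < 1) abort_config("n_rab must be at least 1")
  if (length(dilation_rates) < 1 || any(diff(dilation_rates) <= 0))
    abort_config("dilation_rates must be strictly increasing")
  if (is.null(attention_channels))
    attention_channels <- max(1L, base_channels %/% 16L)
  attention_channels <- as.integer(attention_channels)
  if (attention_channels < 1) abort_config("attention_channels must be positive")
  structure(list(scale = sp, base_channels = base_channels,
                 n_ud_stages = n_ud_stages, n_rab = n_rab,
                 dilation_rates = dilation_rates,
                 attention_channels = attention_channels),
            class = "model_config")
}

# the full weight geometry, derived once from the config; this is the single
# source of truth used by build_model and checkpoint validation
param_shapes <- function(config) {
  C <- config$base_channels
  Ca <- config$attention_channels
  k <- config$scale$kernel
  N <- config$n_ud_stages
  g2 <- config$scale$s^2
  sh <- list()
  add_layer <- function(nm, kk, cin, cout, act = TRUE) {
    sh[[paste0(nm, ".w")]] <<- c(kk, kk, cin, cout)
    sh[[paste0(nm, ".b")]] <<- cout
    if (act) sh[[paste0(nm, ".a")]] <<- cout
  }
  add_layer("init", 3L, 1L, C)
  for (r in config$dilation_rates) add_layer(paste0("dil.r", r), 3L, C, C)
  add_layer("dil.fuse", 1L, length(config$dilation_rates) * C, C)
  for (n in seq_len(N)) {
    pre <- paste0("s", n, ".")
    add_layer(paste0(pre, "reduce"), 1L, n * C, C)
    add_layer(paste0(pre, "p"), k, C, C)
    add_layer(paste0(pre, "g"), k, C, C)
    add_layer(paste0(pre, "q"), k, C, C)
    add_layer(paste0(pre, "k"), 1L, n * C, C)
  }
  add_layer("cascade", 1L, N * C, C)
  for (i in seq_len(config$n_rab)) {
    pre <- paste0("rab", i, ".")
    add_layer(paste0(pre, "conv"), 3L, C, C)
    add_layer(paste0(pre, "sq"), 1L, C, Ca, act = FALSE)
    add_layer(paste0(pre, "ex"), 1L, Ca, C, act = FALSE)
  }
  add_layer("mid", 3L, C, C)
  add_layer("recon.pre", 3L, C, g2 * C)
  add_layer("recon.out", 3L, C, 1L, act = FALSE)
  sh
}

#' Build a model with freshly initialized weights
#'
#' Convolution and deconvolution weights use seeded variance-scaling
#' (fan-in) normal initialization, biases start at zero, and parametric
#' rectifier slopes start at 0.25.  The same seed always yields bit-identical
#' weights.
#'
#' @param config a [model_config]
#' @param seed integer initialization seed
#' @return an object of class `mcrn_model` with fields `config` and `params`
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  if (!inherits(config, "model_config")) abort_config("config must be a model_config")
  shapes <- param_shapes(config)
  params <- with_local_seed(seed, {
    lapply(stats::setNames(names(shapes), names(shapes)), function(nm) {
      d <- shapes[[nm]]
      if (endsWith(nm, ".w")) {
        fan_in <- prod(d[1:3])
        array(stats::rnorm(prod(d), sd = sqrt(2 / fan_in)), dim = d)
      } else if (endsWith(nm, ".a")) {
        rep(0.25, d)
      } else {
        numeric(d)
      }
    })
  })
  structure(list(config = config, params = params, seed = as.integer(seed)),
            class = "mcrn_model")
}

#' @export
print.mcrn_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf(
    "<mcrn_model x%d: %d channels, %d up/down stages, %d RABs, %d parameters>\n",
    x$config$scale$s, x$config$base_channels, x$config$n_ud_stages,
    x$config$n_rab, np))
  invisible(x)
}

config_json <- function(config) {
  jsonlite::toJSON(list(scale = config$scale$s,
                        base_channels = config$base_channels,
                        n_ud_stages = config$n_ud_stages,
                        n_rab = config$n_rab,
                        dilation_rates = config$dilation_rates,
                        attention_channels = config$attention_channels),
                   auto_unbox = TRUE)
}

config_from_json <- function(txt) {
  x <- jsonlite::fromJSON(txt)
  model_config(scale = x$scale, base_channels = x$base_channels,
               n_ud_stages = x$n_ud_stages, n_rab = x$n_rab,
               dilation_rates = x$dilation_rates,
               attention_channels = x$attention_channels)
}

#' Save a model checkpoint
#'
#' A checkpoint is a single file holding the architecture configuration (as
#' JSON text), every named weight array, and optionally the optimizer state,
#' RNG state, and training history, so training can resume bit-exactly.
#'
#' @param model an `mcrn_model`
#' @param path output file path
#' @param optimizer,rng,history optional training state to embed
#' @return `path`, invisibly
#' @export
save_checkpoint <- function(model, path, optimizer = NULL, rng = NULL,
                            history = NULL) {
  obj <- list(format = "mcrn-checkpoint-1",
              config_json = as.character(config_json(model$config)),
              params = model$params, optimizer = optimizer, rng = rng,
              history = history)
  dir <- dirname(path)
  if (!dir.exists(dir)) abort_io(sprintf("output directory '%s' does not exist", dir))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file
#' @param config optional [model_config] the checkpoint must match; a
#'   mismatch is a configuration error, never a silent reshape
#' @param full if `TRUE`, return the whole checkpoint (model + optimizer +
#'   rng + history) instead of just the model
#' @return an `mcrn_model`, or a list when `full = TRUE`
#' @export
load_checkpoint <- function(path, config = NULL, full = FALSE) {
  if (!file.exists(path)) abort_io(sprintf("checkpoint '%s' does not exist", path))
  obj <- tryCatch(readRDS(path), error = function(e)
    abort_format(sprintf("'%s' is not a readable checkpoint: %s", path, conditionMessage(e))))
  if (!identical(obj$format, "mcrn-checkpoint-1"))
    abort_format(sprintf("'%s' is not an mcrn checkpoint", path))
  ck_config <- config_from_json(obj$config_json)
  if (!is.null(config) && !identical(unclass(ck_config), unclass(config)))
    abort_config("checkpoint architecture does not match the requested configuration")
  shapes <- param_shapes(ck_config)
  for (nm in names(shapes)) {
    got <- obj$params[[nm]]
    want <- shapes[[nm]]
    actual <- if (is.null(dim(got))) length(got) else dim(got)
    if (is.null(got) || !identical(as.integer(actual), as.integer(want)))
      abort_config(sprintf("checkpoint weight '%s' has the wrong geometry", nm))
  }
  model <- structure(list(config = ck_config, params = obj$params),
                     class = "mcrn_model")
  if (full) list(model = model, optimizer = obj$optimizer, rng = obj$rng,
                 history = obj$history)
  else model
}
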