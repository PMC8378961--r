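#' @title MCRN network assembly
#' @description The network is a fixed directed acyclic graph: an initial
#'   3x3 feature-extraction layer, a dilated multichannel residual block,
#'   `n_ud_stages` densely cascaded up/down back-projection stages with
#'   explicit error feedback, a residual attention (RA) module on the
#'   reduced low-resolution-grid cascade, and a subpixel reconstruction
#'   head.  Forward and backward passes are hand-written against the same
#'   cached graph, so gradients are exact and the whole model trains on a
#'   CPU with no external deep-learning runtime.
#' @name mcrn-network
NULL

# ---- tape ------------------------------------------------------------------
# A "net environment" carries params, config, a cache of layer inputs and
# pre-activations keyed by use-site (shared weights may have several use
# sites), and an accumulator of parameter gradients.

net_env <- function(model) {
  env <- new.env(parent = emptyenv())
  env$params <- model$params
  env$config <- model$config
  env$cache <- new.env(parent = emptyenv())
  env$grads <- new.env(parent = emptyenv())
  env
}

acc_grad <- function(env, nm, g) {
  cur <- env$grads[[nm]]
  env$grads[[nm]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

# one convolution/deconvolution use-site, with optional parametric rectifier
lay_fw <- function(env, key, nm, x, kind, stride = 1L, pad = 0L, dil = 1L,
                   act = TRUE) {
  p <- env$params
  w <- p[[paste0(nm, ".w")]]
  b <- p[[paste0(nm, ".b")]]
  if (is.null(w)) abort_shape(sprintf("model has no layer '%s'", nm))
  z <- if (kind == "conv") cpp_conv2d(x, w, b, stride, pad, dil)
       else cpp_deconv2d(x, w, b, stride, pad)
  y <- if (act) prelu_fw(z, p[[paste0(nm, ".a")]]) else z
  env$cache[[key]] <- list(nm = nm, x = x, z = z, kind = kind,
                           stride = stride, pad = pad, dil = dil, act = act)
  y
}

lay_bw <- function(env, key, gy) {
  cc <- env$cache[[key]]
  p <- env$params
  gz <- if (cc$act) {
    r <- prelu_bw(gy, cc$z, p[[paste0(cc$nm, ".a")]])
    acc_grad(env, paste0(cc$nm, ".a"), r$ga)
    r$gx
  } else gy
  r <- if (cc$kind == "conv")
    cpp_conv2d_bwd(cc$x, p[[paste0(cc$nm, ".w")]], gz, cc$stride, cc$pad, cc$dil)
  else
    cpp_deconv2d_bwd(cc$x, p[[paste0(cc$nm, ".w")]], gz, cc$stride, cc$pad)
  acc_grad(env, paste0(cc$nm, ".w"), r$gw)
  acc_grad(env, paste0(cc$nm, ".b"), r$gb)
  r$gx
}

# ---- channel attention -----------------------------------------------------

# squeeze-excite gating: global average descriptor -> 1x1 squeeze -> ReLU ->
# 1x1 excite -> logistic gate in (0,1) -> channel-wise rescaling of the input
ca_core <- function(u, W1, b1, W2, b2) {
  d <- dim4(u)
  um <- u; dim(um) <- c(d[1] * d[2], d[3] * d[4])
  pool <- matrix(colMeans(um), d[3], d[4])
  s1 <- crossprod(W1, pool) + b1
  r1 <- pmax(s1, 0)
  s2 <- crossprod(W2, r1) + b2
  g <- 1 / (1 + exp(-s2))
  y <- u * rep(g, each = d[1] * d[2])
  list(y = array(y, dim(u)), pool = pool, s1 = s1, r1 = r1, g = g, dims = d)
}

att_fw <- function(env, key, nm, u) {
  p <- env$params
  ws <- p[[paste0(nm, ".sq.w")]]; we <- p[[paste0(nm, ".ex.w")]]
  C <- dim(ws)[3]; Ca <- dim(ws)[4]
  r <- ca_core(u, matrix(ws, C, Ca), p[[paste0(nm, ".sq.b")]],
               matrix(we, Ca, C), p[[paste0(nm, ".ex.b")]])
  r$nm <- nm; r$u <- u
  env$cache[[key]] <- r
  r$y
}

att_bw <- function(env, key, gy) {
  cc <- env$cache[[key]]
  p <- env$params
  d <- cc$dims
  ws <- p[[paste0(cc$nm, ".sq.w")]]; we <- p[[paste0(cc$nm, ".ex.w")]]
  C <- dim(ws)[3]; Ca <- dim(ws)[4]
  W1 <- matrix(ws, C, Ca); W2 <- matrix(we, Ca, C)
  area <- d[1] * d[2]
  gu1 <- gy * rep(cc$g, each = area)
  t <- gy * cc$u
  dim(t) <- c(area, d[3] * d[4])
  gg <- matrix(colSums(t), d[3], d[4])
  gs2 <- gg * cc$g * (1 - cc$g)
  gW2 <- cc$r1 %*% t(gs2)
  gb2 <- rowSums(gs2)
  gr1 <- W2 %*% gs2
  gs1 <- gr1 * (cc$s1 > 0)
  gW1 <- cc$pool %*% t(gs1)
  gb1 <- rowSums(gs1)
  gpool <- W1 %*% gs1
  gu2 <- rep(gpool, each = area) / area
  acc_grad(env, paste0(cc$nm, ".sq.w"), array(gW1, c(1, 1, C, Ca)))
  acc_grad(env, paste0(cc$nm, ".sq.b"), gb1)
  acc_grad(env, paste0(cc$nm, ".ex.w"), array(gW2, c(1, 1, Ca, C)))
  acc_grad(env, paste0(cc$nm, ".ex.b"), gb2)
  array(gu1 + gu2, dim(cc$u))
}

# ---- full forward / backward ----------------------------------------------

# x: (H, W, 1, B) low-resolution batch; returns (sH, sW, 1, B) raw output
net_forward <- function(env, x) {
  cfg <- env$config
  sp <- cfg$scale
  st <- sp$stride; kp <- sp$pad
  N <- cfg$n_ud_stages
  f0 <- lay_fw(env, "init", "init", x, "conv", 1L, 1L, 1L)
  branches <- lapply(cfg$dilation_rates, function(r)
    lay_fw(env, paste0("dil.r", r), paste0("dil.r", r), f0, "conv", 1L, r, r))
  fu <- lay_fw(env, "dil.fuse", "dil.fuse", cat_channels(branches), "conv")
  d0 <- fu + f0
  Ls <- list(d0); Hs <- list()
  for (n in seq_len(N)) {
    pre <- paste0("s", n, ".")
    lred <- lay_fw(env, paste0(pre, "reduce"), paste0(pre, "reduce"),
                   cat_channels(Ls), "conv")
    h0 <- lay_fw(env, paste0(pre, "p@up"), paste0(pre, "p"), lred, "deconv", st, kp)
    l0 <- lay_fw(env, paste0(pre, "g@up"), paste0(pre, "g"), h0, "conv", st, kp)
    el <- l0 - lred
    h1 <- lay_fw(env, paste0(pre, "q@up"), paste0(pre, "q"), el, "deconv", st, kp)
    Hs[[n]] <- h0 + h1
    h2 <- lay_fw(env, paste0(pre, "k"), paste0(pre, "k"), cat_channels(Hs), "conv")
    l1 <- lay_fw(env, paste0(pre, "g@d1"), paste0(pre, "g"), h2, "conv", st, kp)
    h3 <- lay_fw(env, paste0(pre, "p@dn"), paste0(pre, "p"), l1, "deconv", st, kp)
    eh <- h3 - h2
    l2 <- lay_fw(env, paste0(pre, "g@d2"), paste0(pre, "g"), eh, "conv", st, kp)
    Ls[[n + 1]] <- l1 + l2
  }
  t0 <- lay_fw(env, "cascade", "cascade", cat_channels(Ls[-1]), "conv")
  r <- t0
  for (i in seq_len(cfg$n_rab)) {
    zi <- lay_fw(env, paste0("rab", i, ".conv"), paste0("rab", i, ".conv"),
                 r, "conv", 1L, 1L, 1L)
    r <- r + att_fw(env, paste0("rab", i, ".att"), paste0("rab", i), zi)
  }
  m <- lay_fw(env, "mid", "mid", r, "conv", 1L, 1L, 1L)
  ra <- t0 + m
  pre <- lay_fw(env, "recon.pre", "recon.pre", ra, "conv", 1L, 1L, 1L)
  sh <- pixel_shuffle(pre, sp$s)
  lay_fw(env, "recon.out", "recon.out", sh, "conv", 1L, 1L, 1L, act = FALSE)
}

net_backward <- function(env, gout) {
  cfg <- env$config
  C <- cfg$base_channels
  N <- cfg$n_ud_stages
  g_sh <- lay_bw(env, "recon.out", gout)
  g_pre <- pixel_unshuffle(g_sh, cfg$scale$s)
  g_ra <- lay_bw(env, "recon.pre", g_pre)
  g_t0 <- g_ra
  g_r <- lay_bw(env, "mid", g_ra)
  for (i in rev(seq_len(cfg$n_rab))) {
    g_zi <- att_bw(env, paste0("rab", i, ".att"), g_r)
    g_r <- g_r + lay_bw(env, paste0("rab", i, ".conv"), g_zi)
  }
  g_t0 <- g_t0 + g_r
  g_tcat <- lay_bw(env, "cascade", g_t0)
  gLs <- c(list(0), split_channels(g_tcat, rep(C, N)))
  gHs <- vector("list", N)
  for (n in rev(seq_len(N))) {
    pre <- paste0("s", n, ".")
    # down-block
    g_ln <- gLs[[n + 1]]
    g_eh <- lay_bw(env, paste0(pre, "g@d2"), g_ln)
    g_h2 <- -g_eh
    g_l1 <- g_ln + lay_bw(env, paste0(pre, "p@dn"), g_eh)
    g_h2 <- g_h2 + lay_bw(env, paste0(pre, "g@d1"), g_l1)
    parts <- split_channels(lay_bw(env, paste0(pre, "k"), g_h2), rep(C, n))
    for (j in seq_len(n))
      gHs[[j]] <- if (is.null(gHs[[j]])) parts[[j]] else gHs[[j]] + parts[[j]]
    # up-block
    g_hn <- gHs[[n]]
    g_el <- lay_bw(env, paste0(pre, "q@up"), g_hn)
    g_lred <- -g_el
    g_h0 <- g_hn + lay_bw(env, paste0(pre, "g@up"), g_el)
    g_lred <- g_lred + lay_bw(env, paste0(pre, "p@up"), g_h0)
    parts <- split_channels(lay_bw(env, paste0(pre, "reduce"), g_lred), rep(C, n))
    for (j in seq_len(n))
      gLs[[j]] <- if (identical(gLs[[j]], 0) || is.null(gLs[[j]]))
        parts[[j]] else gLs[[j]] + parts[[j]]
  }
  g_d0 <- gLs[[1]]
  g_ccat <- lay_bw(env, "dil.fuse", g_d0)
  parts <- split_channels(g_ccat, rep(C, length(cfg$dilation_rates)))
  g_f0 <- g_d0
  for (i in seq_along(cfg$dilation_rates))
    g_f0 <- g_f0 + lay_bw(env, paste0("dil.r", cfg$dilation_rates[i]), parts[[i]])
  g_x <- lay_bw(env, "init", g_f0)
  invisible(g_x)
}

# loss + gradients for one batch; x, y are (H,W,1,B) arrays
mcrn_loss_grads <- function(model, x, y) {
  env <- net_env(model)
  pred <- net_forward(env, x)
  if (!identical(dim(pred), dim(y)))
    abort_shape("prediction and target shapes differ")
  diff <- pred - y
  loss <- mean(abs(diff))
  gout <- array(sign(diff) / length(diff), dim(diff))
  net_backward(env, gout)
  grads <- as.list(env$grads)
  list(loss = loss, grads = grads, pred = pred)
}

# ---- public block operations ----------------------------------------------

as_feature <- function(x, channels = NULL) {
  if (inherits(x, "image_gray")) x <- x$pixels
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    abort_shape("expected a matrix or a 3-D/4-D feature array")
  if (!is.null(channels) && dim4(x)[3] != channels)
    abort_shape(sprintf("expected %d channels, got %d", channels, dim4(x)[3]))
  x
}

#' Initial feature extraction
#'
#' A 3x3 convolution (stride 1, pad 1) lifting the single-channel image to
#' `base_channels` feature maps, followed by the parametric rectifier.
#'
#' @param x an [image_gray], matrix, or `(H,W,1)` array
#' @param model an `mcrn_model`
#' @return `(H, W, base_channels)` feature array
#' @export
init_features <- function(x, model) {
  x <- as_feature(x, channels = 1L)
  env <- net_env(model)
  lay_fw(env, "init", "init", x, "conv", 1L, 1L, 1L)
}

#' Dilated multichannel residual block
#'
#' Three parallel 3x3 convolutions at the configured dilation rates (padding
#' equal to the rate, so spatial dims are preserved), channel-concatenated,
#' fused back to `base_channels` by a 1x1 convolution with activation, and
#' added to the input.  The rate-5 branch sees an 11x11 receptive field.
#'
#' @param f `(H, W, base_channels)` feature array
#' @param model an `mcrn_model`
#' @return feature array of the same shape
#' @export
dilated_multichannel_block <- function(f, model) {
  f <- as_feature(f, channels = model$config$base_channels)
  env <- net_env(model)
  branches <- lapply(model$config$dilation_rates, function(r)
    lay_fw(env, paste0("dil.r", r), paste0("dil.r", r), f, "conv", 1L, r, r))
  fu <- lay_fw(env, "dil.fuse", "dil.fuse", cat_channels(branches), "conv")
  fu + f
}

#' Channel attention gate
#'
#' Per-channel global-average descriptor, 1x1 squeeze to the bottleneck
#' width, rectifier, 1x1 excite back to the channel count, logistic gate in
#' (0,1), channel-wise multiplication of the input.
#'
#' @param f `(H, W, C[,B])` feature array
#' @param w_squeeze,b_squeeze squeeze weights `(1,1,C,Ca)` (or `C x Ca`
#'   matrix) and bias
#' @param w_excite,b_excite excite weights `(1,1,Ca,C)` (or matrix) and bias
#' @return gated feature array of the same shape
#' @export
channel_attention <- function(f, w_squeeze, b_squeeze, w_excite, b_excite) {
  f <- as_feature(f)
  d <- dim4(f)
  W1 <- if (is.matrix(w_squeeze)) w_squeeze else matrix(w_squeeze, d[3])
  W2 <- if (is.matrix(w_excite)) w_excite else matrix(w_excite, ncol(W1))
  if (nrow(W1) != d[3] || ncol(W2) != d[3])
    abort_shape("attention weights do not match the channel count")
  ca_core(f, W1, b_squeeze, W2, b_excite)$y
}

#' Residual attention block
#'
#' 3x3 convolution with activation, channel attention, then a short skip
#' adding the block input.
#'
#' @param f `(H, W, base_channels)` feature array
#' @param model an `mcrn_model`
#' @param index which RAB's weights to use (1-based)
#' @return feature array of the same shape
#' @export
residual_attention_block <- function(f, model, index = 1L) {
  f <- as_feature(f, channels = model$config$base_channels)
  env <- net_env(model)
  nm <- paste0("rab", index)
  if (is.null(model$params[[paste0(nm, ".conv.w")]]))
    abort_config(sprintf("model has no residual attention block %d", index))
  z <- lay_fw(env, paste0(nm, ".conv"), paste0(nm, ".conv"), f, "conv", 1L, 1L, 1L)
  f + att_fw(env, paste0(nm, ".att"), nm, z)
}

#' Up-projection block with error feedback
#'
#' Concatenates the low-resolution-grid history, reduces it to
#' `base_channels` with a 1x1 convolution, upsamples by deconvolution,
#' re-downsamples, and corrects the upsampled map with the upsampled
#' low-resolution residual.
#'
#' @param L_history non-empty list of `(H, W, base_channels)` feature arrays
#' @param model an `mcrn_model`
#' @param stage which up/down stage's weights to use (1-based); the history
#'   length must equal `stage`
#' @return list with the output `H` plus intermediates `lred`, `h0`, `l0`,
#'   `e_l`, `h1`
#' @export
up_block <- function(L_history, model, stage = length(L_history)) {
  if (length(L_history) == 0) abort_shape("L_history must be non-empty")
  if (length(L_history) != stage)
    abort_shape("history length must match the stage index")
  env <- net_env(model)
  sp <- model$config$scale
  pre <- paste0("s", stage, ".")
  lred <- lay_fw(env, "reduce", paste0(pre, "reduce"),
                 cat_channels(L_history), "conv")
  h0 <- lay_fw(env, "p", paste0(pre, "p"), lred, "deconv", sp$stride, sp$pad)
  l0 <- lay_fw(env, "g", paste0(pre, "g"), h0, "conv", sp$stride, sp$pad)
  el <- l0 - lred
  h1 <- lay_fw(env, "q", paste0(pre, "q"), el, "deconv", sp$stride, sp$pad)
  list(H = h0 + h1, lred = lred, h0 = h0, l0 = l0, e_l = el, h1 = h1)
}

#' Down-projection block with error feedback
#'
#' Concatenates the high-resolution-grid history, fuses it to
#' `base_channels` with a 1x1 convolution, downsamples, re-upsamples, and
#' corrects the downsampled map with the downsampled high-resolution
#' residual.
#'
#' @param H_history non-empty list of `(sH, sW, base_channels)` feature arrays
#' @param model an `mcrn_model`
#' @param stage which up/down stage's weights to use (1-based)
#' @return list with the output `L` plus intermediates `h2`, `l1`, `h3`,
#'   `e_h`, `l2`
#' @export
down_block <- function(H_history, model, stage = length(H_history)) {
  if (length(H_history) == 0) abort_shape("H_history must be non-empty")
  if (length(H_history) != stage)
    abort_shape("history length must match the stage index")
  env <- net_env(model)
  sp <- model$config$scale
  pre <- paste0("s", stage, ".")
  h2 <- lay_fw(env, "k", paste0(pre, "k"), cat_channels(H_history), "conv")
  l1 <- lay_fw(env, "g1", paste0(pre, "g"), h2, "conv", sp$stride, sp$pad)
  h3 <- lay_fw(env, "p", paste0(pre, "p"), l1, "deconv", sp$stride, sp$pad)
  eh <- h3 - h2
  l2 <- lay_fw(env, "g2", paste0(pre, "g"), eh, "conv", sp$stride, sp$pad)
  list(L = l1 + l2, h2 = h2, l1 = l1, h3 = h3, e_h = eh, l2 = l2)
}

#' Reconstruction head
#'
#' 3x3 convolution widening to `s^2 * base_channels` channels with
#' activation, subpixel rearrangement by the scale factor, and a final
#' linear 3x3 convolution to one channel.  Values are returned raw
#' (unclipped); clipping to \[0,1\] happens only when an image leaves the
#' graph (see [mcrn_forward]).
#'
#' @param cascade `(H, W, base_channels)` reduced cascade feature array
#' @param model an `mcrn_model`
#' @return numeric matrix `(s*H, s*W)` of raw intensities
#' @export
reconstruct <- function(cascade, model) {
  cascade <- as_feature(cascade, channels = model$config$base_channels)
  env <- net_env(model)
  pre <- lay_fw(env, "recon.pre", "recon.pre", cascade, "conv", 1L, 1L, 1L)
  sh <- pixel_shuffle(pre, model$config$scale$s)
  out <- lay_fw(env, "recon.out", "recon.out", sh, "conv", 1L, 1L, 1L, act = FALSE)
  matrix(out, dim(out)[1], dim(out)[2])
}

#' Super-resolve an image with a model
#'
#' Runs the full forward pass: initial features, dilated multichannel block,
#' densely cascaded up/down back-projection stages, residual attention on
#' the reduced cascade, subpixel reconstruction.  Deterministic for fixed
#' weights.
#'
#' @param lr an [image_gray] or matrix, at least 8x8
#' @param model an `mcrn_model`
#' @return an [image_gray] of `s` times the input size, clipped to \[0,1\]
#' @export
mcrn_forward <- function(lr, model) {
  depth <- if (inherits(lr, "image_gray")) lr$source_depth else 8L
  x <- as_feature(lr, channels = 1L)
  d <- dim4(x)
  if (d[1] < 8 || d[2] < 8)
    abort_shape("input must be at least 8x8 pixels")
  dim(x) <- c(d[1], d[2], 1L, 1L)
  env <- net_env(model)
  out <- net_forward(env, x)
  image_gray(matrix(out, dim(out)[1], dim(out)[2]), source_depth = depth,
             clip = TRUE)
}
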