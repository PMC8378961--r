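#' Training configuration
#'
#' The optimization recipe: L1 loss and Adam with learning rate 1e-4,
#' beta1 = 0.9, beta2 = 0.999, eps = 1e-8, at a constant learning rate (only
#' the initial rate is prescribed; no decay is applied).
#'
#' @param lr learning rate
#' @param beta1,beta2,eps Adam moment decay rates and stabilizer
#' @param batch_size patch pairs per optimization step
#' @param max_steps number of optimization steps
#' @param seed RNG seed driving shuffling (and nothing else)
#' @param loss loss name; only `"L1"` is supported
#' @param checkpoint_every write a checkpoint every this many steps when a
#'   checkpoint directory is given (0 disables periodic checkpoints)
#' @param val_fraction fraction of pairs carved off (by seed) into a
#'   validation split whose L1 loss is recorded at checkpoints
#' @param target_psnr optional early-stop: every `eval_every` steps the mean
#'   training-pair PSNR is measured and training stops once it exceeds this
#' @param eval_every cadence of the `target_psnr` check
#' @return a `train_config` list
#' @export
train_config <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         batch_size = 16L, max_steps = 1000L, seed = 1L,
                         loss = "L1", checkpoint_every = 0L, val_fraction = 0,
                         target_psnr = NULL, eval_every = 250L) {
  # lr = 0 is allowed as a null-update diagnostic; negative rates are not
  if (lr < 0) abort_config("lr must be non-negative")
  if (beta1 < 0 || beta1 >= 1 || beta2 < 0 || beta2 >= 1)
    abort_config("beta1 and beta2 must lie in [0,1)")
  if (!(eps > 0)) abort_config("eps must be positive")
  if (!identical(loss, "L1")) abort_config("only the L1 loss is supported")
  if (val_fraction < 0 || val_fraction >= 1)
    abort_config("val_fraction must lie in [0,1)")
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 batch_size = as.integer(batch_size),
                 max_steps = as.integer(max_steps), seed = as.integer(seed),
                 loss = loss, checkpoint_every = as.integer(checkpoint_every),
                 val_fraction = val_fraction, target_psnr = target_psnr,
                 eval_every = as.integer(eval_every)),
            class = "train_config")
}

#' Desk-scale preset
#'
#' A CPU-feasible scaled-down profile fixed a priori: 16 feature channels,
#' 2 up/down stages, 12-pixel low-resolution patches, batch 8, and learning
#' rate 1e-3 (the full-size recipe's 1e-4 is scaled up tenfold because the
#' desk model is orders of magnitude smaller and trains for a few thousand
#' steps rather than hundreds of thousands).
#'
#' @param scale super-resolution factor
#' @param max_steps optimization steps (at most 2000 in the desk profile)
#' @param seed training seed
#' @return list with `model` ([model_config]), `train` ([train_config]),
#'   `patch` and `stride` (low-resolution patch geometry)
#' @export
desk_preset <- function(scale = 2L, max_steps = 800L, seed = 1L) {
  list(model = model_config(scale = scale, base_channels = 16L, n_ud_stages = 2L),
       train = train_config(lr = 1e-3, batch_size = 8L,
                            max_steps = as.integer(max_steps), seed = seed),
       patch = 12L, stride = 12L)
}

#' Mean absolute (L1) loss
#'
#' @param pred,target numeric arrays of identical shape
#' @return mean absolute difference over all elements
#' @export
l1_loss <- function(pred, target) {
  pred <- if (inherits(pred, "image_gray")) pred$pixels else pred
  target <- if (inherits(target, "image_gray")) target$pixels else target
  if (!identical(dim(pred), dim(target)))
    abort_shape("pred and target shapes differ")
  mean(abs(pred - target))
}

# one Adam update; state holds first/second moments and the step counter
adam_step <- function(params, grads, state, cfg) {
  if (is.null(state)) {
    state <- list(m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0),
                  t = 0L)
  }
  state$t <- state$t + 1L
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - cfg$lr * mhat / (sqrt(vhat) + cfg$eps)
  }
  list(params = params, state = state)
}

# stack patch pairs into (p, p, 1, B) input and (sp, sp, 1, B) target arrays
stack_pairs <- function(pairs, idx) {
  p <- nrow(pairs[[idx[1]]]$lr$pixels)
  s <- pairs[[idx[1]]]$scale
  B <- length(idx)
  x <- array(0, c(p, p, 1L, B))
  y <- array(0, c(s * p, s * p, 1L, B))
  for (b in seq_along(idx)) {
    x[, , 1L, b] <- pairs[[idx[b]]]$lr$pixels
    y[, , 1L, b] <- pairs[[idx[b]]]$hr$pixels
  }
  list(x = x, y = y)
}

train_pair_psnr <- function(model, pairs) {
  mean(vapply(pairs, function(pr) {
    sr <- mcrn_forward(pr$lr, model)
    psnr(pr$hr, sr, eval_convention(border_shave = 0L))
  }, 0))
}

#' Train a model on patch pairs
#'
#' Adam updates with the configured hyperparameters, fixed-seed shuffling,
#' constant learning rate, optional periodic checkpoints, and bit-exact
#' resumption: restarting from a checkpoint reproduces the loss sequence an
#' uninterrupted run would have produced.
#'
#' @param model an `mcrn_model` (all pairs must share its scale)
#' @param pairs non-empty list of `patch_pair` objects from
#'   [extract_patch_pairs]
#' @param cfg a [train_config]
#' @param checkpoint_dir directory for periodic checkpoints (`NULL` disables)
#' @param resume path to a checkpoint to resume from
#' @param verbose print a structured log line every 100 steps to stderr
#' @return list with `model` (trained), `history` (data frame of step, loss,
#'   and validation loss where measured), and `optimizer` (final Adam state)
#' @export
train_model <- function(model, pairs, cfg = train_config(),
                        checkpoint_dir = NULL, resume = NULL, verbose = FALSE) {
  if (length(pairs) == 0) abort_config("pairs must be non-empty")
  scales <- unique(vapply(pairs, function(p) p$scale, 0L))
  if (length(scales) != 1 || scales != model$config$scale$s)
    abort_config("all pairs must share the model's scale factor")
  params <- model$params
  state <- NULL
  start_step <- 0L
  history <- list()
  set.seed(cfg$seed)
  n_val <- floor(cfg$val_fraction * length(pairs))
  val_idx <- if (n_val > 0) sample(length(pairs), n_val) else integer(0)
  train_idx <- setdiff(seq_along(pairs), val_idx)
  if (length(train_idx) == 0) abort_config("val_fraction leaves no training pairs")
  if (!is.null(resume)) {
    ck <- load_checkpoint(resume, config = model$config, full = TRUE)
    params <- ck$model$params
    state <- ck$optimizer$state
    start_step <- ck$optimizer$step
    if (!is.null(ck$rng)) assign(".Random.seed", ck$rng, envir = globalenv())
    if (!is.null(ck$history)) history <- ck$history
  }
  B <- cfg$batch_size
  for (step in seq.int(start_step + 1L, length.out = max(0L, cfg$max_steps - start_step))) {
    idx <- if (length(train_idx) <= B) {
      rep_len(train_idx, B)
    } else sample(train_idx, B)
    batch <- stack_pairs(pairs, idx)
    work <- structure(list(config = model$config, params = params),
                      class = "mcrn_model")
    lg <- mcrn_loss_grads(work, batch$x, batch$y)
    upd <- adam_step(params, lg$grads, state, cfg)
    params <- upd$params
    state <- upd$state
    rec <- list(step = step, loss = lg$loss, val_loss = NA_real_)
    ckpt_due <- cfg$checkpoint_every > 0 && step %% cfg$checkpoint_every == 0
    if (ckpt_due && n_val > 0) {
      vb <- stack_pairs(pairs, val_idx)
      venv <- net_env(structure(list(config = model$config, params = params),
                                class = "mcrn_model"))
      rec$val_loss <- l1_loss(net_forward(venv, vb$x), vb$y)
    }
    history[[length(history) + 1L]] <- rec
    if (verbose && step %% 100L == 0)
      message(sprintf("step %d loss %.6f lr %g time %s", step, lg$loss, cfg$lr,
                      format(Sys.time(), "%H:%M:%S")))
    cur <- structure(list(config = model$config, params = params),
                     class = "mcrn_model")
    if (ckpt_due && !is.null(checkpoint_dir)) {
      if (!dir.exists(checkpoint_dir)) dir.create(checkpoint_dir, recursive = TRUE)
      save_checkpoint(cur, file.path(checkpoint_dir, sprintf("step%06d.rds", step)),
                      optimizer = list(state = state, step = step),
                      rng = get(".Random.seed", envir = globalenv()),
                      history = history)
    }
    if (!is.null(cfg$target_psnr) && step %% cfg$eval_every == 0) {
      if (train_pair_psnr(cur, pairs[train_idx]) > cfg$target_psnr) break
    }
  }
  hist_df <- do.call(rbind, lapply(history, function(r)
    data.frame(step = r$step, loss = r$loss, val_loss = r$val_loss)))
  list(model = structure(list(config = model$config, params = params),
                         class = "mcrn_model"),
       history = hist_df,
       optimizer = list(state = state,
                        step = if (length(history)) history[[length(history)]]$step else 0L))
}

#' Evaluate a model against the bicubic baseline
#'
#' Each high-resolution image is cropped to a size divisible by the model's
#' scale, bicubic-degraded, super-resolved by the model, and scored against
#' the original under the given convention; the bicubic upsampling of the
#' same degraded input is scored alongside as the non-learned baseline.
#'
#' @param model an `mcrn_model`
#' @param hr_images list of [image_gray] high-resolution references
#' @param conv an [eval_convention]; defaults to border shave = scale
#' @return list with `per_image` (data frame) and `summary` (named means)
#' @export
evaluate_model <- function(model, hr_images,
                           conv = eval_convention(border_shave = model$config$scale$s)) {
  s <- model$config$scale$s
  rows <- lapply(seq_along(hr_images), function(i) {
    hr <- hr_images[[i]]
    m <- as_pixels(hr)
    hh <- (nrow(m) %/% s) * s; ww <- (ncol(m) %/% s) * s
    m <- m[seq_len(hh), seq_len(ww), drop = FALSE]
    lr <- bicubic_resize(m, 1 / s)
    sr <- mcrn_forward(lr, model)
    bic <- bicubic_resize(lr, s)
    rp_sr <- evaluate_pair(m, sr$pixels, conv)
    rp_bi <- evaluate_pair(m, bic, conv)
    data.frame(image = i,
               psnr_sr = rp_sr$psnr_db, ssim_sr = rp_sr$ssim,
               entropy_sr = rp_sr$entropy_bits, avg_grad_sr = rp_sr$avg_gradient,
               psnr_bicubic = rp_bi$psnr_db, ssim_bicubic = rp_bi$ssim,
               entropy_bicubic = rp_bi$entropy_bits,
               avg_grad_bicubic = rp_bi$avg_gradient)
  })
  per_image <- do.call(rbind, rows)
  summary <- as.list(colMeans(per_image[, -1]))
  list(per_image = per_image, summary = summary)
}
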