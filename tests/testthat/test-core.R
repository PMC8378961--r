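test_that("build_model allocates the declared geometry and is seed-deterministic", {
  m <- build_model(model_config(scale = 2), seed = 7)
  p <- m$params
  expect_equal(dim(p$init.w), c(3L, 3L, 1L, 64L))
  expect_equal(dim(p$rab1.conv.w), c(3L, 3L, 64L, 64L))
  expect_equal(dim(p$rab1.sq.w), c(1L, 1L, 64L, 4L))   # 64 -> 4 bottleneck
  expect_equal(dim(p$rab1.ex.w), c(1L, 1L, 4L, 64L))   # 4 -> 64 expand
  expect_equal(dim(p$s1.p.w), c(4L, 4L, 64L, 64L))     # kernel 4, x2 geometry
  expect_equal(dim(p$s2.reduce.w), c(1L, 1L, 128L, 64L))  # 2-stage cascade
  expect_equal(dim(p$s3.k.w), c(1L, 1L, 192L, 64L))
  expect_equal(dim(p$cascade.w), c(1L, 1L, 192L, 64L))
  expect_equal(dim(p$recon.pre.w), c(3L, 3L, 64L, 256L))  # 64 -> s^2 * 64
  expect_equal(dim(p$recon.out.w), c(3L, 3L, 64L, 1L))
  expect_identical(m$params, build_model(model_config(scale = 2), seed = 7)$params)
  expect_false(identical(m$params, build_model(model_config(scale = 2), seed = 8)$params))
})

test_that("unsupported scale factors and bad configs error", {
  expect_error(model_config(scale = 5), class = "mcrn_config_error")
  expect_error(model_config(dilation_rates = c(3, 1, 5)), class = "mcrn_config_error")
  expect_error(model_config(n_ud_stages = 0), class = "mcrn_config_error")
})

test_that("initial feature extraction lifts 1 -> base channels preserving space", {
  m <- build_model(tiny_config(), seed = 1)
  f <- init_features(matrix(runif(32 * 32), 32, 32), m)
  expect_equal(dim(f), c(32L, 32L, 16L))
  z <- init_features(matrix(0.5, 16, 16), zero_model(m))
  expect_true(all(z == 0))
  expect_error(init_features(array(0.1, c(8, 8, 3)), m), class = "mcrn_shape_error")
})

test_that("initial layer is shift-equivariant on the interior (wrap translation)", {
  m <- build_model(tiny_config(), seed = 2)
  x <- matrix(runif(16 * 16), 16, 16)
  xs <- rbind(x[16, ], x[1:15, ])           # wrap-shift rows down by 1
  f <- init_features(x, m)
  fs <- init_features(xs, m)
  # interior outputs shift identically (borders touch the zero pad)
  expect_equal(fs[3:15, 2:15, ], f[2:14, 2:15, ], tolerance = 1e-12)
})

test_that("dilated multichannel block: shape, residual identity, receptive field", {
  m <- build_model(tiny_config(), seed = 3)
  f <- array(runif(32 * 32 * 16), c(32, 32, 16))
  out <- dilated_multichannel_block(f, m)
  expect_equal(dim(out), dim(f))
  # zero fusion weights and bias -> exact identity
  mz <- m
  mz$params$dil.fuse.w[] <- 0
  mz$params$dil.fuse.b[] <- 0
  expect_equal(dilated_multichannel_block(f, mz), f, tolerance = 0)
  # rate-5 branch: gradient support of one output pixel spans offsets {-5,0,5}
  w <- m$params$dil.r5.w
  x <- array(0, c(23, 23, 16))
  gy <- array(0, c(23, 23, 16)); gy[12, 12, 1] <- 1
  gx <- mcrn:::cpp_conv2d_bwd(x, w, gy, 1L, 5L, 5L)$gx
  hit <- which(apply(gx != 0, c(1, 2), any), arr.ind = TRUE)
  offs <- unique(as.vector(hit - 12))
  expect_setequal(offs, c(-5, 0, 5))        # 11x11 effective footprint
})

test_that("channel attention gates as documented and matches the dense oracle", {
  set.seed(4)
  C <- 16; Ca <- 4
  f <- array(runif(4 * 4 * C), c(4, 4, C))
  W1 <- matrix(rnorm(C * Ca), C, Ca); b1 <- rnorm(Ca)
  W2 <- matrix(rnorm(Ca * C), Ca, C); b2 <- rnorm(C)
  got <- channel_attention(f, W1, b1, W2, b2)
  expect_lt(max(abs(got - oracle_channel_attention(f, W1, b1, W2, b2))), 1e-12)
  # all-zero gate path: logistic(0) = 0.5 exactly
  half <- channel_attention(f, W1 * 0, b1 * 0, W2 * 0, b2 * 0)
  expect_equal(half, f * 0.5, tolerance = 0)
  # gates strictly inside (0,1): output strictly between 0 and the input
  pos <- array(runif(4 * 4 * C, 0.1, 1), c(4, 4, C))
  gated <- channel_attention(pos, W1, b1, W2, b2)
  expect_true(all(gated > 0 & gated < pos))
})

test_that("residual attention blocks reduce to the identity when zeroed", {
  m <- build_model(tiny_config(), seed = 5)
  f <- array(runif(16 * 16 * 16), c(16, 16, 16))
  expect_equal(dim(residual_attention_block(f, m, 1)), dim(f))
  mz <- m
  for (i in 1:3) {
    mz$params[[paste0("rab", i, ".conv.w")]][] <- 0
    mz$params[[paste0("rab", i, ".conv.b")]][] <- 0
  }
  r <- f
  for (i in 1:3) r <- residual_attention_block(r, mz, i)
  expect_equal(r, f, tolerance = 0)
  # the full RA module (3 RABs + mid conv + long skip) with all weights zero
  mz2 <- zero_model(m)
  r2 <- f
  for (i in 1:3) r2 <- residual_attention_block(r2, mz2, i)
  mid <- prelu_ref(conv2d(r2, mz2$params$mid.w, mz2$params$mid.b, 1, 1, 1),
                   mz2$params$mid.a)
  expect_equal(f + mid, f, tolerance = 0)
})

test_that("up/down blocks scale space by s with error feedback", {
  m <- build_model(model_config(scale = 2, base_channels = 16, n_ud_stages = 2),
                   seed = 6)
  L <- array(runif(16 * 16 * 16), c(16, 16, 16))
  up <- up_block(list(L), m, stage = 1)
  expect_equal(dim(up$H), c(32L, 32L, 16L))
  down <- down_block(list(up$H), m, stage = 1)
  expect_equal(dim(down$L), c(16L, 16L, 16L))
  # stage-2 fusion consumes the 2-map history
  up2 <- up_block(list(L, down$L), m, stage = 2)
  expect_equal(dim(up2$H), c(32L, 32L, 16L))
  # all-zero weights and biases give all-zero outputs
  mz <- zero_model(m)
  expect_true(all(up_block(list(L), mz, 1)$H == 0))
  expect_true(all(down_block(list(up$H), mz, 1)$L == 0))
  expect_error(up_block(list(), m), class = "mcrn_shape_error")
})

test_that("error feedback vanishes exactly when the residual is zero", {
  m <- build_model(tiny_config(), seed = 7)
  # arrange constant maps so the low-resolution residual e_l is exactly zero:
  # zero reduce/p/g weights with matched biases, q keeps random weights but
  # zero bias, so H = H0 must hold exactly
  mz <- m
  for (nm in c("s1.reduce", "s1.p", "s1.g")) mz$params[[paste0(nm, ".w")]][] <- 0
  mz$params$s1.reduce.b[] <- 0.3
  mz$params$s1.p.b[] <- 0.7
  mz$params$s1.g.b[] <- 0.3   # matches the reduced map -> e_l = 0
  mz$params$s1.q.b[] <- 0
  L <- array(runif(8 * 8 * 16), c(8, 8, 16))
  up <- up_block(list(L), mz, 1)
  expect_equal(max(abs(up$e_l)), 0)
  expect_identical(up$H, up$h0)
  expect_gt(max(abs(up$H)), 0)              # non-degenerate check
  # dual arrangement for the down block: e_h = 0 with zero bias in the
  # residual-path convolution forces L = L1
  md <- m
  for (nm in c("s1.k", "s1.p")) md$params[[paste0(nm, ".w")]][] <- 0
  md$params$s1.k.b[] <- 0.6
  md$params$s1.p.b[] <- 0.6   # H3 matches H2 -> e_h = 0
  md$params$s1.g.b[] <- 0
  H <- array(runif(16 * 16 * 16), c(16, 16, 16))
  down <- down_block(list(H), md, 1)
  expect_equal(max(abs(down$e_h)), 0)
  expect_identical(down$L, down$l1)
  expect_gt(max(abs(down$L)), 0)
})

test_that("reconstruction head: shapes and degenerate bias", {
  m <- build_model(model_config(scale = 2), seed = 8)
  cascade <- array(runif(16 * 16 * 64), c(16, 16, 64))
  out <- reconstruct(cascade, m)
  expect_equal(dim(out), c(32L, 32L))
  # all weights zero, final bias beta -> constant image of value beta
  mz <- zero_model(m)
  mz$params$recon.out.b[] <- 0.3
  outz <- reconstruct(cascade, mz)
  expect_equal(unique(as.vector(outz)), 0.3)
})

test_that("full forward pass: shape contract and determinism", {
  m <- build_model(tiny_config(), seed = 9)
  img <- image_gray(wave_image(24))
  sr <- mcrn_forward(img, m)
  expect_equal(dim(sr$pixels), c(48L, 48L))
  expect_identical(mcrn_forward(img, m), sr)
  for (s in 3:4) {
    ms <- build_model(model_config(scale = s, base_channels = 16, n_ud_stages = 1),
                      seed = 9)
    expect_equal(dim(mcrn_forward(img, ms)$pixels), c(24L, 24L) * s)
  }
  expect_error(mcrn_forward(matrix(0.5, 4, 4), m), class = "mcrn_shape_error")
})

test_that("1-stage forward equals the hand-composed chain of block operations", {
  m <- build_model(tiny_config(n_rab = 3), seed = 10)
  img <- wave_image(12)
  p <- m$params
  f0 <- init_features(img, m)
  d0 <- dilated_multichannel_block(f0, m)
  up <- up_block(list(d0), m, 1)
  down <- down_block(list(up$H), m, 1)
  t0 <- prelu_ref(conv2d(down$L, p$cascade.w, p$cascade.b), p$cascade.a)
  r <- t0
  for (i in 1:3) r <- residual_attention_block(r, m, i)
  mid <- prelu_ref(conv2d(r, p$mid.w, p$mid.b, 1, 1, 1), p$mid.a)
  out <- reconstruct(t0 + mid, m)
  out <- pmin(pmax(out, 0), 1)
  full <- mcrn_forward(img, m)
  expect_lt(max(abs(full$pixels - out)), 1e-6)
})

test_that("gradient flows back to the initial layer through the whole cascade", {
  m <- build_model(tiny_config(), seed = 11)
  x <- array(runif(8 * 8), c(8, 8, 1, 1))
  y <- array(runif(16 * 16), c(16, 16, 1, 1))
  lg <- mcrn:::mcrn_loss_grads(m, x, y)
  expect_gt(max(abs(lg$grads$init.w)), 0)
  expect_gt(max(abs(lg$grads$dil.r1.w)), 0)
  expect_gt(max(abs(lg$grads$s1.q.w)), 0)
})

test_that("checkpoints round-trip and reject mismatched configurations", {
  dir <- withr::local_tempdir()
  m <- build_model(tiny_config(), seed = 12)
  p <- file.path(dir, "m.rds")
  save_checkpoint(m, p)
  back <- load_checkpoint(p)
  expect_identical(back$params, m$params)
  expect_identical(unclass(back$config), unclass(m$config))
  expect_error(load_checkpoint(p, config = model_config(scale = 3)),
               class = "mcrn_config_error")
  expect_error(load_checkpoint(file.path(dir, "none.rds")),
               class = "mcrn_io_error")
})
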