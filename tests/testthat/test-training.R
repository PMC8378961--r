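test_that("L1 loss matches its closed forms", {
  a <- array(runif(32), c(4, 4, 2))
  expect_equal(l1_loss(a, a), 0)
  expect_equal(l1_loss(a + 0.2, a), 0.2)
  expect_equal(l1_loss(array(c(0, 0.5), c(2, 1, 1)),
                       array(c(0.5, 1.0), c(2, 1, 1))), 0.5)
  expect_error(l1_loss(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "mcrn_shape_error")
})

test_that("Adam updates match a hand-coded oracle over several steps", {
  set.seed(31)
  cfg <- train_config(lr = 1e-2, seed = 1)
  w0 <- array(rnorm(12), c(2, 2, 3, 1))
  gs <- lapply(1:3, function(i) array(rnorm(12), c(2, 2, 3, 1)))
  params <- list(w = w0)
  state <- NULL
  for (g in gs) {
    upd <- mcrn:::adam_step(params, list(w = g), state, cfg)
    params <- upd$params; state <- upd$state
  }
  expect_equal(params$w, oracle_adam(w0, gs, 1e-2, 0.9, 0.999, 1e-8),
               tolerance = 1e-12)
  # bias-corrected first step with a unit gradient moves by lr/(1 + eps')
  upd1 <- mcrn:::adam_step(list(w = w0), list(w = w0 * 0 + 1), NULL, cfg)
  expect_equal(unique(as.vector(w0 - upd1$params$w)),
               1e-2 * 1 / (1 + 1e-8), tolerance = 1e-12)
})

test_that("lr = 0 performs the null update", {
  ph <- phantom_corpus(1, size = 32, seed = 3)
  pairs <- extract_patch_pairs(ph[[1]], 2, 8, 8)
  m <- build_model(tiny_config(), seed = 1)
  fit <- train_model(m, pairs, train_config(lr = 0, batch_size = 2,
                                            max_steps = 3, seed = 1))
  expect_identical(fit$model$params, m$params)
})

test_that("training is seed-deterministic and checkpoint resume is bit-exact", {
  dir <- withr::local_tempdir()
  ph <- phantom_corpus(2, size = 32, seed = 4)
  pairs <- unlist(lapply(ph, extract_patch_pairs, scale = 2, lr_patch = 8,
                         stride = 8), recursive = FALSE)
  m <- build_model(tiny_config(), seed = 2)
  cfg <- train_config(lr = 1e-3, batch_size = 3, max_steps = 6, seed = 9,
                      checkpoint_every = 3L)
  full <- train_model(m, pairs, cfg, checkpoint_dir = dir)
  again <- train_model(m, pairs, cfg)
  expect_identical(full$history$loss, again$history$loss)
  expect_identical(full$model$params, again$model$params)
  resumed <- train_model(m, pairs, cfg,
                         resume = file.path(dir, "step000003.rds"))
  expect_identical(resumed$history$loss[4], full$history$loss[4])
  expect_identical(resumed$model$params, full$model$params)
})

test_that("loss decreases over 50 fixed-batch steps in >= 90% of seeds", {
  ph <- phantom_corpus(1, size = 32, seed = 6)
  pairs <- extract_patch_pairs(ph[[1]], 2, 8, 8)   # 16 pairs, one fixed batch
  wins <- 0L
  for (seed in 1:10) {
    m <- build_model(tiny_config(), seed = seed)
    fit <- train_model(m, pairs,
                       train_config(lr = 1e-4, batch_size = length(pairs),
                                    max_steps = 50, seed = seed))
    if (fit$history$loss[50] <= fit$history$loss[1]) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("training rejects scale mismatches and empty corpora", {
  m <- build_model(tiny_config(), seed = 1)
  expect_error(train_model(m, list(), train_config()),
               class = "mcrn_config_error")
  ph <- phantom_corpus(1, size = 36, seed = 1)
  wrong <- extract_patch_pairs(ph[[1]], 3, 8, 8)
  expect_error(train_model(m, wrong, train_config()),
               class = "mcrn_config_error")
})

test_that("evaluation orders a degenerate model below bicubic, deterministically", {
  ph <- phantom_corpus(3, size = 32, seed = 7)
  m <- zero_model(build_model(tiny_config(), seed = 1))   # constant output
  ev <- evaluate_model(m, ph)
  expect_true(all(ev$per_image$psnr_sr < ev$per_image$psnr_bicubic))
  ev2 <- evaluate_model(m, ph)
  expect_identical(ev$per_image, ev2$per_image)
  expect_named(ev$summary, c("psnr_sr", "ssim_sr", "entropy_sr", "avg_grad_sr",
                             "psnr_bicubic", "ssim_bicubic", "entropy_bicubic",
                             "avg_grad_bicubic"))
})
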