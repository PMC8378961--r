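test_that("PSNR closed forms hold on 8-bit levels", {
  conv <- eval_convention()
  x <- image_gray(wave_image(16))
  expect_identical(psnr(x, x, conv), Inf)
  # uniform +1 gray-level offset: MSE = 1 -> 20*log10(255) = 48.1308 dB
  ref <- matrix(sample(0:254, 256, replace = TRUE) / 255, 16, 16)
  test <- ref + 1 / 255
  expect_equal(psnr(ref, test, conv), 48.1308, tolerance = 1e-4)
  # full-range error: MSE = L^2 -> 0 dB
  expect_equal(psnr(matrix(0, 16, 16), matrix(1, 16, 16), conv), 0)
  expect_error(psnr(matrix(0, 16, 16), matrix(0, 8, 8), conv),
               class = "mcrn_shape_error")
})

test_that("PSNR is symmetric and decreases with noise amplitude", {
  set.seed(21)
  a <- wave_image(24); b <- matrix(runif(24 * 24), 24, 24)
  expect_equal(psnr(a, b), psnr(b, a))
  sigmas <- c(0.01, 0.03, 0.09)
  means <- vapply(sigmas, function(s) {
    mean(vapply(1:5, function(i) {
      noisy <- pmin(pmax(a + matrix(rnorm(24 * 24, sd = s), 24, 24), 0), 1)
      psnr(a, noisy)
    }, 0))
  }, 0)
  expect_true(all(diff(means) < 0))
})

test_that("SSIM closed form for constant images and basic properties", {
  conv <- eval_convention()
  x <- image_gray(wave_image(16))
  expect_equal(ssim(x, x, conv), 1.0)
  # constant 100 vs 150 at L = 255: zero variances collapse the formula
  r <- matrix(100 / 255, 12, 12); t <- matrix(150 / 255, 12, 12)
  expected <- (2 * 100 * 150 + 6.5025) / (100^2 + 150^2 + 6.5025)
  expect_equal(ssim(r, t, conv), expected, tolerance = 1e-9)
  expect_equal(expected, 0.9231, tolerance = 1e-4)
  # symmetry and bounds on random pairs
  set.seed(22)
  for (i in 1:3) {
    a <- matrix(runif(15 * 15), 15, 15)
    b <- matrix(runif(15 * 15), 15, 15)
    s <- ssim(a, b, conv)
    expect_equal(s, ssim(b, a, conv))
    expect_true(s >= -1 && s <= 1)
  }
  expect_error(ssim(matrix(0.5, 8, 8), matrix(0.4, 8, 8), conv),
               class = "mcrn_shape_error")
})

test_that("entropy closed forms: 0 / 1 / 8 bits", {
  expect_equal(shannon_entropy(matrix(0.42, 10, 10)), 0)
  two <- matrix(c(0, 1), 16, 16)        # two levels, half the pixels each
  expect_equal(shannon_entropy(two), 1)
  all_levels <- matrix((0:255) / 255, 16, 16)  # 256 equifrequent levels
  expect_equal(shannon_entropy(all_levels), 8)
})

test_that("entropy is invariant to pixel permutation", {
  set.seed(23)
  m <- matrix(runif(144), 12, 12)
  p <- matrix(sample(m), 12, 12)
  expect_equal(shannon_entropy(m), shannon_entropy(p))
})

test_that("average gradient closed forms and homogeneity", {
  expect_equal(average_gradient(matrix(0.7, 10, 10)), 0)
  c0 <- 0.002
  h <- 20; w <- 20
  ramp_h <- matrix(rep((0:(w - 1)) * c0, each = h), h, w)
  expect_equal(average_gradient(ramp_h), c0 / sqrt(2), tolerance = 1e-12)
  ramp_d <- outer(0:(h - 1), 0:(w - 1), function(i, j) (i + j) * c0 / 2)
  expect_equal(average_gradient(ramp_d), c0 / 2, tolerance = 1e-12)
  # absolute homogeneity on an arbitrary matrix (raw values, no range limit)
  set.seed(24)
  m <- matrix(rnorm(100), 10, 10)
  expect_equal(average_gradient(m * -3), 3 * average_gradient(m))
})

rhaz_ref <- function(m) round(m * 255) / 255

test_that("evaluate_pair composes the individual metrics under one convention", {
  set.seed(25)
  ref <- image_gray(wave_image(36))
  test <- image_gray(pmin(pmax(ref$pixels +
    matrix(rnorm(36 * 36, sd = 0.02), 36, 36), 0), 1))
  conv <- eval_convention(border_shave = 2L)
  rep <- evaluate_pair(ref, test, conv)
  expect_equal(rep$psnr_db, psnr(ref, test, conv))
  expect_equal(rep$ssim, ssim(ref, test, conv))
  # border_shave = 2 on 36x36 scores a 32x32 region
  inner <- function(m) m[3:34, 3:34]
  expect_equal(rep$psnr_db,
               psnr(inner(ref$pixels), inner(test$pixels), eval_convention()))
  tq <- rhaz_ref(inner(test$pixels))
  expect_equal(rep$entropy_bits, shannon_entropy(tq))
  expect_equal(rep$avg_gradient, average_gradient(tq))
  # identical pair
  idrep <- evaluate_pair(ref, ref, conv)
  expect_identical(idrep$psnr_db, Inf)
  expect_equal(idrep$ssim, 1.0)
})
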