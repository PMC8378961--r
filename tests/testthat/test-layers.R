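test_that("convolution engine matches the quadruple-loop oracle", {
  set.seed(11)
  cases <- list(c(3, 1, 1, 1), c(4, 2, 1, 1), c(3, 1, 3, 3), c(3, 1, 5, 5),
                c(1, 1, 0, 1))
  for (cs in cases) {
    k <- cs[1]; st <- cs[2]; pd <- cs[3]; dl <- cs[4]
    x <- array(rnorm(10 * 9 * 3 * 2), c(10, 9, 3, 2))
    w <- array(rnorm(k * k * 3 * 4), c(k, k, 3, 4))
    b <- rnorm(4)
    expect_lt(max(abs(conv2d(x, w, b, st, pd, dl) -
                        naive_conv2d(x, w, b, st, pd, dl))), 1e-10)
  }
})

test_that("transposed convolution matches the scatter oracle at every scale geometry", {
  set.seed(12)
  for (s in 2:4) {
    sp <- scale_spec(s)
    x <- array(rnorm(5 * 6 * 3 * 2), c(5, 6, 3, 2))
    w <- array(rnorm(sp$kernel^2 * 3 * 2), c(sp$kernel, sp$kernel, 3, 2))
    b <- rnorm(2)
    y <- deconv2d(x, w, b, sp$stride, sp$pad)
    expect_equal(dim(y)[1:2], c(5L, 6L) * s)   # exact factor-s geometry
    expect_lt(max(abs(y - naive_deconv2d(x, w, b, sp$stride, sp$pad))), 1e-10)
  }
})

test_that("analytic layer gradients agree with central differences", {
  set.seed(13)
  x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  gy <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  bw <- mcrn:::cpp_conv2d_bwd(x, w, gy, 1L, 1L, 1L)
  f <- function(xx, ww) sum(conv2d(xx, ww, NULL, 1, 1, 1) * gy)
  eps <- 1e-6
  for (t in 1:6) {
    i <- sample(length(w), 1)
    wp <- w; wp[i] <- wp[i] + eps; wm <- w; wm[i] <- wm[i] - eps
    expect_equal(bw$gw[i], (f(x, wp) - f(x, wm)) / (2 * eps), tolerance = 1e-5)
    i <- sample(length(x), 1)
    xp <- x; xp[i] <- xp[i] + eps; xm <- x; xm[i] <- xm[i] - eps
    expect_equal(bw$gx[i], (f(xp, w) - f(xm, w)) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("pixel shuffle is a value-preserving permutation with exact inverse", {
  set.seed(14)
  for (r in 2:3) {
    x <- array(rnorm(4 * 5 * r * r * 3), c(4, 5, r * r * 3))
    y <- pixel_shuffle(x, r)
    expect_equal(dim(y), c(4L * r, 5L * r, 3L))
    expect_identical(sort(as.vector(y)), sort(as.vector(x)))  # multiset
    expect_equal(sum(y), sum(x))
    expect_equal(range(y), range(x))
    expect_identical(pixel_unshuffle(y, r), x)                # exact inverse
  }
  expect_error(pixel_shuffle(array(0, c(4, 4, 7)), 2), class = "mcrn_shape_error")
})

test_that("pixel shuffle places channel blocks at the documented offsets", {
  # channel c*r^2 + di*r + dj  ->  position (r*i + di, r*j + dj)
  r <- 2
  x <- array(0, c(2, 2, 4))
  for (ch in 1:4) x[, , ch] <- ch
  y <- pixel_shuffle(x, r)
  expect_equal(y[1, 1, 1], 1)  # di = 0, dj = 0 -> channel 0
  expect_equal(y[1, 2, 1], 2)  # dj = 1 -> channel 1
  expect_equal(y[2, 1, 1], 3)  # di = 1 -> channel 2
  expect_equal(y[2, 2, 1], 4)
})

test_that("parametric rectifier forward/backward are consistent", {
  set.seed(15)
  z <- array(rnorm(6 * 6 * 4), c(6, 6, 4, 1))
  a <- runif(4, 0, 0.5)
  y <- mcrn:::prelu_fw(z, a)
  expect_equal(y[z > 0], z[z > 0])
  gy <- array(rnorm(length(z)), dim(z))
  bw <- mcrn:::prelu_bw(gy, z, a)
  eps <- 1e-6
  for (c in 1:4) {
    ap <- a; ap[c] <- ap[c] + eps
    am <- a; am[c] <- am[c] - eps
    num <- (sum(mcrn:::prelu_fw(z, ap) * gy) - sum(mcrn:::prelu_fw(z, am) * gy)) / (2 * eps)
    expect_equal(bw$ga[c], num, tolerance = 1e-6)
  }
})
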