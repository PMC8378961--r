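# Independent brute-force oracles.  These deliberately re-derive results with
# plain loops / direct formulas and never call the implementation paths they
# check.

# direct quadruple-loop 2-D convolution
naive_conv2d <- function(x, w, b, stride = 1, pad = 0, dil = 1) {
  d <- dim(x)
  if (length(d) == 3) dim(x) <- c(d, 1)
  d <- dim(x)
  H <- d[1]; W <- d[2]; Cin <- d[3]; B <- d[4]
  k <- dim(w)[1]; Cout <- dim(w)[4]
  span <- dil * (k - 1) + 1
  Ho <- (H + 2 * pad - span) %/% stride + 1
  Wo <- (W + 2 * pad - span) %/% stride + 1
  y <- array(0, c(Ho, Wo, Cout, B))
  for (bb in 1:B) for (co in 1:Cout) for (io in 1:Ho) for (jo in 1:Wo) {
    s <- b[co]
    for (ci in 1:Cin) for (ki in 1:k) for (kj in 1:k) {
      ii <- (io - 1) * stride + (ki - 1) * dil - pad + 1
      jj <- (jo - 1) * stride + (kj - 1) * dil - pad + 1
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        s <- s + x[ii, jj, ci, bb] * w[ki, kj, ci, co]
    }
    y[io, jo, co, bb] <- s
  }
  y
}

# direct scatter transposed convolution
naive_deconv2d <- function(x, w, b, stride, pad) {
  d <- dim(x)
  if (length(d) == 3) dim(x) <- c(d, 1)
  d <- dim(x)
  H <- d[1]; W <- d[2]; Cin <- d[3]; B <- d[4]
  k <- dim(w)[1]; Cout <- dim(w)[4]
  Ho <- (H - 1) * stride + k - 2 * pad
  Wo <- (W - 1) * stride + k - 2 * pad
  y <- array(0, c(Ho, Wo, Cout, B))
  for (bb in 1:B) for (co in 1:Cout) y[, , co, bb] <- b[co]
  for (bb in 1:B) for (co in 1:Cout) for (i in 1:H) for (j in 1:W)
    for (ci in 1:Cin) for (ki in 1:k) for (kj in 1:k) {
      oi <- (i - 1) * stride + (ki - 1) - pad + 1
      oj <- (j - 1) * stride + (kj - 1) - pad + 1
      if (oi >= 1 && oi <= Ho && oj >= 1 && oj <= Wo)
        y[oi, oj, co, bb] <- y[oi, oj, co, bb] + x[i, j, ci, bb] * w[ki, kj, ci, co]
    }
  y
}

# brute-force separable cubic-kernel interpolation (Catmull-Rom a = -0.5,
# symmetric reflection), direct per-pixel summation
oracle_cubic_kernel <- function(t) {
  a <- -0.5
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

oracle_reflect <- function(j, n) {
  p <- 2 * n
  j <- j %% p
  ifelse(j >= n, p - 1 - j, j)
}

oracle_bicubic_up <- function(m, factor) {
  stopifnot(factor >= 1)
  h <- nrow(m); w <- ncol(m)
  ho <- round(h * factor); wo <- round(w * factor)
  interp_axis <- function(vlen, olen, idx) {
    src <- (idx + 0.5) / (olen / vlen) - 0.5
    j <- seq(floor(src) - 1, floor(src) + 2)
    wgt <- oracle_cubic_kernel(src - j)
    wgt <- wgt / sum(wgt)
    list(j = oracle_reflect(j, vlen) + 1, w = wgt)
  }
  out <- matrix(0, ho, wo)
  for (i in seq_len(ho)) {
    ri <- interp_axis(h, ho, i - 1)
    for (j in seq_len(wo)) {
      cj <- interp_axis(w, wo, j - 1)
      s <- 0
      for (a in seq_along(ri$j)) for (b in seq_along(cj$j))
        s <- s + ri$w[a] * cj$w[b] * m[ri$j[a], cj$j[b]]
      out[i, j] <- s
    }
  }
  pmin(pmax(out, 0), 1)
}

# dense, loop-based channel-attention recomputation
oracle_channel_attention <- function(f, W1, b1, W2, b2) {
  d <- dim(f)
  C <- d[3]
  out <- array(0, d)
  pool <- vapply(seq_len(C), function(c) mean(f[, , c]), 0)
  s1 <- as.numeric(t(W1) %*% pool) + b1
  r1 <- pmax(s1, 0)
  s2 <- as.numeric(t(W2) %*% r1) + b2
  gate <- 1 / (1 + exp(-s2))
  for (c in seq_len(C)) out[, , c] <- f[, , c] * gate[c]
  out
}

# single-step-at-a-time Adam reference
oracle_adam <- function(w, gs, lr, beta1, beta2, eps) {
  m <- w * 0; v <- w * 0
  for (t in seq_along(gs)) {
    g <- gs[[t]]
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    w <- w - lr * mhat / (sqrt(vhat) + eps)
  }
  w
}

# manual parametric rectifier (for hand-composed forward chains)
prelu_ref <- function(z, a) {
  d <- dim(z)
  slope <- rep(a, each = d[1] * d[2])
  pmax(z, 0) + slope * pmin(z, 0)
}

# zero every weight, bias, and rectifier slope of a model
zero_model <- function(model) {
  model$params <- lapply(model$params, function(p) p * 0)
  model
}
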