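# The CNN engine is hand-built, so its kernels are verified against naive R
# convolutions and finite-difference gradients.

naive_conv2d <- function(x, w, b, k) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]; Cout <- nrow(w)
  p <- (k - 1) / 2
  out <- array(0, c(H, W, Cout))
  for (co in seq_len(Cout)) for (i in seq_len(H)) for (j in seq_len(W)) {
    s <- b[co]
    for (ci in seq_len(Cin)) for (dr in 0:(k - 1)) for (dc in 0:(k - 1)) {
      si <- i + dr - p; sj <- j + dc - p
      if (si >= 1 && si <= H && sj >= 1 && sj <= W)
        s <- s + w[co, ((ci - 1) * k + dr) * k + dc + 1] * x[si, sj, ci]
    }
    out[i, j, co] <- s
  }
  out
}

num_grad <- function(v, fn, eps = 1e-6) {
  vapply(seq_along(v), function(i) {
    vp <- v; vp[i] <- vp[i] + eps
    vm <- v; vm[i] <- vm[i] - eps
    (fn(vp) - fn(vm)) / (2 * eps)
  }, numeric(1))
}

test_that("2D convolution matches a naive oracle and its gradients check", {
  set.seed(101)
  ns <- asNamespace("rfstage")
  x <- array(rnorm(5 * 6 * 2), c(5, 6, 2))
  w <- matrix(rnorm(3 * 18), 3)
  b <- rnorm(3)
  y <- ns$conv2d_fw(x, w, b, 3L, 3L)
  expect_equal(y, naive_conv2d(x, w, b, 3), tolerance = 1e-12)
  fc <- ns$conv2d_fwc(x, w, b, 3L, 3L)
  expect_equal(fc$y, y)
  gy <- array(rnorm(length(y)), dim(y))
  bw <- ns$conv2d_bwc(fc$cols, w, gy, 3L, 3L, 2L)
  f <- function(xx, ww, bb)
    sum(ns$conv2d_fw(array(xx, dim(x)), matrix(ww, 3), bb, 3L, 3L) * gy)
  expect_equal(c(bw$gx), num_grad(c(x), function(v) f(v, w, b)),
               tolerance = 1e-6)
  expect_equal(c(bw$gw), num_grad(c(w), function(v) f(c(x), v, b)),
               tolerance = 1e-6)
  expect_equal(c(bw$gb), num_grad(b, function(v) f(c(x), c(w), v)),
               tolerance = 1e-6)
})

test_that("transpose convolution doubles the grid and gradients check", {
  set.seed(102)
  ns <- asNamespace("rfstage")
  x <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  w <- matrix(rnorm(2 * 4 * 3), 8)
  b <- rnorm(2)
  y <- ns$convT2d_fw(x, w, b)
  expect_equal(dim(y), c(8L, 10L, 2L))
  gy <- array(rnorm(length(y)), dim(y))
  bw <- ns$convT2d_bw(x, w, gy)
  f <- function(xx, ww, bb)
    sum(ns$convT2d_fw(array(xx, dim(x)), matrix(ww, 8), bb) * gy)
  expect_equal(c(bw$gx), num_grad(c(x), function(v) f(v, w, b)),
               tolerance = 1e-6)
  expect_equal(c(bw$gw), num_grad(c(w), function(v) f(c(x), v, b)),
               tolerance = 1e-6)
})

test_that("batched 1D convolution and pooling gradients check", {
  set.seed(103)
  ns <- asNamespace("rfstage")
  x <- array(rnorm(12 * 2 * 3), c(12, 2, 3))
  w <- matrix(rnorm(3 * 10), 3)
  b <- rnorm(3)
  y <- ns$conv1d_fw(x, w, b, 5L)
  expect_equal(dim(y), c(12L, 3L, 3L))
  fc <- ns$conv1d_fwc(x, w, b, 5L)
  expect_equal(fc$y, y)
  expect_equal(ns$conv1d_fw(x, w, b, 5L, act = TRUE), tanh(y))
  gy <- array(rnorm(length(y)), dim(y))
  bw <- ns$conv1d_bwc(fc$cols, w, gy, 5L, 2L)
  f <- function(xx, ww, bb)
    sum(ns$conv1d_fw(array(xx, dim(x)), matrix(ww, 3), bb, 5L) * gy)
  expect_equal(c(bw$gx), num_grad(c(x), function(v) f(v, w, b)),
               tolerance = 1e-6)
  expect_equal(c(bw$gw), num_grad(c(w), function(v) f(c(x), v, b)),
               tolerance = 1e-6)
  pl <- ns$maxpool1d_fw(x, 3L)
  expect_equal(dim(pl$y), c(4L, 2L, 3L))
  gyp <- array(rnorm(length(pl$y)), dim(pl$y))
  fp <- function(v) sum(ns$maxpool1d_fw(array(v, dim(x)), 3L)$y * gyp)
  expect_equal(c(ns$maxpool1d_bw(gyp, pl$idx, 12L)),
               num_grad(c(x), fp), tolerance = 1e-6)
})

test_that("batch normalisation backward matches finite differences", {
  set.seed(104)
  ns <- asNamespace("rfstage")
  zs <- lapply(1:2, function(i) array(rnorm(4 * 3 * 2), c(4, 3, 2)))
  gamma <- runif(2, 0.5, 1.5); beta <- rnorm(2)
  gys <- lapply(1:2, function(i) array(rnorm(24), c(4, 3, 2)))
  fwd <- function(z1, gm) {
    zz <- list(array(z1, c(4, 3, 2)), zs[[2]])
    o <- ns$bn2d_fw(zz, gm, beta, rep(0, 2), rep(1, 2), TRUE)
    sum(o$ys[[1]] * gys[[1]]) + sum(o$ys[[2]] * gys[[2]])
  }
  o <- ns$bn2d_fw(zs, gamma, beta, rep(0, 2), rep(1, 2), TRUE)
  bw <- ns$bn2d_bw(gys, o, gamma)
  expect_equal(c(bw$gxs[[1]]), num_grad(c(zs[[1]]), function(v) fwd(v, gamma)),
               tolerance = 1e-5)
  expect_equal(bw$dgamma, num_grad(gamma, function(v) fwd(c(zs[[1]]), v)),
               tolerance = 1e-5)
})

test_that("whole-network gradients agree with finite differences", {
  set.seed(105)
  ns <- asNamespace("rfstage")
  cfg <- seg_config(arch = "attention_unet", input_shape = c(8L, 8L),
                    encoder_widths = c(3L, 5L), epochs = 1L, seed = 3)
  net <- build_segnet(cfg)
  xs <- lapply(1:2, function(i) array(runif(8 * 8 * 3), c(8, 8, 3)))
  ys <- lapply(1:2, function(i) matrix(rbinom(64, 1, .5), 8, 8))
  st <- ns$seg_train_step(net$params, net$rstats, cfg, xs, ys)
  lossfn <- function(p) ns$seg_train_step(p, net$rstats, cfg, xs, ys)$loss
  eps <- 1e-5
  for (nm in names(st$grads)) {
    g <- st$grads[[nm]]
    for (i in seq_len(min(2, length(g)))) {
      pp <- net$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- net$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      nd <- (lossfn(pp) - lossfn(pm)) / (2 * eps)
      expect_lt(abs(nd - g[i]) / max(1e-6, abs(nd), abs(g[i])), 1e-3)
    }
  }
  ccfg <- clf_config(conv_channels = c(2L, 3L, 3L, 4L),
                     kernel_sizes = c(5L, 3L, 3L, 3L),
                     pool_sizes = c(2L, 2L, 2L, 2L),
                     fc_widths = c(6L, 5L, 4L, 2L), input_len = 32L, seed = 5)
  cnet <- build_clf(ccfg)
  x <- matrix(rnorm(32 * 6), 32, 6)
  y <- c(0L, 1L, 0L, 1L, 1L, 0L)
  st2 <- ns$clf_train_step(cnet$params, ccfg, x, y)
  lossfn2 <- function(p) ns$clf_train_step(p, ccfg, x, y)$loss
  for (nm in names(st2$grads)) {
    g <- st2$grads[[nm]]
    for (i in seq_len(min(3, length(g)))) {
      pp <- cnet$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- cnet$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      nd <- (lossfn2(pp) - lossfn2(pm)) / (2 * eps)
      expect_lt(abs(nd - g[i]) / max(1e-6, abs(nd), abs(g[i])), 1e-3)
    }
  }
})
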