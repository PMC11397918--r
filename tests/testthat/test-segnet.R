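test_that("network output shape equals input shape and config validates", {
  cfg <- seg_config(input_shape = c(192L, 256L), encoder_widths = c(4L, 8L),
                    seed = 2)
  net <- build_segnet(cfg)
  pm <- segment_prob(net, matrix(runif(192 * 256), 192, 256))
  expect_equal(dim(pm), c(192L, 256L))
  expect_true(all(pm > 0 & pm < 1))
  m <- segment_bmode(net, matrix(runif(192 * 256), 192, 256))
  expect_s3_class(m, "liver_mask")
  expect_equal(dim(m$pixels), c(192L, 256L))
  expect_true(all(m$pixels %in% c(0L, 1L)))
  # also for another 2^depth-divisible shape
  cfg2 <- seg_config(input_shape = c(32L, 48L), encoder_widths = c(4L, 8L, 16L))
  pm2 <- segment_prob(build_segnet(cfg2), matrix(runif(32 * 48), 32, 48))
  expect_equal(dim(pm2), c(32L, 48L))
  expect_error(seg_config(input_shape = c(100L, 256L),
                          encoder_widths = c(8L, 16L, 32L, 64L)), "divisible")
  expect_error(seg_config(encoder_widths = c(16L, 8L)), "increasing")
  expect_error(segment_prob(net, matrix(0.5, 64, 64)), "shape mismatch")
})

test_that("attention gating only adds parameters, and widths add parameters", {
  base <- seg_config(input_shape = c(32L, 32L), encoder_widths = c(4L, 8L),
                     seed = 7)
  att <- seg_config(arch = "attention_unet", input_shape = c(32L, 32L),
                    encoder_widths = c(4L, 8L), seed = 7)
  n1 <- build_segnet(base); n2 <- build_segnet(att)
  shared <- intersect(names(n1$params), names(n2$params))
  expect_setequal(shared, names(n1$params))
  expect_gt(count_params(n2), count_params(n1))
  extra <- setdiff(names(n2$params), names(n1$params))
  expect_true(all(grepl("^att", extra)))
  deeper <- seg_config(input_shape = c(32L, 32L),
                       encoder_widths = c(4L, 8L, 16L), seed = 7)
  expect_gt(count_params(build_segnet(deeper)), count_params(n1))
})

test_that("builds are deterministic in the seed", {
  cfg <- seg_config(input_shape = c(32L, 32L), encoder_widths = c(4L, 8L),
                    seed = 9)
  expect_identical(build_segnet(cfg)$params, build_segnet(cfg)$params)
  cfg2 <- seg_config(input_shape = c(32L, 32L), encoder_widths = c(4L, 8L),
                     seed = 10)
  expect_false(identical(build_segnet(cfg)$params, build_segnet(cfg2)$params))
})

test_that("attention coefficients collapse to a constant without spatial cues", {
  set.seed(30)
  ci <- 3L; cx <- 4L
  wx <- matrix(rnorm(ci * cx), ci); wg <- matrix(rnorm(ci * cx), ci)
  bg <- rnorm(ci); psi <- matrix(rnorm(ci), 1); bpsi <- 0.3
  x_const <- array(rep(runif(cx), each = 36), c(6, 6, cx))
  g_zero <- array(0, c(6, 6, cx))
  out <- attention_gate(x_const, g_zero, wx, wg, bg, psi, bpsi)
  expect_lt(diff(range(out$alpha)), 1e-12)    # no spatial preference
  expect_true(all(out$alpha > 0 & out$alpha < 1))
  # gating with structure modulates the coefficients
  g_struct <- array(rnorm(36 * cx), c(6, 6, cx))
  out2 <- attention_gate(x_const, g_struct, wx, wg, bg, psi, bpsi)
  expect_gt(diff(range(out2$alpha)), 1e-6)
  expect_equal(out$gated[, , 1], x_const[, , 1] * out$alpha)
})

test_that("binary cross-entropy of a perfect prediction is ~0", {
  ns <- asNamespace("rfstage")
  y <- matrix(c(0, 1, 1, 0), 2, 2)
  z <- (2 * y - 1) * 30        # confident logits matching the targets
  expect_lt(ns$bce_logits(z, y)$loss, 1e-3)
})

test_that("training overfits a single pair and drives loss down", {
  set.seed(31)
  cfg <- seg_config(input_shape = c(32L, 32L), encoder_widths = c(4L, 8L),
                    epochs = 60L, lr = 3e-3, batch_size = 1L, seed = 12)
  img <- matrix(runif(32 * 32), 32, 32)
  msk <- matrix(0L, 32, 32); msk[8:24, 10:28] <- 1L
  net <- train_segnet(build_segnet(cfg), list(img), list(msk))
  expect_true(all(diff(net$history$train_loss[1:5]) < 0))
  d <- seg_metrics(segment_bmode(net, img)$pixels, msk)$dsc
  expect_gt(d, 0.95)
})

test_that("all-background targets drive the output probability to zero", {
  set.seed(32)
  cfg <- seg_config(input_shape = c(32L, 32L), encoder_widths = c(4L, 8L),
                    epochs = 150L, lr = 1e-2, batch_size = 2L, seed = 13)
  imgs <- lapply(1:2, function(i) matrix(runif(32 * 32), 32, 32))
  msks <- lapply(1:2, function(i) matrix(0L, 32, 32))
  net <- train_segnet(build_segnet(cfg), imgs, msks)
  expect_lt(mean(segment_prob(net, imgs[[1]])), 0.05)
})

test_that("training is deterministic for a fixed seed and data order", {
  set.seed(33)
  cfg <- seg_config(input_shape = c(16L, 16L), encoder_widths = c(3L, 6L),
                    epochs = 2L, seed = 14)
  imgs <- lapply(1:4, function(i) matrix(runif(256), 16, 16))
  msks <- lapply(1:4, function(i) matrix(rbinom(256, 1, .5), 16, 16))
  n1 <- train_segnet(build_segnet(cfg), imgs, msks)
  n2 <- train_segnet(build_segnet(cfg), imgs, msks)
  expect_identical(n1$history, n2$history)
  expect_identical(n1$params, n2$params)
})

test_that("thresholding is idempotent and behaves at the extremes", {
  expect_equal(threshold_mask(matrix(0.7, 3, 3)), matrix(1L, 3, 3))
  expect_equal(threshold_mask(matrix(0.2, 3, 3)), matrix(0L, 3, 3))
  p <- matrix(runif(64), 8, 8)
  m <- threshold_mask(p)
  expect_identical(threshold_mask(m), m)
})

test_that("mask resize back to signal space preserves band geometry", {
  ones <- matrix(1L, 192, 256)
  up <- resize_mask_to_signal(ones)
  expect_equal(dim(up$pixels), c(1247L, 256L))
  expect_true(all(up$pixels == 1L))
  expect_true(all(resize_mask_to_signal(matrix(0L, 192, 256))$pixels == 0L))
  band <- matrix(0L, 192, 256)
  band[49:144, ] <- 1L                 # rows [48, 144) zero-based
  ub <- resize_mask_to_signal(band)
  rows <- range(which(ub$pixels[, 1] == 1L))
  expect_lt(abs(rows[1] - 48 / 192 * 1247), 4)
  expect_lt(abs(rows[2] - 144 / 192 * 1247), 4)
  frac <- mean(ub$pixels)
  expect_lt(abs(frac - 96 / 192), 0.01)
  expect_error(resize_mask_to_signal(matrix(0.4, 8, 8)), "binary")
})
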