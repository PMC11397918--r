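test_that("binary tasks partition the stages at the right cuts", {
  t2 <- binary_task("geF2")
  expect_equal(t2$positive_stages, 2:4)
  expect_equal(t2$negative_stages, 0:1)
  expect_equal(sort(c(t2$positive_stages, t2$negative_stages)), 0:4)
  expect_equal(binary_task("geF1")$negative_stages, 0)
  expect_equal(binary_task("geF4")$positive_stages, 4)
})

test_that("masking zeroes exactly the non-liver support", {
  set.seed(20)
  m <- matrix(rnorm(40 * 6), 40, 6)
  sf <- spectrum_frame(m, "amplitude")
  ones <- matrix(1L, 40, 6)
  expect_equal(apply_mask(sf, ones)$values, sf$values)
  zeros <- matrix(0L, 40, 6)
  expect_true(all(apply_mask(sf, zeros)$values == 0))
  chk <- (outer(1:40, 1:6, `+`) %% 2L)
  r <- apply_mask(sf, chk)
  expect_identical(r$values != 0, chk == 1 & sf$values != 0)
  expect_error(apply_mask(sf, ones[1:10, ]), "shape")
  expect_error(apply_mask(sf, ones * 2L), "binary")
})

test_that("min-max normalization is the stated affine map and idempotent", {
  sf <- spectrum_frame(matrix(rnorm(32 * 4), 32, 4), "amplitude")
  roi <- apply_mask(sf, matrix(1L, 32, 4))
  roi$values <- matrix(seq(0, 2, length.out = 128), 32, 4)
  nr <- normalize_roi(roi)
  expect_equal(nr$values, roi$values / 2)
  expect_equal(min(nr$values), 0)
  expect_equal(max(nr$values), 1)
  # phase-like frame spanning [-pi, pi]
  roi$values <- matrix(seq(-pi, pi, length.out = 128), 32, 4)
  np <- normalize_roi(roi)
  expect_equal(range(np$values), c(0, 1))
  expect_equal(np$values[which.min(abs(roi$values))], 0.5, tolerance = 0.02)
  # idempotence
  expect_equal(normalize_roi(np)$values, np$values)
  roi$values <- matrix(1, 32, 4)
  expect_error(normalize_roi(roi), "degenerate")
})

test_that("gate counts match the placement formula and edge cases", {
  roi <- synthetic_roi(run_mask(1247, 1, 1247, start = 1))
  g <- gate_lines(roi)
  expect_equal(ncol(g), floor((1247 - 768) / 20) + 1)   # 24 placements
  roi <- synthetic_roi(run_mask(1247, 1, 768, start = 100))
  expect_equal(ncol(gate_lines(roi)), 1)
  roi767 <- synthetic_roi(run_mask(1247, 1, 767, start = 100))
  expect_error(gate_lines(roi767), "no eligible line")
  # strict reading excludes the exactly-fitting run
  roi768 <- synthetic_roi(run_mask(1247, 1, 768, start = 100))
  expect_error(gate_lines(roi768, strict = TRUE), "no eligible line")
})

test_that("gated segments are the right slices in line-major order", {
  mask <- run_mask(1247, 3, 800, start = 50)
  mask[, 2] <- 0L                       # middle line ineligible
  roi <- synthetic_roi(mask, seed = 4)
  g <- gate_lines(roi)
  per_line <- floor((800 - 768) / 20) + 1   # 2 segments per eligible line
  expect_equal(ncol(g), 2 * per_line)
  expect_equal(g[, 1], roi$values[50:817, 1])
  expect_equal(g[, 2], roi$values[70:837, 1])
  expect_equal(g[, 3], roi$values[50:817, 3])
})

test_that("gating works on the longest contiguous run of fragmented masks", {
  m <- matrix(0L, 1247, 1)
  m[10:100, 1] <- 1L            # short fragment
  m[200:1100, 1] <- 1L          # long run of 901
  roi <- synthetic_roi(m, seed = 5)
  g <- gate_lines(roi)
  expect_equal(ncol(g), floor((901 - 768) / 20) + 1)
  expect_equal(g[, 1], roi$values[200:967, 1])
})

test_that("windowing emits exactly n_aug in-bounds windows", {
  gated <- matrix(rep(1:512, each = 768), 768, 512)   # column index as value
  w <- window_frames(gated, 4L, label = 1L, frame_id = "f")
  expect_length(w, 4)
  starts <- vapply(w, function(s) s$values[1, 1], numeric(1))
  expect_equal(starts, c(1, 65, 129, 193))            # steps of (512-256)/4
  for (s in w) {
    expect_equal(dim(s$values), c(768L, 256L))
    expect_equal(s$label, 1L)
  }
  one <- window_frames(gated[, 1:256], 3L)
  expect_length(one, 3)
  expect_true(all(vapply(one, function(s)
    identical(s$values, gated[, 1:256]), logical(1))))
  single <- window_frames(gated, 1L)
  expect_equal(single[[1]]$values[1, 1], 1)
  expect_error(window_frames(gated[, 1:100], 2L), "L_lateral")
  padded <- window_frames(gated[, 1:100], 2L, pad = TRUE)
  expect_equal(dim(padded[[1]]$values), c(768L, 256L))
})

test_that("random window placements always fit", {
  set.seed(21)
  for (i in 1:25) {
    L <- sample(256:900, 1)
    n_aug <- sample(1:10, 1)
    gated <- matrix(rep(seq_len(L), each = 4), 4, L)
    w <- window_frames(gated, n_aug, width = 256L)
    expect_length(w, n_aug)
    st <- vapply(w, function(s) s$values[1, 1], numeric(1))
    expect_true(all(st >= 1 & st + 255 <= L))
  }
})

test_that("augmentation factor is the rounded majority/minority ratio", {
  expect_equal(n_aug_factor(161, 76), 2L)   # the >=F2 cohort ratio
  expect_equal(n_aug_factor(10, 10), 1L)
  expect_equal(n_aug_factor(100, 9), 11L)
  expect_error(n_aug_factor(5, 0), "empty")
})

test_that("balance_and_assemble splits, balances and stays participant-pure", {
  masks <- run_mask(1247, 256, 900, start = 100)
  stages <- c(0L, 0L, 0L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 4L, 4L)
  frames <- lapply(seq_along(stages), function(i)
    synthetic_roi(masks, label = stages[i], id = sprintf("P%02d", i),
                  seed = 100 + i))
  ds <- balance_and_assemble(frames, binary_task("geF3"),
                             ratios = c(0.6, 0.2, 0.2), seed = 2)
  # classes: neg {0,0,0,1,2,2} pos {3,3,4,4,4,4}: balanced -> n_aug 1
  expect_equal(ds$n_aug, 1L)
  expect_true(all(vapply(ds$train, function(s)
    identical(dim(s$values), c(768L, 256L)), logical(1))))
  ids_by_part <- lapply(ds[c("train", "val", "test")], function(part)
    unique(vapply(part, `[[`, "", "source_frame_id")))
  expect_equal(anyDuplicated(unlist(ids_by_part)), 0L)   # leakage guard
  # unbalanced case: 2 negatives vs 10 positives in a geF1-style setting
  stages2 <- c(0L, 0L, 0L, 0L, rep(4L, 8))
  frames2 <- lapply(seq_along(stages2), function(i)
    synthetic_roi(masks, label = stages2[i], id = sprintf("Q%02d", i),
                  seed = 200 + i))
  expect_warning(
    ds2 <- balance_and_assemble(frames2, binary_task("geF1"),
                                ratios = c(0.6, 0.2, 0.2), seed = 3),
    "validation")
  # training part: floor(0.6*4)=2 negatives, floor(0.6*8)=4 positives
  expect_equal(ds2$n_aug, 2L)
  ytr <- vapply(ds2$train, `[[`, integer(1), "label")
  expect_equal(sum(ytr == 0), 4L)   # 2 minority frames x 2 windows
  expect_equal(sum(ytr == 1), 4L)   # majority frames keep 1 window
  expect_true(all(vapply(ds2$val, `[[`, integer(1), "window_index") == 1L))
  # single-class input errors
  frames3 <- frames2[5:12]
  expect_error(balance_and_assemble(frames3, binary_task("geF1"), seed = 1),
               "both classes")
})
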