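test_that("pulse is a unit-peak, odd-length gated cosine at fc", {
  acq <- acquisition_spec()
  p <- make_pulse(acq)
  expect_true(length(p) %% 2 == 1)
  expect_equal(max(abs(p)), 1)
  c0 <- (length(p) + 1) / 2
  expect_equal(p[c0], 1)
  # fs/fc = 4 samples per carrier period: half period (2 samples) flips sign
  expect_lt(p[c0 + 2], 0)
  expect_gt(p[c0 + 4], 0)             # one full period back to positive
})

test_that("narrow fractional bandwidth approaches an unwindowed cosine", {
  acq <- acquisition_spec(pulse_bw = 0.02)
  p <- make_pulse(acq)
  c0 <- (length(p) + 1) / 2
  peaks <- p[c0 + seq(-8, 8, by = 4)]   # carrier maxima near the centre
  expect_lt(max(peaks) - min(peaks), 0.02)
  wide <- make_pulse(acquisition_spec(pulse_bw = 0.6))
  cw <- (length(wide) + 1) / 2
  wpeaks <- wide[cw + seq(-8, 8, by = 4)]
  expect_gt(max(wpeaks) - min(wpeaks), 0.5)  # wide band decays fast
})

test_that("acquisition and phantom validation reject bad settings", {
  expect_error(acquisition_spec(fc = 7e6, fs = 12e6), "fc")
  expect_error(acquisition_spec(pulse_bw = 0), "pulse_bw")
  expect_error(acquisition_spec(n_samples = 0), "n_samples")
  expect_error(phantom_spec(stage = 5), "stage")
  expect_error(phantom_spec(stage = 1, density_base = 0), "density")
})

test_that("simulate_frame is reproducible and mask matches the band", {
  acq <- acquisition_spec()
  ph <- phantom_spec(stage = 2)
  f1 <- simulate_frame(ph, acq, seed = 31)
  f2 <- simulate_frame(ph, acq, seed = 31)
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$truth_mask, f2$truth_mask)
  f3 <- simulate_frame(ph, acq, seed = 32)
  expect_false(identical(f1$samples, f3$samples))
  expect_equal(f1$label, 2L)
  # mask is 1 exactly between the boundary curves
  ref <- matrix(0L, acq$n_samples, acq$n_lines)
  for (j in seq_len(acq$n_lines)) ref[f1$top[j]:f1$bottom[j], j] <- 1L
  expect_identical(f1$truth_mask, ref)
  expect_true(all(f1$bottom - f1$top + 1L >= 768L))
})

test_that("vanishing scatterer density leaves the liver band silent", {
  acq <- acquisition_spec()
  ph <- phantom_spec(stage = 0, density_base = 1e-12, coherent_slope = 0)
  f <- simulate_frame(ph, acq, seed = 5)
  # interior of the band, clear of pulse leakage from the wall
  hp <- (length(make_pulse(acq)) - 1) / 2
  inner <- sapply(seq_len(acq$n_lines), function(j)
    max(abs(f$samples[(f$top[j] + hp):(f$bottom[j] - hp), j])))
  expect_equal(max(inner), 0)
})

test_that("dense diffuse speckle reaches the Rayleigh envelope SNR", {
  acq <- acquisition_spec()
  ph <- phantom_spec(stage = 0, density_base = 20, coherent_slope = 0)
  snr <- vapply(1:50, function(i) {
    f <- simulate_frame(ph, acq, seed = 400 + i)
    env <- rfstage:::envelope_frame(f$samples)
    v <- env[f$truth_mask == 1]
    mean(v) / stats::sd(v)
  }, numeric(1))
  rayleigh <- sqrt(pi / (4 - pi))   # 1.9130...
  expect_lt(abs(mean(snr) - rayleigh) / rayleigh, 0.10)
})

test_that("mean liver-band envelope is monotone in fibrosis stage", {
  acq <- acquisition_spec()
  me <- vapply(0:4, function(s) {
    mean(vapply(1:3, function(i) {
      f <- simulate_frame(phantom_spec(stage = s), acq, seed = 70 + 10 * s + i)
      env <- rfstage:::envelope_frame(f$samples)
      mean(env[f$truth_mask == 1])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(me) > 0))
})

test_that("stage maps are monotone in stage", {
  d <- vapply(0:4, function(s) stage_params(phantom_spec(s))$density, numeric(1))
  cv <- vapply(0:4, function(s) stage_params(phantom_spec(s))$cv, numeric(1))
  co <- vapply(0:4, function(s) stage_params(phantom_spec(s))$coherent, numeric(1))
  expect_true(all(diff(d) > 0) && all(diff(cv) > 0) && all(diff(co) > 0))
})

test_that("simulate_dataset counts, labels and seeding behave", {
  acq <- acquisition_spec(n_samples = 900L, n_lines = 8L)
  ds <- simulate_dataset(n_per_stage = 2, acq = acq, seed = 9,
                         top_range = c(20, 40), bottom_range = c(850, 880),
                         min_band = 700, wobble_amp = 5)
  expect_length(ds, 10)
  expect_equal(vapply(ds, `[[`, integer(1), "label"),
               rep(0:4, each = 2))
  ds2 <- simulate_dataset(n_per_stage = 2, acq = acq, seed = 9,
                          top_range = c(20, 40), bottom_range = c(850, 880),
                          min_band = 700, wobble_amp = 5)
  expect_identical(lapply(ds, `[[`, "samples"), lapply(ds2, `[[`, "samples"))
  ds3 <- simulate_dataset(n_per_stage = 2, acq = acq, seed = 10,
                          top_range = c(20, 40), bottom_range = c(850, 880),
                          min_band = 700, wobble_amp = 5)
  sums <- vapply(ds, function(f) sum(f$samples), numeric(1))
  sums3 <- vapply(ds3, function(f) sum(f$samples), numeric(1))
  expect_false(any(sums %in% sums3))   # no identical frames across seeds
})

test_that("cohort proportions reproduce the reference stage counts", {
  expect_identical(stage_proportions(237), c(27L, 49L, 51L, 49L, 61L))
  expect_equal(sum(stage_proportions(100)), 100)
  expect_equal(sum(stage_proportions(10)), 10)
})

test_that("dataset container round-trips frames and manifest", {
  acq <- acquisition_spec(n_samples = 900L, n_lines = 8L)
  ds <- simulate_dataset(n_per_stage = 1, stages = c(0, 4), acq = acq,
                         seed = 3, top_range = c(20, 40),
                         bottom_range = c(850, 880), min_band = 700,
                         wobble_amp = 5)
  f <- tempfile(fileext = ".rds")
  write_rf_dataset(ds, f)
  back <- read_rf_dataset(f)
  expect_equal(back[[1]]$samples, ds[[1]]$samples)
  expect_equal(back[[2]]$truth_mask, ds[[2]]$truth_mask)
  expect_equal(vapply(back, `[[`, integer(1), "label"), c(0L, 4L))
  man <- read.csv(sub("\\.rds$", "_manifest.csv", f))
  expect_equal(nrow(man), 2)
  expect_equal(man$stage, c(0L, 4L))
  unlink(c(f, sub("\\.rds$", "_manifest.csv", f)))
})
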