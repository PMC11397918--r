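# Shared fixtures, all generated in code.

# naive O(N^2) DFT oracle, independent of stats::fft
naive_dft <- function(s) {
  n <- length(s)
  k <- 0:(n - 1)
  vapply(k, function(kk)
    sum(s * exp(-2i * pi * kk * (0:(n - 1)) / n)), complex(1))
}

# pairwise Mann-Whitney AUC oracle (ties counted 1/2)
mw_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# lightweight ROI spectrum frame with a chosen mask (values random, already
# in [0,1] so it can feed the gating/windowing operations directly)
synthetic_roi <- function(mask, label = 0L, id = "synthetic",
                          values = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(values))
    values <- matrix(runif(length(mask)), nrow(mask)) * mask
  structure(list(values = values, mask = mask, kind = "phase",
                 label = label, source_frame_id = id, normalized = TRUE),
            class = "roi_spectrum")
}

# mask with one contiguous liver run of length L per line
run_mask <- function(n_samples, n_lines, run_len, start = 100L) {
  m <- matrix(0L, n_samples, n_lines)
  if (run_len > 0) m[start:(start + run_len - 1L), ] <- 1L
  m
}

# small simulated ROI-spectrum cohort for classifier tests
sim_rois <- function(n_per_class, stages = c(0L, 4L), kind = "phase",
                     stage_effect = 1, seed = 1L) {
  acq <- acquisition_spec()
  rois <- list()
  for (s in stages) {
    for (i in seq_len(n_per_class)) {
      f <- simulate_frame(phantom_spec(stage = s, stage_effect = stage_effect),
                          acq, seed = seed + 1000L * s + i)
      r <- normalize_roi(apply_mask(spectrum_frame(f, kind), f$truth_mask))
      r$source_frame_id <- sprintf("P_s%d_%d", s, i)
      rois[[length(rois) + 1L]] <- r
    }
  }
  rois
}

# circular distance between phase angles (the +-pi boundary is one point)
phase_dist <- function(a, b) {
  d <- abs(a - b)
  pmin(d, abs(2 * pi - d))
}
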