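#' Binary fibrosis-stage dichotomy
#'
#' The four clinical binary tasks: `geF1` (F0 vs F1-F4), `geF2` (F0-F1 vs
#' F2-F4), `geF3` (F0-F2 vs F3-F4) and `geF4` (F0-F3 vs F4). Positive class =
#' stages at or above the cut.
#'
#' @param name One of "geF1", "geF2", "geF3", "geF4".
#' @return Object of class `binary_task` with `name`, `positive_stages`,
#'   `negative_stages`.
#' @export
binary_task <- function(name = c("geF1", "geF2", "geF3", "geF4")) {
  name <- match.arg(name)
  cut <- as.integer(substring(name, 4))
  structure(list(name = name,
                 positive_stages = cut:4,
                 negative_stages = 0:(cut - 1)),
            class = "binary_task")
}

task_label <- function(task, stage) as.integer(stage %in% task$positive_stages)

#' Mask a spectrum frame to the liver ROI
#'
#' Elementwise product of the spectrum frame with the binary liver mask (the
#' mask is applied along the bin axis exactly as the pipeline defines it), so
#' values outside the liver region become 0.
#'
#' @param spec A `spectrum_frame`.
#' @param mask Binary matrix of the same shape (a liver mask resized to signal
#'   space), or a `liver_mask` object.
#' @return Object of class `roi_spectrum` with `values`, `mask`, `kind`,
#'   `label`, `source_frame_id`, `normalized = FALSE`.
#' @export
apply_mask <- function(spec, mask) {
  stopifnot(inherits(spec, "spectrum_frame"))
  if (inherits(mask, "liver_mask")) mask <- mask$pixels
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(spec$values))) stop("shape mismatch")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  structure(list(values = spec$values * mask, mask = mask, kind = spec$kind,
                 label = spec$label, source_frame_id = spec$source_frame_id,
                 normalized = FALSE),
            class = "roi_spectrum")
}

#' Min-max normalization of an ROI spectrum frame
#'
#' Frame-wide affine map `(R - min(R)) / (max(R) - min(R))`; the masked zeros
#' participate in the min/max. The minimum maps to 0 and the maximum to 1.
#' Idempotent once applied.
#'
#' @param roi A `roi_spectrum`.
#' @return The frame with `values` in \[0,1\] and `normalized = TRUE`.
#' @export
normalize_roi <- function(roi) {
  stopifnot(inherits(roi, "roi_spectrum"))
  lo <- min(roi$values); hi <- max(roi$values)
  if (hi == lo) stop("degenerate frame: max equals min")
  roi$values <- (roi$values - lo) / (hi - lo)
  roi$normalized <- TRUE
  roi
}

# longest contiguous run of 1s in a binary vector -> c(start, length); first
# run wins ties
longest_run <- function(m) {
  r <- rle(as.integer(m))
  if (!any(r$values == 1L)) return(c(0L, 0L))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  one <- which(r$values == 1L)
  k <- one[which.max(r$lengths[one])]
  c(starts[k], r$lengths[k])
}

#' Sliding-gate extraction of ROI spectrum segments
#'
#' For each scan line whose longest contiguous liver run has length
#' `L >= gate_len` (set `strict = TRUE` for `L > gate_len`), slides a
#' `gate_len`-point gate along the run in steps of `gate_step` and extracts
#' every fitting segment. Segments from all lines are concatenated laterally,
#' line order first, gate offset second, giving a `gate_len x L_lateral`
#' matrix. A line with run length L contributes
#' `floor((L - gate_len) / gate_step) + 1` segments.
#'
#' @param roi A normalized `roi_spectrum`.
#' @param gate_len Gate length in points (default 768).
#' @param gate_step Gate step in points (default 20).
#' @param strict If TRUE, require strictly more than `gate_len` liver points.
#' @return Matrix `gate_len x L_lateral`.
#' @export
gate_lines <- function(roi, gate_len = 768L, gate_step = 20L, strict = FALSE) {
  stopifnot(inherits(roi, "roi_spectrum"))
  segs <- list()
  n_elig <- 0L
  for (j in seq_len(ncol(roi$values))) {
    run <- longest_run(roi$mask[, j])
    ok <- if (strict) run[2] > gate_len else run[2] >= gate_len
    if (!ok) next
    n_elig <- n_elig + 1L
    starts <- seq(run[1], run[1] + run[2] - gate_len, by = gate_step)
    for (s0 in starts)
      segs[[length(segs) + 1L]] <- roi$values[s0:(s0 + gate_len - 1L), j]
  }
  if (length(segs) == 0L)
    stop(sprintf("no eligible line (eligible lines: %d)", n_elig))
  do.call(cbind, segs)
}

#' Sliding-window assembly of classifier input frames
#'
#' Slides a `gate_len x 256`-line window over the gated segment matrix in
#' lateral steps of `max(1, floor((L_lateral - 256) / n_aug))` and emits
#' exactly `n_aug` windows; start columns are clipped so every window fits.
#'
#' @param gated Matrix from [gate_lines()] (`gate_len x L_lateral`).
#' @param n_aug Number of windows to emit (>= 1).
#' @param label Binary label attached to each window.
#' @param frame_id Source frame identifier.
#' @param width Window width in lines (default 256).
#' @param pad If TRUE and `L_lateral < width`, reflect-pad laterally instead
#'   of erroring.
#' @return List of `gated_sample` objects (`values` gate_len x width, `label`,
#'   `source_frame_id`, `window_index`).
#' @export
window_frames <- function(gated, n_aug = 1L, label = NA_integer_,
                          frame_id = NULL, width = 256L, pad = FALSE) {
  if (n_aug < 1L) stop("n_aug must be >= 1")
  L <- ncol(gated)
  if (L < width) {
    if (!pad) stop(sprintf("L_lateral = %d < %d lines", L, width))
    while (ncol(gated) < width) {
      k <- min(ncol(gated), width - ncol(gated))
      gated <- cbind(gated, gated[, ncol(gated):(ncol(gated) - k + 1L),
                                  drop = FALSE])
    }
    L <- ncol(gated)
  }
  step <- max(1L, floor((L - width) / n_aug))
  starts <- pmin((seq_len(n_aug) - 1L) * step, L - width)
  lapply(seq_len(n_aug), function(i) {
    s0 <- starts[i]
    structure(list(values = gated[, (s0 + 1L):(s0 + width), drop = FALSE],
                   label = label, source_frame_id = frame_id,
                   window_index = i),
              class = "gated_sample")
  })
}

#' Augmentation factor for class balancing
#'
#' Nearest-integer ratio of majority to minority class counts, at least 1.
#'
#' @param n_major,n_minor Class frame counts.
#' @return Integer augmentation factor.
#' @export
n_aug_factor <- function(n_major, n_minor) {
  if (n_minor <= 0) stop("minority class is empty")
  max(1L, as.integer(round(n_major / n_minor)))
}

#' Split, balance and window ROI spectrum frames for one binary task
#'
#' Splits frames participant-pure into train/validation/test parts,
#' stratified by the task's binary class (per class: floor, floor, remainder,
#' after a seeded shuffle). Within the training part the minority class is
#' augmented: each minority frame yields `n_aug = round(N_major / N_minor)`
#' sliding windows, majority frames one window; validation and test frames
#' always yield one window. A class missing from train or test is an error;
#' missing from validation only raises a warning.
#'
#' @param frames List of normalized `roi_spectrum` frames with stage labels.
#' @param task A [binary_task()].
#' @param ratios Split fractions (default 80:10:10).
#' @param seed RNG seed for the shuffle.
#' @param gate_len,gate_step,strict Passed to [gate_lines()].
#' @return List with `train`, `val`, `test` (lists of `gated_sample`),
#'   `n_aug`, `split` (frame ids per part), `task`.
#' @export
balance_and_assemble <- function(frames, task, ratios = c(0.8, 0.1, 0.1),
                                 seed = 1L, gate_len = 768L, gate_step = 20L,
                                 strict = FALSE) {
  stopifnot(inherits(task, "binary_task"))
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1")
  y <- vapply(frames, function(f) task_label(task, f$label), integer(1))
  if (length(unique(y)) < 2L) stop("both classes must be non-empty")
  set.seed(as.integer(seed))
  part <- character(length(frames))
  for (cl in c(0L, 1L)) {
    idx <- sample(which(y == cl))
    n <- length(idx)
    n1 <- floor(ratios[1] * n); n2 <- floor(ratios[2] * n)
    part[idx[seq_len(n1)]] <- "train"
    if (n2 > 0) part[idx[n1 + seq_len(n2)]] <- "val"
    if (n1 + n2 < n) part[idx[(n1 + n2 + 1):n]] <- "test"
  }
  for (p in c("train", "test")) {
    cls <- unique(y[part == p])
    if (length(cls) < 2L)
      stop(sprintf("a class is absent from the %s part", p))
  }
  if (length(unique(y[part == "val"])) < 2L)
    warning("validation part does not contain both classes")

  tr <- y[part == "train"]
  n_pos <- sum(tr == 1L); n_neg <- sum(tr == 0L)
  minority <- if (n_pos < n_neg) 1L else 0L
  n_aug <- n_aug_factor(max(n_pos, n_neg), min(n_pos, n_neg))

  emit <- function(i, n_windows) {
    g <- gate_lines(frames[[i]], gate_len, gate_step, strict)
    window_frames(g, n_windows, label = y[i],
                  frame_id = frames[[i]]$source_frame_id)
  }
  out <- list(train = list(), val = list(), test = list())
  for (i in seq_along(frames)) {
    p <- part[i]
    nw <- if (p == "train" && y[i] == minority && n_pos != n_neg) n_aug else 1L
    out[[p]] <- c(out[[p]], emit(i, nw))
  }
  out$n_aug <- n_aug
  out$task <- task
  out$split <- split(vapply(frames, function(f)
    if (is.null(f$source_frame_id)) "" else f$source_frame_id, ""), part)
  out
}
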