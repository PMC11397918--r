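#' Envelope detection via the analytic signal
#'
#' Returns the magnitude of the analytic signal of an RF line, i.e. the
#' Hilbert-transform envelope: the carrier is removed and the echo amplitude
#' remains. Computed with the standard FFT construction (double the positive
#' frequencies, zero the negative ones).
#'
#' @param rf_line Finite numeric vector, length >= 2.
#' @return Nonnegative numeric vector of the same length.
#' @export
envelope <- function(rf_line) {
  if (length(rf_line) < 2L) stop("rf_line must have length >= 2")
  if (!all(is.finite(rf_line))) stop("non-finite input")
  n <- length(rf_line)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(rf_line) * h, inverse = TRUE) / n)
}

# frame-wise envelope, batched over scan lines
envelope_frame <- function(samples) {
  n <- nrow(samples)
  if (!all(is.finite(samples))) stop("non-finite input")
  h <- numeric(n)
  if (n %% 2 == 0) { h[c(1, n / 2 + 1)] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  Mod(stats::mvfft(stats::mvfft(samples) * h, inverse = TRUE) / n)
}

#' Logarithmic compression to a B-mode image
#'
#' Maps an envelope frame to display pixels in \[0, 1\] over a decibel dynamic
#' range: `pixel = clip((20*log10(env/env_max) + DR) / DR, 0, 1)`. The frame
#' maximum maps to 1 and anything `DR` dB below it (or less) to 0.
#'
#' @param env Nonnegative matrix (envelope frame) with at least one positive
#'   value.
#' @param dynamic_range_db Dynamic range in decibels (> 0), default 40.
#' @param frame_id Identifier carried on the result.
#' @return Object of class `bmode_image` with `pixels` in \[0,1\] of the same
#'   shape as `env` and `dynamic_range_db`.
#' @export
log_compress <- function(env, dynamic_range_db = 40, frame_id = NULL) {
  env <- as.matrix(env)
  if (any(env < 0)) stop("envelope must be nonnegative")
  m <- max(env)
  if (m <= 0) stop("all-zero envelope: no reference maximum")
  if (dynamic_range_db <= 0) stop("dynamic_range_db must be > 0")
  db <- 20 * log10(env / m)          # -Inf at zeros, clipped below
  px <- pmin(pmax((db + dynamic_range_db) / dynamic_range_db, 0), 1)
  structure(list(pixels = px, dynamic_range_db = dynamic_range_db,
                 source_frame_id = frame_id),
            class = "bmode_image")
}

#' Reconstruct the B-mode image of an RF frame
#'
#' Envelope detection followed by log compression; no scan conversion, so the
#' image stays on the sample-by-line grid.
#'
#' @param frame An `rf_frame`.
#' @param dynamic_range_db Dynamic range in dB.
#' @return A `bmode_image`.
#' @export
bmode <- function(frame, dynamic_range_db = 40) {
  stopifnot(inherits(frame, "rf_frame"))
  log_compress(envelope_frame(frame$samples), dynamic_range_db,
               frame_id = frame$frame_id)
}

#' @export
print.bmode_image <- function(x, ...) {
  cat(sprintf("<bmode_image %s> %d x %d px, dynamic range %g dB\n",
              if (is.null(x$source_frame_id)) "" else x$source_frame_id,
              nrow(x$pixels), ncol(x$pixels), x$dynamic_range_db))
  invisible(x)
}

# Keys bicubic kernel (a = -0.5, Catmull-Rom)
cubic_kernel <- function(t) {
  t <- abs(t); a <- -0.5
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# dense (n_out x n_in) interpolation matrix; edge-clamped, rows sum to 1
bicubic_weights <- function(n_in, n_out) {
  w <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale - 0.5          # 0-based source coordinate
    i0 <- floor(src)
    for (m in -1:2) {
      k <- cubic_kernel(src - (i0 + m))
      j <- min(max(i0 + m, 0), n_in - 1) + 1
      w[i, j] <- w[i, j] + k
    }
  }
  w
}

#' Bicubic image resize
#'
#' Separable bicubic interpolation (Keys kernel, a = -0.5) with edge clamping.
#' A constant image maps to the same constant and resizing to the identical
#' shape is exact.
#'
#' @param img Numeric matrix.
#' @param out_shape Integer vector (height, width), both positive.
#' @return Resized matrix of dimension `out_shape`.
#' @export
resize_image <- function(img, out_shape) {
  img <- as.matrix(img)
  out_shape <- as.integer(out_shape)
  if (length(out_shape) != 2L || any(out_shape < 1L))
    stop("out_shape must be two positive integers")
  wr <- bicubic_weights(nrow(img), out_shape[1])
  wc <- bicubic_weights(ncol(img), out_shape[2])
  wr %*% img %*% t(wc)
}

#' Rotate a matrix by a multiple of 90 degrees
#'
#' Exact array rotation (no interpolation); `k` quarter-turns
#' counter-clockwise. Rotating a non-square matrix by 90/270 degrees swaps its
#' dimensions.
#'
#' @param img Matrix.
#' @param k Number of quarter turns (0..3).
#' @return Rotated matrix.
#' @export
rotate90 <- function(img, k) {
  k <- k %% 4
  if (k == 0) return(img)
  if (k == 2) return(img[nrow(img):1, ncol(img):1, drop = FALSE])
  r <- t(img)[ncol(img):1, , drop = FALSE]        # one CCW quarter turn
  rotate90(r, k - 1)
}

#' Participant-level dataset split
#'
#' Shuffles ids with the given seed and splits them into train/validation/test
#' parts: the training part gets `floor(r1 * N)` ids, validation
#' `floor(r2 * N)`, and the test part the remainder (so 613 ids at 60:20:20
#' give 367/122/124). Each id represents one participant, so the split is
#' participant-pure by construction.
#'
#' @param ids Non-empty vector of unique identifiers.
#' @param ratios Three fractions summing to 1.
#' @param seed RNG seed for the shuffle.
#' @return Object of class `dataset_split` with `train`, `val`, `test`,
#'   `ratios`.
#' @export
split_dataset <- function(ids, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  if (length(ids) == 0) stop("ids must be non-empty")
  if (anyDuplicated(ids)) stop("ids must be unique")
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-8)
    stop("ratios must be three fractions summing to 1")
  set.seed(as.integer(seed))
  ids <- sample(ids)
  n <- length(ids)
  n1 <- floor(ratios[1] * n); n2 <- floor(ratios[2] * n)
  if (n1 + n2 >= n || n1 == 0 || n2 == 0) stop("a split part is empty")
  structure(list(train = ids[seq_len(n1)],
                 val = ids[n1 + seq_len(n2)],
                 test = ids[(n1 + n2 + 1):n],
                 ratios = ratios),
            class = "dataset_split")
}

jitter_photometric <- function(img, range = 0.1) {
  b <- runif(1, -range, range)           # brightness
  cgain <- 1 + runif(1, -range, range)   # contrast about the mean
  # saturation jitter is a no-op on single-channel images and is omitted
  m <- mean(img)
  pmin(pmax((img - m) * cgain + m + b, 0), 1)
}

#' Image + mask augmentation for segmentation training
#'
#' Appends exactly one augmented copy per input pair, doubling the count.
#' The augmentation draws a rotation from \{0, 90, 180, 270\} degrees and a
#' random crop of 80-100% area (resized back to the original shape), applied
#' identically to image and mask; brightness/contrast jitter (+-10%) applies
#' to the image only. 90/270-degree rotations of non-square images are resized
#' back to the original shape so batches stay rectangular. Masks are
#' re-binarised at 0.5 after any interpolation.
#'
#' @param images List of numeric matrices in \[0,1\].
#' @param masks List of binary matrices, shapes matching `images`.
#' @param seed RNG seed.
#' @param jitter Photometric jitter half-range.
#' @return List with `images` and `masks`, each of length `2 * length(images)`
#'   (originals first, augmented copies after).
#' @export
augment_images <- function(images, masks, seed = 1L, jitter = 0.1) {
  if (length(images) != length(masks)) stop("images/masks length mismatch")
  for (i in seq_along(images))
    if (!all(dim(images[[i]]) == dim(masks[[i]])))
      stop("image/mask shape mismatch")
  set.seed(as.integer(seed))
  aug_i <- vector("list", length(images))
  aug_m <- vector("list", length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]; msk <- masks[[i]]
    shp <- dim(img)
    k <- sample(0:3, 1)
    img <- rotate90(img, k); msk <- rotate90(msk, k)
    if (k %% 2 == 1) {
      img <- resize_image(img, shp)
      msk <- (resize_image(msk, shp) >= 0.5) * 1L
    }
    a <- runif(1, 0.8, 1)                  # crop area fraction
    s <- sqrt(a)
    h2 <- max(1L, round(shp[1] * s)); w2 <- max(1L, round(shp[2] * s))
    r0 <- sample.int(shp[1] - h2 + 1L, 1); c0 <- sample.int(shp[2] - w2 + 1L, 1)
    img <- resize_image(img[r0:(r0 + h2 - 1L), c0:(c0 + w2 - 1L), drop = FALSE], shp)
    msk <- (resize_image(msk[r0:(r0 + h2 - 1L), c0:(c0 + w2 - 1L), drop = FALSE],
                         shp) >= 0.5) * 1L
    img <- jitter_photometric(pmin(pmax(img, 0), 1), jitter)
    aug_i[[i]] <- img; aug_m[[i]] <- msk
  }
  list(images = c(images, aug_i), masks = c(masks, aug_m))
}
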