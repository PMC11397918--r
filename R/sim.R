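#' Acquisition geometry and pulse parameters
#'
#' Describes the RF acquisition grid: a frame is `n_samples` axial samples by
#' `n_lines` scan lines, digitised at `fs` Hz, insonified with a pulse of
#' centre frequency `fc` Hz and fractional (-6 dB) bandwidth `pulse_bw`.
#' Defaults mirror a 3 MHz convex probe sampled at 12 MHz with 1247-sample
#' lines and 256 lines per frame.
#'
#' @param n_samples Axial samples per scan line (>= 1).
#' @param n_lines Scan lines per frame (>= 1).
#' @param fs Sampling frequency in Hz.
#' @param fc Pulse centre frequency in Hz; must satisfy 0 < fc < fs/2.
#' @param pulse_bw Fractional -6 dB bandwidth of the pulse, in (0, 1].
#' @param seed Default RNG seed carried with the acquisition settings.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(n_samples = 1247L, n_lines = 256L,
                             fs = 12e6, fc = 3e6, pulse_bw = 0.6,
                             seed = 1L) {
  n_samples <- as.integer(n_samples); n_lines <- as.integer(n_lines)
  if (n_samples < 1L || n_lines < 1L)
    stop("n_samples and n_lines must be >= 1")
  if (!(fc > 0 && fc < fs / 2))
    stop("configuration error: need 0 < fc < fs/2")
  if (!(pulse_bw > 0 && pulse_bw <= 1))
    stop("configuration error: pulse_bw must be in (0, 1]")
  structure(list(n_samples = n_samples, n_lines = n_lines, fs = fs, fc = fc,
                 pulse_bw = pulse_bw, seed = as.integer(seed)),
            class = "acquisition_spec")
}

#' Gaussian-enveloped transmit pulse
#'
#' Builds the point-spread pulse used by the simulator: a cosine carrier at
#' `fc` under a Gaussian envelope whose -6 dB width matches the fractional
#' bandwidth, sampled at `fs`. The returned vector has odd length (so it has
#' an exact centre sample) and unit peak amplitude.
#'
#' @param acq An [acquisition_spec()].
#' @return Numeric vector of odd length with `max(abs(.)) == 1`.
#' @export
make_pulse <- function(acq) {
  stopifnot(inherits(acq, "acquisition_spec"))
  sigma_f <- acq$pulse_bw * acq$fc / (2 * sqrt(2 * log(2)))
  sigma_t <- 1 / (2 * pi * sigma_f)
  half <- ceiling(3 * sigma_t * acq$fs)
  t <- (-half:half) / acq$fs
  p <- cos(2 * pi * acq$fc * t) * exp(-t^2 / (2 * sigma_t^2))
  p / max(abs(p))
}

#' Resolution cell length in samples
#'
#' The axial resolution cell is defined as the -6 dB length of the pulse
#' envelope, expressed in samples at the acquisition rate. It sets the scale
#' for the scatterer density parameter (scatterers per resolution cell).
#'
#' @param acq An [acquisition_spec()].
#' @return Length of the -6 dB envelope in samples (numeric scalar).
#' @export
resolution_cell <- function(acq) {
  sigma_f <- acq$pulse_bw * acq$fc / (2 * sqrt(2 * log(2)))
  sigma_t <- 1 / (2 * pi * sigma_f)
  2 * sigma_t * sqrt(2 * log(2)) * acq$fs
}

#' Tissue phantom description for one fibrosis stage
#'
#' Parameterises the synthetic liver phantom. The liver band is delimited per
#' scan line by two smooth cosine-perturbed depth curves; inside the band the
#' backscatter is a diffuse scatterer field whose density and amplitude
#' variability grow with the METAVIR stage, plus a stage-dependent coherent
#' component of quasi-regularly spaced septa-like reflectors that imprints
#' structure on the frequency spectra. Outside the band a brighter
#' abdominal-wall-like field is generated.
#'
#' Stage maps (with `s` the stage and `e = stage_effect`):
#' density per cell `density_base * (1 + density_slope * s * e)`,
#' amplitude CV `cv_base * (1 + cv_slope * s * e)`, and coherent-to-diffuse
#' amplitude ratio `coherent_slope * s * e`.
#'
#' @param stage METAVIR stage, integer in 0..4.
#' @param stage_effect Multiplier on all stage slopes (1 = default contrast;
#'   0 = stages indistinguishable). Used to study separability.
#' @param density_base,density_slope Mean scatterers per resolution cell at
#'   stage 0 and its relative increase per stage.
#' @param cv_base,cv_slope Coefficient of variation of scatterer amplitude
#'   magnitudes at stage 0 and its relative increase per stage.
#' @param coherent_slope Per-stage increase of the coherent (septa) reflector
#'   amplitude, expressed relative to the local diffuse energy over one
#'   spacing period (so stage 4 with slope 0.25 has coherent energy about
#'   equal to diffuse energy).
#' @param septa_spacing,septa_jitter Mean spacing (samples) of the coherent
#'   reflector train and the Gaussian jitter (samples) of each position.
#' @param top_range,bottom_range Uniform sampling ranges (samples) for the
#'   per-frame mean depth of the upper/lower liver boundary. The lower bound
#'   of the bottom draw is raised so the band always admits a 768-sample gate.
#' @param wobble_amp,wobble_cycles Amplitude (samples) and number of cosine
#'   cycles of the lateral boundary perturbation.
#' @param wall_amplitude Echo amplitude of the non-liver band relative to the
#'   stage-0 diffuse liver amplitude.
#' @param wall_density Scatterers per resolution cell outside the liver band.
#' @param min_band Minimum guaranteed liver band height in samples.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(stage, stage_effect = 1,
                         density_base = 10, density_slope = 0.4,
                         cv_base = 0.3, cv_slope = 0.3,
                         coherent_slope = 0.25,
                         septa_spacing = 60, septa_jitter = 3,
                         top_range = c(150, 350),
                         bottom_range = c(900, 1200),
                         wobble_amp = 15, wobble_cycles = 2,
                         wall_amplitude = 2.5, wall_density = 10,
                         min_band = 772) {
  stage <- as.integer(stage)
  if (!stage %in% 0:4) stop("stage must be one of 0,1,2,3,4")
  if (density_base <= 0 || wall_density <= 0) stop("density must be > 0")
  if (density_slope < 0 || cv_slope < 0 || coherent_slope < 0)
    stop("stage slopes must be >= 0 so stage maps stay monotone")
  structure(list(stage = stage, stage_effect = stage_effect,
                 density_base = density_base, density_slope = density_slope,
                 cv_base = cv_base, cv_slope = cv_slope,
                 coherent_slope = coherent_slope,
                 septa_spacing = septa_spacing, septa_jitter = septa_jitter,
                 top_range = top_range, bottom_range = bottom_range,
                 wobble_amp = wobble_amp, wobble_cycles = wobble_cycles,
                 wall_amplitude = wall_amplitude, wall_density = wall_density,
                 min_band = min_band),
            class = "phantom_spec")
}

#' Stage-dependent parameter maps
#'
#' @param phantom A [phantom_spec()].
#' @return Named list with `density` (scatterers per resolution cell),
#'   `cv` (amplitude coefficient of variation) and `coherent` (coherent-to-
#'   diffuse amplitude ratio) at the phantom's stage.
#' @export
stage_params <- function(phantom) {
  s <- phantom$stage * phantom$stage_effect
  list(density = phantom$density_base * (1 + phantom$density_slope * s),
       cv = phantom$cv_base * (1 + phantom$cv_slope * s),
       coherent = phantom$coherent_slope * s)
}

# Gamma-distributed magnitudes with mean 1 and coefficient of variation cv,
# signed by a fair coin: a diffuse reflectivity model.
draw_amplitudes <- function(n, cv) {
  if (n == 0L) return(numeric(0))
  if (cv <= 0) mag <- rep(1, n)
  else mag <- rgamma(n, shape = 1 / cv^2, scale = cv^2)
  mag * (2 * rbinom(n, 1L, 0.5) - 1)
}

#' Simulate one labeled RF frame
#'
#' Generates a frame of backscattered RF signals by per-line impulse-train
#' convolution with the transmit pulse: Poisson scatterer counts, uniform
#' depths and gamma-distributed amplitude magnitudes with random sign. Inside
#' the liver band the stage maps of `phantom` apply and a coherent
#' quasi-periodic reflector train is added; outside, wall statistics apply.
#' The ground-truth liver mask and the stage label travel with the frame.
#' Fully reproducible from `seed`.
#'
#' @param phantom A [phantom_spec()].
#' @param acq An [acquisition_spec()].
#' @param seed Integer RNG seed for this frame.
#' @param frame_id Optional identifier string.
#' @return An object of class `rf_frame` with elements `samples`
#'   (n_samples x n_lines), `acq`, `label`, `truth_mask`, `top`, `bottom`,
#'   `frame_id`, `seed`.
#' @export
simulate_frame <- function(phantom, acq = acquisition_spec(), seed = 1L,
                           frame_id = NULL) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(acq, "acquisition_spec"))
  set.seed(as.integer(seed))
  ns <- acq$n_samples; nl <- acq$n_lines
  pulse <- make_pulse(acq)
  cell <- resolution_cell(acq)
  sp <- stage_params(phantom)
  dens_samp <- sp$density / cell                 # scatterers per sample, liver
  wall_samp <- phantom$wall_density / cell

  # boundary curves: per-frame mean depths, cosine wobble along the lateral axis
  top0 <- runif(1, phantom$top_range[1], phantom$top_range[2])
  blo <- max(phantom$bottom_range[1],
             top0 + phantom$min_band + 2 * phantom$wobble_amp + 4)
  if (blo >= phantom$bottom_range[2])
    stop("empty liver band: boundary ranges leave no room for the band")
  bot0 <- runif(1, blo, phantom$bottom_range[2])
  ph1 <- runif(1, 0, 2 * pi); ph2 <- runif(1, 0, 2 * pi)
  l <- seq_len(nl)
  wob <- 2 * pi * phantom$wobble_cycles * l / nl
  top <- round(top0 + phantom$wobble_amp * cos(wob + ph1))
  bottom <- round(bot0 + phantom$wobble_amp * cos(wob + ph2))
  top <- pmax(1L, pmin(as.integer(top), ns - 1L))
  bottom <- pmax(top + 1L, pmin(as.integer(bottom), ns))
  if (any(bottom <= top)) stop("empty liver band on some line")

  # energy scale of the diffuse liver field at this stage, per spacing period
  coh_amp <- sp$coherent *
    sqrt(phantom$septa_spacing * dens_samp * (1 + sp$cv^2))

  imp <- matrix(0, ns, nl)
  mask <- matrix(0L, ns, nl)
  for (j in l) {
    rows <- top[j]:bottom[j]
    mask[rows, j] <- 1L
    # diffuse liver scatterers
    n_liv <- rpois(1, length(rows) * dens_samp)
    if (n_liv > 0) {
      at <- sample(rows, n_liv, replace = TRUE)
      a <- draw_amplitudes(n_liv, sp$cv)
      for (k in seq_len(n_liv)) imp[at[k], j] <- imp[at[k], j] + a[k]
    }
    # coherent septa-like reflector train (stage-dependent)
    if (coh_amp > 0) {
      off <- runif(1, 0, phantom$septa_spacing)
      pos <- seq(top[j] + off, bottom[j], by = phantom$septa_spacing)
      if (length(pos) > 0) {
        pos <- round(pos + rnorm(length(pos), 0, phantom$septa_jitter))
        pos <- pos[pos >= top[j] & pos <= bottom[j]]
        imp[pos, j] <- imp[pos, j] + coh_amp
      }
    }
    # non-liver (wall) scatterers above and below the band
    out_rows <- c(seq_len(top[j] - 1L), if (bottom[j] < ns) (bottom[j] + 1L):ns)
    if (length(out_rows) > 0) {
      n_wall <- rpois(1, length(out_rows) * wall_samp)
      if (n_wall > 0) {
        at <- sample(out_rows, n_wall, replace = TRUE)
        a <- phantom$wall_amplitude * draw_amplitudes(n_wall, phantom$cv_base)
        for (k in seq_len(n_wall)) imp[at[k], j] <- imp[at[k], j] + a[k]
      }
    }
  }

  samples <- convolve_lines(imp, pulse)
  structure(list(samples = samples, acq = acq, label = phantom$stage,
                 truth_mask = mask, top = top, bottom = bottom,
                 phantom = phantom, seed = as.integer(seed),
                 frame_id = if (is.null(frame_id))
                   sprintf("frame_s%d_seed%d", phantom$stage, seed)
                 else frame_id),
            class = "rf_frame")
}

# 'same' convolution of every column of imp with a centred odd-length pulse,
# via one batched FFT (mvfft) over all scan lines.
convolve_lines <- function(imp, pulse) {
  ns <- nrow(imp); nl <- ncol(imp)
  lp <- length(pulse); half <- (lp - 1L) / 2L
  n <- ns + lp - 1L
  fi <- stats::mvfft(rbind(imp, matrix(0, lp - 1L, nl)))
  fp <- stats::fft(c(pulse, rep(0, ns - 1L)))
  full <- Re(stats::mvfft(fi * fp, inverse = TRUE)) / n
  full[(half + 1L):(half + ns), , drop = FALSE]
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("<rf_frame %s> %d x %d samples, stage F%d, seed %d\n",
              x$frame_id, nrow(x$samples), ncol(x$samples), x$label, x$seed))
  invisible(x)
}

#' Per-stage frame counts following the reference cohort proportions
#'
#' Distributes `total` frames over stages F0..F4 in the proportions
#' 27:49:51:49:61 (largest-remainder rounding), so `total = 237` recovers the
#' counts (27, 49, 51, 49, 61) exactly.
#'
#' @param total Total number of frames.
#' @return Integer vector of length 5 (stages 0..4) summing to `total`.
#' @export
stage_proportions <- function(total) {
  ref <- c(27, 49, 51, 49, 61)
  p <- ref / sum(ref)
  base <- floor(p * total)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- p * total - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

# counter-based per-frame seed derivation: order-independent, < 2^31
frame_seed <- function(master, i) {
  as.integer((as.double(master) * 1000003 + 7919 * as.double(i)) %% 2147483629) + 1L
}

#' Simulate a labeled dataset of RF frames
#'
#' Either a balanced design (`n_per_stage` frames for each stage in `stages`)
#' or a cohort-proportioned design (`mode = "paper"` with `total` frames split
#' per [stage_proportions()]). Per-frame seeds are derived from the master
#' seed by a counter so the dataset is reproducible and order-independent.
#'
#' @param n_per_stage Frames per stage (balanced mode).
#' @param total Total frames (proportions mode).
#' @param mode "balanced" or "paper" (cohort proportions).
#' @param stages Stages to include (balanced mode only).
#' @param acq An [acquisition_spec()].
#' @param seed Master seed.
#' @param ... Passed to [phantom_spec()] (e.g. `stage_effect`).
#' @return List of [simulate_frame()] results, grouped by stage.
#' @export
simulate_dataset <- function(n_per_stage = NULL, total = NULL,
                             mode = c("balanced", "paper"), stages = 0:4,
                             acq = acquisition_spec(), seed = 1L, ...) {
  mode <- match.arg(mode)
  if (mode == "paper") {
    if (is.null(total)) stop("proportions mode needs `total`")
    counts <- stage_proportions(total)
    stages <- 0:4
  } else {
    if (is.null(n_per_stage) || n_per_stage < 1)
      stop("n_per_stage must be >= 1")
    counts <- rep(as.integer(n_per_stage), length(stages))
  }
  frames <- vector("list", sum(counts))
  i <- 0L
  for (k in seq_along(stages)) {
    ph <- phantom_spec(stage = stages[k], ...)
    for (r in seq_len(counts[k])) {
      i <- i + 1L
      frames[[i]] <- simulate_frame(ph, acq, seed = frame_seed(seed, i),
                                    frame_id = sprintf("P%03d_F%d", i, stages[k]))
    }
  }
  frames
}

#' Write an RF dataset container
#'
#' Serialises frames into a single container file with documented keys
#' `rf` (float array frames x n_samples x n_lines), `mask` (integer array),
#' `label` (integer vector), `meta` (JSON string), and writes a CSV manifest
#' (frame_id, stage, seed) next to it.
#'
#' @param frames List of `rf_frame` objects.
#' @param file Output path (RDS container).
#' @param manifest Manifest CSV path; default replaces the extension.
#' @return `file`, invisibly.
#' @export
write_rf_dataset <- function(frames, file,
                             manifest = paste0(tools::file_path_sans_ext(file),
                                               "_manifest.csv")) {
  ns <- nrow(frames[[1]]$samples); nl <- ncol(frames[[1]]$samples)
  n <- length(frames)
  rf <- array(0, c(n, ns, nl)); mk <- array(0L, c(n, ns, nl))
  for (i in seq_len(n)) {
    rf[i, , ] <- frames[[i]]$samples
    mk[i, , ] <- frames[[i]]$truth_mask
  }
  meta <- jsonlite::toJSON(list(acq = unclass(frames[[1]]$acq),
                                frame_id = vapply(frames, `[[`, "", "frame_id")),
                           auto_unbox = TRUE)
  obj <- list(rf = rf, mask = mk,
              label = vapply(frames, `[[`, integer(1), "label"),
              seed = vapply(frames, `[[`, integer(1), "seed"),
              meta = as.character(meta))
  saveRDS(obj, file)
  write.csv(data.frame(frame_id = vapply(frames, `[[`, "", "frame_id"),
                       stage = obj$label, seed = obj$seed),
            manifest, row.names = FALSE)
  invisible(file)
}

#' Read an RF dataset container written by [write_rf_dataset()]
#'
#' @param file Container path.
#' @return List of `rf_frame` objects.
#' @export
read_rf_dataset <- function(file) {
  obj <- readRDS(file)
  meta <- jsonlite::fromJSON(obj$meta)
  acq <- do.call(acquisition_spec, as.list(meta$acq))
  lapply(seq_along(obj$label), function(i) {
    structure(list(samples = obj$rf[i, , ], acq = acq, label = obj$label[i],
                   truth_mask = matrix(as.integer(obj$mask[i, , ]),
                                       nrow = dim(obj$mask)[2]),
                   seed = obj$seed[i], frame_id = meta$frame_id[i]),
              class = "rf_frame")
  })
}
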