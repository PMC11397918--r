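#' Frequency spectrum of one scan line
#'
#' Computes the full-length two-sided FFT of a scan line (no windowing, no
#' zero-padding) and returns the requested spectrum: amplitude `|S|`, phase
#' `angle(S)` or power `|S|^2 / N`. Bins are in standard FFT order (DC first,
#' then positive, then negative frequencies). The phase of an exactly zero
#' bin is 0.
#'
#' @param s Finite numeric vector (one scan line).
#' @param kind One of "amplitude", "phase", "power".
#' @return Numeric vector of the same length as `s`.
#' @export
spectrum_line <- function(s, kind = c("amplitude", "phase", "power")) {
  kind <- match.arg(kind)
  if (!all(is.finite(s))) stop("non-finite input")
  sf <- stats::fft(s)
  switch(kind,
         amplitude = Mod(sf),
         phase = Arg(sf),
         power = Mod(sf)^2 / length(s))
}

#' Per-line frequency spectra of an RF frame
#'
#' Applies [spectrum_line()] independently to each scan line (column) of the
#' frame; columns keep their input order. Shape is preserved, so a 1247 x 256
#' frame yields a 1247 x 256 spectrum frame.
#'
#' @param rf An `rf_frame`, or a numeric matrix (samples x lines).
#' @param kind Spectrum kind, see [spectrum_line()].
#' @return Object of class `spectrum_frame` with `values`, `kind`, `label`,
#'   `source_frame_id`.
#' @export
spectrum_frame <- function(rf, kind = c("amplitude", "phase", "power")) {
  kind <- match.arg(kind)
  if (inherits(rf, "rf_frame")) {
    samples <- rf$samples; fid <- rf$frame_id; label <- rf$label
  } else {
    samples <- as.matrix(rf); fid <- NULL; label <- NULL
  }
  if (!all(is.finite(samples))) stop("non-finite input")
  sf <- stats::mvfft(samples)
  values <- switch(kind,
                   amplitude = Mod(sf),
                   phase = Arg(sf),
                   power = Mod(sf)^2 / nrow(samples))
  structure(list(values = values, kind = kind, label = label,
                 source_frame_id = fid),
            class = "spectrum_frame")
}

#' @export
print.spectrum_frame <- function(x, ...) {
  cat(sprintf("<spectrum_frame %s> %s, %d x %d\n",
              if (is.null(x$source_frame_id)) "" else x$source_frame_id,
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}
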