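#' Bispectral frequency resolution rule
#'
#' The bifrequency grid uses the fractional power of two `2^(-k)` (Hz) closest
#' to the experimental spectral resolution `fs / segment_length`. For
#' 500-sample segments at 100 Hz the experimental resolution is 0.2 Hz and the
#' selected bispectral resolution is 0.25 Hz.
#'
#' @param fs Sampling rate in Hz.
#' @param segment_length Segment length in samples.
#' @return The selected resolution in Hz.
#' @examples
#' bispectral_resolution(100, 500) # 0.25
#' @export
bispectral_resolution <- function(fs, segment_length) {
  stopifnot(fs > 0, segment_length > 0)
  df_exp <- fs / segment_length
  k <- c(floor(log2(df_exp)), ceiling(log2(df_exp)))
  cand <- 2^k
  cand[which.min(abs(cand - df_exp))]
}

#' Welch segmentation plan
#'
#' Fixes the segmentation and frequency grid used by all spectral estimators:
#' segments of `segment_length` samples sliding with `overlap` fraction across
#' the concatenated record, transformed over `dft_length = fs / delta_f`
#' points so that the grid step `delta_f` is the fractional power of two
#' closest to the experimental resolution (see [bispectral_resolution()]).
#' Segments longer than `dft_length` are truncated, shorter ones zero-padded.
#'
#' @param fs Sampling rate in Hz.
#' @param segment_length Segment length in samples (defaults to one epoch of
#'   the study settings, 500 samples).
#' @param overlap Overlap fraction between consecutive segments, default 0.5.
#' @param delta_f Grid resolution in Hz; by default the power-of-two rule.
#' @return An object of class `segment_plan` with fields `segment_length`,
#'   `overlap`, `step`, `dft_length`, `delta_f`, `f_nyquist`.
#' @export
segment_plan <- function(fs, segment_length = 500L, overlap = 0.5,
                         delta_f = bispectral_resolution(fs, segment_length)) {
  stopifnot(fs > 0, segment_length >= 2, overlap >= 0, overlap < 1,
            delta_f > 0)
  dft_length <- fs / delta_f
  if (abs(dft_length - round(dft_length)) > 1e-9) {
    stop("fs / delta_f must be an integer DFT length")
  }
  step <- max(1L, as.integer(round(segment_length * (1 - overlap))))
  structure(list(fs = fs, segment_length = as.integer(segment_length),
                 overlap = overlap, step = step,
                 dft_length = as.integer(round(dft_length)),
                 delta_f = delta_f, f_nyquist = fs / 2),
            class = "segment_plan")
}

#' @export
print.segment_plan <- function(x, ...) {
  cat(sprintf("<segment_plan> %d-sample segments, %.0f%% overlap, DFT %d -> delta_f = %g Hz, Nyquist %g Hz\n",
              x$segment_length, 100 * x$overlap, x$dft_length, x$delta_f,
              x$f_nyquist))
  invisible(x)
}

#' Segment an epoched series and compute per-segment spectra
#'
#' Applies Welch segmentation to the concatenated record: overlapping
#' segments slide across epoch boundaries (set `per_epoch = TRUE` to restart
#' segmentation at each epoch instead). Each segment is mean-removed and
#' variance-normalised per channel, truncated or zero-padded to the plan's
#' DFT length, and transformed without taper.
#'
#' @param series An [epoched_series()].
#' @param plan A [segment_plan()]; defaults to the study plan for the series'
#'   sampling rate and epoch length.
#' @param per_epoch Restart segmentation at each epoch boundary.
#' @return An object of class `segment_spectra`: complex array
#'   `dft_length x segments x channels` plus grid metadata.
#' @examples
#' sim <- simulate_condition(condition_spec(8.5, 10.5, 9.5, n_epochs = 2,
#'                                          seed = 1))
#' sp <- segment_series(sim)
#' sp$L # 3 segments from 2 epochs at 50% overlap
#' @export
segment_series <- function(series, plan = NULL, per_epoch = FALSE) {
  if (!inherits(series, "epoched_series")) {
    stop("'series' must be an epoched_series")
  }
  d <- dim(series$data)
  if (is.null(plan)) {
    plan <- segment_plan(series$fs, segment_length = min(d[1], 500L))
  }
  if (plan$segment_length > d[1] * (if (per_epoch) 1L else d[2])) {
    stop("record shorter than one segment")
  }
  if (per_epoch && plan$segment_length > d[1]) {
    stop("epoch shorter than one segment")
  }
  starts <- if (per_epoch) {
    per <- seq(1L, d[1] - plan$segment_length + 1L, by = plan$step)
    as.vector(outer(per, (seq_len(d[2]) - 1L) * d[1], "+"))
  } else {
    seq(1L, d[1] * d[2] - plan$segment_length + 1L, by = plan$step)
  }
  L <- length(starts)
  nf <- plan$dft_length
  take <- min(nf, plan$segment_length)
  spec <- array(complex(real = 0), dim = c(nf, L, d[3]))
  for (ch in seq_len(d[3])) {
    x <- as.vector(series$data[, , ch])
    segs <- matrix(0, nrow = nf, ncol = L)
    for (s in seq_len(L)) {
      seg <- x[starts[s]:(starts[s] + plan$segment_length - 1L)]
      seg <- seg - mean(seg)
      sdv <- stats::sd(seg)
      if (sdv > 0) seg <- seg / sdv
      segs[seq_len(take), s] <- seg[seq_len(take)]
    }
    # re-centre after truncation so the DC bin is exactly zero
    segs <- sweep(segs, 2L, colMeans(segs))
    spec[, , ch] <- stats::mvfft(segs)
  }
  structure(list(spectra = spec, L = L, fs = plan$fs,
                 delta_f = plan$delta_f, f_nyquist = plan$f_nyquist,
                 dft_length = nf, channels = series$channels,
                 plan = plan),
            class = "segment_spectra")
}

#' @export
print.segment_spectra <- function(x, ...) {
  cat(sprintf("<segment_spectra> %d channel(s), L = %d segments, delta_f = %g Hz\n",
              dim(x$spectra)[3], x$L, x$delta_f))
  invisible(x)
}
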