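#' Carrier waveform specification
#'
#' Describes one periodic carrier of the three-channel model: a triangular,
#' rectangular or cosine wave of frequency `frequency` (Hz) with initial phase
#' `phase` (radians). In the simulator the phase is redrawn independently for
#' every epoch from Uniform\[0, 2pi).
#'
#' @param kind One of `"triangular"`, `"rectangular"`, `"cosine"`.
#' @param frequency Carrier frequency in Hz, > 0.
#' @param phase Initial phase in radians (reduced modulo 2pi).
#' @return An object of class `waveform_spec`.
#' @examples
#' w <- waveform_spec("triangular", frequency = 1)
#' waveform_sample(w, t = 0.25) # peak of the triangular wave: pi
#' @export
waveform_spec <- function(kind = c("triangular", "rectangular", "cosine"),
                          frequency, phase = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(frequency) || length(frequency) != 1L ||
      !is.finite(frequency) || frequency <= 0) {
    stop("'frequency' must be a single positive finite number (Hz)")
  }
  if (!is.numeric(phase) || length(phase) != 1L || !is.finite(phase)) {
    stop("'phase' must be a single finite number (radians)")
  }
  structure(list(kind = kind, frequency = frequency,
                 phase = phase %% (2 * pi)),
            class = "waveform_spec")
}

#' Sample a carrier waveform
#'
#' Evaluates the carrier at times `t` (seconds). The triangular wave is
#' `2 asin(sin(2 pi F t + omega))` with range \[-pi, pi\]; the rectangular wave
#' is +1 when `(2 pi F t + omega) mod 2pi` falls in \[0, pi) and -1 otherwise;
#' the cosine wave is `cos(2 pi F t + omega)`.
#'
#' @param spec A [waveform_spec()].
#' @param t Numeric vector of times in seconds.
#' @return Numeric vector of samples, same length as `t`.
#' @export
waveform_sample <- function(spec, t) {
  if (!inherits(spec, "waveform_spec")) {
    stop("'spec' must be a waveform_spec")
  }
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t))) {
    stop("'t' must be finite numeric")
  }
  arg <- 2 * pi * spec$frequency * t + spec$phase
  switch(spec$kind,
    triangular = 2 * asin(sin(arg)),
    rectangular = ifelse(arg %% (2 * pi) < pi, 1, -1),
    cosine = cos(arg),
    stop("unknown waveform kind: ", spec$kind)
  )
}

#' @export
print.waveform_spec <- function(x, ...) {
  cat(sprintf("<waveform_spec> %s, F = %.6g Hz, phase = %.4g rad\n",
              x$kind, x$frequency, x$phase))
  invisible(x)
}

#' Carrier frequency set of the simulation study
#'
#' The six carrier frequencies (Hz) used throughout the simulation study:
#' `70/2pi`, `80/2pi`, `120/2pi`, `150/2pi`, `230/2pi` and `50 - 10/2pi`.
#' Dividing by `2pi` cancels the `2pi` in the trigonometric arguments so the
#' carriers are deliberately off any rational frequency grid.
#'
#' @return Named numeric vector of frequencies in Hz.
#' @export
study_frequencies <- function() {
  c("70/2pi"     = 70 / (2 * pi),
    "80/2pi"     = 80 / (2 * pi),
    "120/2pi"    = 120 / (2 * pi),
    "150/2pi"    = 150 / (2 * pi),
    "230/2pi"    = 230 / (2 * pi),
    "50-10/2pi"  = 50 - 10 / (2 * pi))
}

#' Coupling strengths of the simulation study
#'
#' @return Numeric vector of the six coupling strengths, weak to strong.
#' @export
study_couplings <- function() {
  c(0.025, 0.050, 0.075, 0.150, 0.300, 0.750)
}

# Harmonic line decomposition of a carrier: frequencies (multiples of F) and
# amplitudes of the Fourier series, truncated so that at least `1 - tol` of
# the waveform power is retained.
#   triangular: odd k, amplitude 8/(pi k^2), power sum pi^2/3
#   rectangular: odd k, amplitude 4/(pi k), power sum 1
#   cosine: k = 1, amplitude 1, power 1/2
waveform_harmonics <- function(kind, tol = 1e-3) {
  switch(kind,
    cosine = data.frame(k = 1, amplitude = 1),
    triangular = {
      k <- seq(1, 15, by = 2) # captures > 99.99% of pi^2/3
      data.frame(k = k, amplitude = 8 / (pi * k^2))
    },
    rectangular = {
      # power tail beyond harmonic K is ~ 1/(2K) of sum(8/pi^2 k^-2)
      kmax <- max(15, 2 * ceiling(1 / (2 * tol * pi^2 / 4)) + 1)
      k <- seq(1, kmax, by = 2)
      data.frame(k = k, amplitude = 4 / (pi * k))
    },
    stop("unknown waveform kind: ", kind)
  )
}

# Fold a frequency into (0, fs/2] by aliasing: f -> f mod fs, reflected at
# the Nyquist frequency.
fold_frequency <- function(f, fs) {
  f <- abs(f) %% fs
  ifelse(f > fs / 2, fs - f, f)
}
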