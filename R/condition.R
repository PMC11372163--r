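#' Experimental condition of the three-channel model
#'
#' Bundles the parameters of one simulated condition: the three carrier
#' frequencies (Hz), the coupling strength `W` between channels 1 and 2 into
#' channel 3, the sampling rate, the epoch layout and the noise level. The
#' carrying frequency `F3` must be distinct from `F1`, `F2` and `F1 + F2`
#' (otherwise the output carrier is confounded with the coupling line); pass
#' `allow_degenerate = TRUE` to explore such conditions anyway.
#'
#' @param F1,F2,F3 Carrier frequencies in Hz (> 0).
#' @param W Coupling strength, dimensionless, >= 0.
#' @param fs Sampling rate in Hz.
#' @param epoch_duration Epoch length in seconds; `fs * epoch_duration` must be
#'   an integer number of samples.
#' @param n_epochs Number of independent epochs.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed making the simulation reproducible.
#' @param allow_degenerate Allow `F3` in `{F1, F2, F1 + F2}`.
#' @return An object of class `condition_spec`.
#' @examples
#' cond <- condition_spec(F1 = 120 / (2 * pi), F2 = 70 / (2 * pi),
#'                        F3 = 80 / (2 * pi), W = 0.05, seed = 1)
#' cond
#' @export
condition_spec <- function(F1, F2, F3, W = 0,
                           fs = 100, epoch_duration = 5, n_epochs = 128,
                           noise_sd = 1, seed = 1L,
                           allow_degenerate = FALSE) {
  stopifnot(is.numeric(F1), F1 > 0, is.numeric(F2), F2 > 0,
            is.numeric(F3), F3 > 0, is.numeric(W), W >= 0,
            fs > 0, epoch_duration > 0, n_epochs >= 1, noise_sd >= 0)
  ns <- fs * epoch_duration
  if (abs(ns - round(ns)) > 1e-9) {
    stop("fs * epoch_duration must be an integer number of samples")
  }
  tol <- 1e-9
  if (!allow_degenerate &&
      any(abs(F3 - c(F1, F2, F1 + F2)) < tol)) {
    stop("F3 must be distinct from F1, F2 and F1 + F2 ",
         "(use allow_degenerate = TRUE to override)")
  }
  structure(list(F1 = F1, F2 = F2, F3 = F3, W = W,
                 fs = fs, epoch_duration = epoch_duration,
                 n_epochs = as.integer(n_epochs),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "condition_spec")
}

#' @export
print.condition_spec <- function(x, ...) {
  cat("<condition_spec>\n")
  cat(sprintf("  F1 = %.4f Hz (triangular), F2 = %.4f Hz (rectangular), F3 = %.4f Hz (cosine)\n",
              x$F1, x$F2, x$F3))
  cat(sprintf("  W = %.3f, fs = %g Hz, %d epochs x %g s, noise sd = %g, seed = %d\n",
              x$W, x$fs, x$n_epochs, x$epoch_duration, x$noise_sd, x$seed))
  invisible(x)
}
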