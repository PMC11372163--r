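#' Epoched multichannel series container
#'
#' Holds multichannel samples organised as equal-length epochs together with
#' the sampling rate. `data` is a numeric array with dimensions
#' `samples x epochs x channels`.
#'
#' @param data Numeric array `samples x epochs x channels`.
#' @param fs Sampling rate in Hz.
#' @param channels Character vector of channel names.
#' @param condition Optional [condition_spec()] the series was generated from.
#' @return An object of class `epoched_series`.
#' @export
epoched_series <- function(data, fs, channels = NULL, condition = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("'data' must be a 3-d array (samples x epochs x channels)")
  }
  if (is.null(channels)) {
    channels <- dimnames(data)[[3]]
    if (is.null(channels)) channels <- paste0("X", seq_len(dim(data)[3]))
  }
  if (length(channels) != dim(data)[3]) {
    stop("length of 'channels' must match the third dimension of 'data'")
  }
  dimnames(data) <- list(NULL, NULL, channels)
  structure(list(data = data, fs = fs, channels = channels,
                 condition = condition),
            class = "epoched_series")
}

#' @export
print.epoched_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_series> %d channel(s) x %d epoch(s) x %d samples @ %g Hz (%g s total)\n",
              d[3], d[2], d[1], x$fs, d[1] * d[2] / x$fs))
  invisible(x)
}

#' @export
as.data.frame.epoched_series <- function(x, ...) {
  d <- dim(x$data)
  out <- data.frame(
    epoch = rep(seq_len(d[2]), each = d[1]),
    sample = rep(seq_len(d[1]), times = d[2])
  )
  for (ch in seq_len(d[3])) {
    out[[x$channels[ch]]] <- as.vector(x$data[, , ch])
  }
  out
}

# Channel vector over the concatenated record (epochs in order).
channel_vector <- function(series, channel) {
  as.vector(series$data[, , channel])
}

#' Simulate the three-channel bifrequency-interaction model
#'
#' Generates the noisy instantaneous-multiplier model: channel 1 carries a
#' triangular wave at `F1`, channel 2 a rectangular wave at `F2`, and channel 3
#' receives the point-wise product of channels 1 and 2 scaled by the coupling
#' strength `W` plus a cosine carrier at `F3`:
#' \deqn{X_1 = I_1 + \xi_1,\quad X_2 = I_2 + \xi_2,\quad
#'       X_3 = W X_1 X_2 + I_3 + \xi_3.}
#' Carrier phases are drawn independently per epoch from Uniform\[0, 2pi) and
#' the additive noise is i.i.d. Gaussian, independent across epochs and
#' channels. The whole realisation is reproducible from `cond$seed`: phases
#' are drawn first (3 x n_epochs), then the noise array, in one seeded stream.
#'
#' @param cond A [condition_spec()].
#' @return An [epoched_series()] with channels `X1`, `X2`, `X3`.
#' @examples
#' cond <- condition_spec(F1 = 8.5, F2 = 10.5, F3 = 9.5, W = 0.3,
#'                        n_epochs = 4, seed = 42)
#' sim <- simulate_condition(cond)
#' sim
#' @export
simulate_condition <- function(cond) {
  if (!inherits(cond, "condition_spec")) stop("'cond' must be a condition_spec")
  ns <- as.integer(round(cond$fs * cond$epoch_duration))
  ne <- cond$n_epochs
  t <- (seq_len(ns) - 1L) / cond$fs

  set.seed(cond$seed)
  phases <- matrix(stats::runif(3L * ne, 0, 2 * pi), nrow = 3L)
  noise <- array(stats::rnorm(ns * ne * 3L, sd = cond$noise_sd),
                 dim = c(ns, ne, 3L))

  data <- array(0, dim = c(ns, ne, 3L))
  for (e in seq_len(ne)) {
    i1 <- waveform_sample(waveform_spec("triangular", cond$F1, phases[1L, e]), t)
    i2 <- waveform_sample(waveform_spec("rectangular", cond$F2, phases[2L, e]), t)
    i3 <- waveform_sample(waveform_spec("cosine", cond$F3, phases[3L, e]), t)
    x1 <- i1 + noise[, e, 1L]
    x2 <- i2 + noise[, e, 2L]
    x3 <- cond$W * x1 * x2 + i3 + noise[, e, 3L]
    data[, e, 1L] <- x1
    data[, e, 2L] <- x2
    data[, e, 3L] <- x3
  }
  out <- epoched_series(data, fs = cond$fs, channels = c("X1", "X2", "X3"),
                        condition = cond)
  attr(out, "phases") <- phases # 3 x n_epochs, for diagnostics
  out
}
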