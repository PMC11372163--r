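#' Analytic signal-to-noise ratio of a model channel
#'
#' Closed-form SNR of the three model channels with unit-variance noise:
#' channel 1 (triangular carrier) has SNR `pi^2/3`; channel 2 (rectangular
#' carrier) has SNR 1; channel 3 has SNR `(2 pi^2 / 3 + 2) W^2 + 1/2`, the
#' quadratic term being the power of the product `W X1 X2` relative to unit
#' noise and the 1/2 the cosine carrier power.
#'
#' @param channel Channel index, 1, 2 or 3.
#' @param W Coupling strength (used only for channel 3).
#' @return The expected SNR (dimensionless).
#' @examples
#' expected_snr(1)      # pi^2 / 3
#' expected_snr(3, 0)   # 0.5
#' @export
expected_snr <- function(channel, W = 0) {
  if (!is.numeric(channel) || length(channel) != 1L ||
      !(channel %in% 1:3)) {
    stop("'channel' must be 1, 2 or 3")
  }
  if (!is.numeric(W) || length(W) != 1L || W < 0) {
    stop("'W' must be a single non-negative number")
  }
  switch(channel,
         pi^2 / 3,
         1,
         (2 * pi^2 / 3 + 2) * W^2 + 0.5)
}

# Declared spectral line frequencies (Hz, folded into (0, Nyquist]) for one
# channel of the model. Channel 3 includes the intermodulation products
# |k F1 +/- l F2| of the two carriers when W > 0.
declared_lines <- function(channel, cond) {
  fs <- cond$fs
  lines <- switch(channel,
    {
      h <- waveform_harmonics("triangular")
      data.frame(f = h$k * cond$F1, a = h$amplitude)
    },
    {
      h <- waveform_harmonics("rectangular")
      data.frame(f = h$k * cond$F2, a = h$amplitude)
    },
    {
      out <- data.frame(f = cond$F3, a = 1)
      if (cond$W > 0) {
        k <- seq(1, 5, by = 2)   # triangular harmonics of the product
        l <- seq(1, 21, by = 2)  # rectangular harmonics of the product
        kl <- expand.grid(k = k, l = l)
        a <- (8 / (pi * kl$k^2)) * (4 / (pi * kl$l)) / 2
        out <- rbind(out,
                     data.frame(f = kl$k * cond$F1 + kl$l * cond$F2, a = a),
                     data.frame(f = abs(kl$k * cond$F1 - kl$l * cond$F2), a = a))
      }
      out
    })
  lines$f <- fold_frequency(lines$f, fs)
  lines <- lines[lines$f > 1e-9, , drop = FALSE]
  # strongest lines first, then collapse aliases onto the same frequency
  lines <- lines[order(-lines$a), , drop = FALSE]
  lines <- lines[!duplicated(round(lines$f * 1e8)), , drop = FALSE]
  lines$f
}

#' Empirical signal-to-noise ratio of simulated channels
#'
#' Estimates the per-channel SNR of an epoched series generated by
#' [simulate_condition()], together with the analytic expectation and, for
#' channel 3, the SNR efficiency (empirical / expected).
#'
#' Two estimators are provided. The default, `method = "projection"`, projects
#' each epoch onto the declared harmonic structure of the channel (fundamental
#' and odd harmonics for the triangular/rectangular carriers, the single
#' cosine line for channel 3, plus the carrier intermodulation lines
#' `|k F1 +/- l F2|` when `W > 0`, all folded at the Nyquist frequency by
#' aliasing). Signal power is the explained power corrected for the
#' least-squares degrees of freedom, and noise power is the residual variance;
#' this estimator is free of the spectral leakage of finite rectangular
#' windows. `method = "periodogram"` instead sums the periodogram excess over
#' a median-based noise floor inside a guard window around each declared line;
#' it is simpler but systematically loses the line power leaked beyond the
#' guard window when carriers fall between Fourier bins.
#'
#' @param series An [epoched_series()].
#' @param cond The [condition_spec()] the series was generated under (or a
#'   compatible one declaring the harmonic structure).
#' @param method `"projection"` (default) or `"periodogram"`.
#' @param guard Half-width, in bins, of the signal window around each line
#'   (periodogram method only).
#' @return An object of class `snr_report`: a data frame with one row per
#'   channel (`empirical`, `expected`) and an `efficiency` attribute for
#'   channel 3.
#' @export
empirical_snr <- function(series, cond, method = c("projection", "periodogram"),
                          guard = 3L) {
  method <- match.arg(method)
  if (!inherits(series, "epoched_series")) {
    stop("'series' must be an epoched_series")
  }
  if (!inherits(cond, "condition_spec")) stop("'cond' must be a condition_spec")
  nch <- dim(series$data)[3]
  emp <- numeric(nch)
  for (ch in seq_len(nch)) {
    lines <- declared_lines(ch, cond)
    emp[ch] <- if (method == "projection") {
      snr_projection(series$data[, , ch, drop = TRUE], series$fs, lines)
    } else {
      snr_periodogram(series$data[, , ch, drop = TRUE], series$fs, lines, guard)
    }
  }
  exp_snr <- vapply(seq_len(nch), function(ch) expected_snr(ch, cond$W),
                    numeric(1))
  out <- data.frame(channel = series$channels[seq_len(nch)],
                    empirical = emp, expected = exp_snr)
  eff <- if (nch >= 3) emp[3] / exp_snr[3] else NA_real_
  structure(out, efficiency = eff, class = c("snr_report", "data.frame"))
}

#' @export
print.snr_report <- function(x, ...) {
  cat("Empirical vs expected signal-to-noise ratio\n")
  print.data.frame(cbind(x, efficiency = x$empirical / x$expected),
                   row.names = FALSE, digits = 4)
  invisible(x)
}

# Least-squares projection SNR: epochs (samples x epochs matrix) are projected
# on the sin/cos pair of every declared line; explained power is corrected for
# the p fitted degrees of freedom (E[ESS] = n * signal + p * sigma^2).
snr_projection <- function(epochs, fs, lines) {
  if (is.null(dim(epochs))) epochs <- matrix(epochs, ncol = 1L)
  ns <- nrow(epochs)
  # keep the strongest lines if the basis would exhaust the epoch length
  max_lines <- floor(0.8 * ns / 2)
  if (length(lines) > max_lines) lines <- lines[seq_len(max_lines)]
  t <- (seq_len(ns) - 1L) / fs
  basis <- matrix(0, nrow = ns, ncol = 2L * length(lines))
  for (i in seq_along(lines)) {
    basis[, 2L * i - 1L] <- cos(2 * pi * lines[i] * t)
    basis[, 2L * i] <- sin(2 * pi * lines[i] * t)
  }
  keep <- colSums(basis^2) > 1e-12
  basis <- basis[, keep, drop = FALSE]
  p <- ncol(basis)
  qrb <- qr(basis)
  p <- qrb$rank
  fitted <- qr.fitted(qrb, epochs)
  rss <- colSums((epochs - fitted)^2)
  ess <- colSums(fitted^2)
  sigma2 <- rss / (ns - p)
  psig <- (ess - p * sigma2) / ns
  pnoise <- mean(sigma2)
  if (pnoise <= 0) stop("zero noise floor: cannot form an SNR")
  mean(psig) / pnoise
}

# Periodogram-excess SNR: average per-epoch periodogram, signal = excess over
# a median noise floor within +/- guard bins of each declared line, noise =
# floor times the number of bins. The floor median is rescaled by the exact
# mean/median ratio of the averaged-periodogram Gamma distribution.
snr_periodogram <- function(epochs, fs, lines, guard = 3L) {
  if (is.null(dim(epochs))) epochs <- matrix(epochs, ncol = 1L)
  ns <- nrow(epochs)
  ne <- ncol(epochs)
  pg <- abs(stats::mvfft(epochs))^2 / ns^2
  nb <- floor(ns / 2)
  # one-sided power per bin (bins 1 .. nb, excluding DC)
  one_sided <- 2 * pg[2:(nb + 1), , drop = FALSE]
  if (ns %% 2 == 0) one_sided[nb, ] <- one_sided[nb, ] / 2
  pbar <- rowMeans(one_sided)
  df <- fs / ns
  # declared lines come strongest-first; keep only as many as leave enough
  # clean bins to estimate the floor from
  floor_bins <- integer(0)
  sig_idx <- integer(0)
  for (k in unique(pmin(c(length(lines), 50L, 25L, 12L, 6L, 3L),
                        length(lines)))) {
    bins <- unique(pmin(pmax(round(lines[seq_len(k)] / df), 1L), nb))
    sig_idx <- unique(unlist(lapply(bins, function(b) {
      seq(max(1L, b - guard), min(nb, b + guard))
    })))
    excl_idx <- unique(unlist(lapply(bins, function(b) {
      seq(max(1L, b - guard - 7L), min(nb, b + guard + 7L))
    })))
    floor_bins <- setdiff(seq_len(nb), excl_idx)
    if (length(floor_bins) >= 30L) break
  }
  if (length(floor_bins) < 1L) stop("no noise-floor bins left on the grid")
  med <- stats::median(pbar[floor_bins])
  if (!is.finite(med) || med <= mean(pbar) * 1e-12) {
    stop("zero noise floor: cannot form an SNR")
  }
  # mean/median correction for the Gamma(ne) distribution of averaged bins
  floor_est <- med * ne / stats::qgamma(0.5, shape = ne)
  psig <- sum(pmax(pbar[sig_idx] - floor_est, 0))
  pnoise <- floor_est * nb
  psig / pnoise
}
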