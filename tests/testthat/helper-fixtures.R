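# Shared fixture builders and independent oracles. Everything is generated in
# code at test time; no stored data.

# White-noise epoched series (channels independent standard Gaussians).
white_series <- function(ns = 500, ne = 8, nch = 3, fs = 100, seed = 1) {
  set.seed(seed)
  epoched_series(array(rnorm(ns * ne * nch), c(ns, ne, nch)), fs = fs)
}

# Deterministically QPC-locked cosines: per epoch, X1 and X2 carry random
# phases and X3 carries the sum phase at the sum frequency; noiseless.
qpc_locked_series <- function(f1 = 8, f2 = 12, ne = 16, fs = 128, ns = 128,
                              seed = 1, noise_sd = 0) {
  set.seed(seed)
  t <- (seq_len(ns) - 1) / fs
  dat <- array(0, c(ns, ne, 3))
  for (e in seq_len(ne)) {
    p1 <- runif(1, 0, 2 * pi)
    p2 <- runif(1, 0, 2 * pi)
    dat[, e, 1] <- cos(2 * pi * f1 * t + p1) + rnorm(ns, sd = noise_sd)
    dat[, e, 2] <- cos(2 * pi * f2 * t + p2) + rnorm(ns, sd = noise_sd)
    dat[, e, 3] <- cos(2 * pi * (f1 + f2) * t + p1 + p2) +
      rnorm(ns, sd = noise_sd)
  }
  epoched_series(dat, fs = fs)
}

# Naive triple-loop cross-bicoherence (and cross-bispectrum mean), the
# independent oracle for the vectorised estimator.
naive_bicoherence <- function(spectra, i, j, k) {
  n <- spectra$dft_length
  m <- round(spectra$f_nyquist / spectra$delta_f)
  L <- spectra$L
  b2 <- matrix(0, m, m)
  bmean <- matrix(complex(real = 0), m, m)
  for (m1 in seq_len(m)) {
    for (m2 in seq_len(m)) {
      msum <- m1 + m2
      idx <- if (msum == n) 1L else msum + 1L
      num <- 0 + 0i
      d1 <- 0
      d2 <- 0
      for (s in seq_len(L)) {
        xi <- spectra$spectra[m1 + 1L, s, i]
        xj <- spectra$spectra[m2 + 1L, s, j]
        xk <- spectra$spectra[idx, s, k]
        b <- xi * xj * Conj(xk)
        num <- num + b
        d1 <- d1 + Mod(xi * xj)^2
        d2 <- d2 + Mod(xk)^2
      }
      bmean[m1, m2] <- num / L
      den <- d1 * d2
      b2[m1, m2] <- if (den > 0) Mod(num)^2 / den else 0
    }
  }
  list(b2 = b2, B = bmean)
}

# Textbook Benjamini-Hochberg adjusted p-values, written independently of
# stats::p.adjust for the fallback-equality check.
textbook_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Stable bivariate VAR(2) with causality only from the source (column 2) to
# the target (column 1).
simulate_var2 <- function(n, c1 = 0.5, c2 = 0, seed = 1) {
  set.seed(seed)
  x <- numeric(n)
  y <- numeric(n)
  ex <- rnorm(n)
  ey <- rnorm(n)
  for (t in 3:n) {
    y[t] <- 0.55 * y[t - 1] - 0.2 * y[t - 2] + ey[t]
    x[t] <- 0.5 * x[t - 1] - 0.3 * x[t - 2] + c1 * y[t - 1] +
      c2 * y[t - 2] + ex[t]
  }
  cbind(x, y)
}

# Significance map built directly from planted significant values, for the
# ratio operations (grid of the study settings unless stated).
planted_significance_map <- function(b2bar, delta_f = 0.25, f_nyquist = 50) {
  grid <- bifrequency_grid(delta_f, f_nyquist)
  stopifnot(all(dim(b2bar) == c(length(grid$f1), length(grid$f2))))
  sig <- b2bar > 0
  structure(list(b2bar = b2bar, significant = sig,
                 q = ifelse(sig, 0.01, 0.5),
                 q_threshold = 0.05, fit = NULL,
                 f1 = grid$f1, f2 = grid$f2, sector = grid$sector,
                 principal = grid$principal, L = NA_integer_,
                 channels = c(1, 2, 3), delta_f = delta_f,
                 f_nyquist = f_nyquist),
            class = "significance_map")
}

# GC spectrum carrying planted significant values on the 0.2 Hz Fourier grid
# of 500-sample segments at 100 Hz.
planted_gc_spectrum <- function(bgcs_bar, fs = 100, segment_length = 500) {
  freq <- (fs / segment_length) * seq_len(segment_length / 2 - 1)
  stopifnot(length(bgcs_bar) == length(freq))
  structure(list(freq = freq, bgcs = bgcs_bar, bgcs_bar = bgcs_bar,
                 significant = bgcs_bar > 0,
                 theta = if (any(bgcs_bar > 0)) min(bgcs_bar[bgcs_bar > 0])
                         else NA_real_,
                 lag = 7L, L = NA_integer_, mode = "welch", fs = fs,
                 f_nyquist = fs / 2, delta_f_exp = fs / segment_length,
                 segment_length = segment_length),
            class = "gc_spectrum")
}

# The printed sums of the worked example, planted as inputs for the ratio
# operations: 3.604 inside G([8,9] x [10,11]) and 10.906 - 3.604 elsewhere in
# sector Q_I.
worked_example_sig_map <- function() {
  grid <- bifrequency_grid(0.25, 50)
  b2bar <- matrix(0, length(grid$f1), length(grid$f2))
  g_bins <- outer(grid$f1 >= 8 & grid$f1 <= 9,
                  grid$f2 >= 10 & grid$f2 <= 11, "&")
  b2bar[g_bins] <- 3.604 / sum(g_bins)
  out_bins <- outer(grid$f1 >= 20 & grid$f1 <= 24.75,
                    grid$f2 >= 5 & grid$f2 <= 6, "&")
  stopifnot(all(grid$sector[out_bins] == "Q_I"))
  b2bar[out_bins] <- (10.906 - 3.604) / sum(out_bins)
  planted_significance_map(b2bar)
}

# The printed sums of the worked example for the GC arm: 0.128 inside the
# interval of interest [18, 20] Hz and 0.552 - 0.128 elsewhere in (0, 50).
worked_example_gc_spectrum <- function() {
  freq <- 0.2 * seq_len(249)
  bar <- numeric(249)
  inside <- freq >= 18 & freq <= 20
  bar[inside] <- 0.128 / sum(inside)
  outside <- freq >= 30 & freq <= 35
  bar[outside] <- (0.552 - 0.128) / sum(outside)
  planted_gc_spectrum(bar)
}
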