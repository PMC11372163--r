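#' Bootstrap count rule
#'
#' Number of bootstrap series determined by the experimental spectral
#' resolution: `nboots = round(sqrt(delta_f_exp) * 1000)`.
#'
#' @param delta_f_exp Experimental spectral resolution in Hz (> 0).
#' @return Integer bootstrap count.
#' @examples
#' nboots_rule(0.2) # 447
#' @export
nboots_rule <- function(delta_f_exp) {
  if (!is.numeric(delta_f_exp) || delta_f_exp <= 0) {
    stop("'delta_f_exp' must be positive")
  }
  as.integer(round(sqrt(delta_f_exp) * 1000))
}

# OLS fit of a bivariate VAR(l) without intercept (series are standardised).
# Returns coefficient array A[2, 2, l] with y_t = sum_m A[,,m] y_{t-m} + e_t,
# the ML residual covariance and the residuals.
var_ols <- function(xy, l) {
  stopifnot(is.matrix(xy), ncol(xy) == 2L, l >= 1)
  z <- stats::embed(xy, l + 1L)
  y <- z[, 1:2, drop = FALSE]
  x <- z[, -(1:2), drop = FALSE]
  g <- crossprod(x)
  ch <- tryCatch(chol(g), error = function(e) NULL)
  if (is.null(ch)) return(NULL) # singular design
  b <- backsolve(ch, forwardsolve(t(ch), crossprod(x, y))) # (2l) x 2
  res <- y - x %*% b
  sigma <- crossprod(res) / nrow(y)
  A <- array(t(b), dim = c(2L, 2L, l))
  list(A = A, sigma = sigma, residuals = res, n = nrow(y))
}

# Univariate AR(l) by OLS (reduced model of the target channel).
ar_ols <- function(v, l) {
  z <- stats::embed(matrix(v, ncol = 1L), l + 1L)
  y <- z[, 1L]
  x <- z[, -1L, drop = FALSE]
  b <- qr.coef(qr(x), y)
  res <- y - x %*% b
  list(coef = as.vector(b), sigma2 = mean(res^2), residuals = as.vector(res))
}

#' VAR lag order by the Schwarz criterion with an anti-overfitting margin
#'
#' Fits bivariate VAR models of order 1..`lag_max` by least squares on a
#' common sample and computes the Schwarz criterion
#' `SC(l) = log det(Sigma_l) + log(N)/N * 4 l`. Very long records tend to
#' push the SC minimum to large orders with negligible fit gain, so instead
#' of the arg-min the smallest order whose SC is within 5% of the minimum (on
#' the `|SC_min|` scale, i.e. `SC(l) <= SC_min + 0.05 |SC_min|`) is selected;
#' by construction it never exceeds the arg-min.
#'
#' @param xy Two-column matrix (target, source) or an object coercible to it.
#' @param lag_max Maximum order to scan (default 50). If the series is
#'   shorter than `2 * lag_max` samples, `lag_max` is reduced with a warning.
#' @param margin Relative SC margin (default 0.05).
#' @return Integer lag order, with the SC table in attribute `"sc"`.
#' @export
select_lag <- function(xy, lag_max = 50L, margin = 0.05) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2L)
  n <- nrow(xy)
  if (n < 2L * lag_max) {
    lag_max <- max(1L, floor(n / 2) - 2L)
    warning("series shorter than 2 * lag_max; reducing lag_max to ", lag_max)
  }
  z <- stats::embed(xy, lag_max + 1L)
  y <- z[, 1:2, drop = FALSE]
  x <- z[, -(1:2), drop = FALSE]
  neff <- nrow(y)
  g <- crossprod(x)
  gy <- crossprod(x, y)
  yy <- crossprod(y)
  sc <- rep(NA_real_, lag_max)
  for (l in seq_len(lag_max)) {
    idx <- seq_len(2L * l)
    b <- tryCatch(solve(g[idx, idx, drop = FALSE], gy[idx, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(b)) next
    sigma <- (yy - crossprod(gy[idx, , drop = FALSE], b)) / neff
    dt <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2]^2
    if (dt <= 0) next
    sc[l] <- log(dt) + log(neff) / neff * 4 * l
  }
  if (all(is.na(sc))) stop("VAR fitting failed at every order")
  sc_min <- min(sc, na.rm = TRUE)
  ok <- which(!is.na(sc) & sc <= sc_min + margin * abs(sc_min))
  structure(min(ok), sc = sc)
}

# Geweke spectral causality source -> target for a bivariate VAR, evaluated
# at frequencies `freqs` (Hz). Channel 1 is the target, channel 2 the source.
# `zmat` caches exp(-2i pi f m / fs) across repeated calls on one grid.
geweke_spectrum <- function(A, sigma, freqs, fs, zmat = NULL) {
  l <- dim(A)[3]
  if (is.null(zmat) || ncol(zmat) != l) {
    zmat <- exp(-2i * pi * outer(freqs / fs, seq_len(l))) # nfreq x l
  }
  a11 <- 1 - as.vector(zmat %*% A[1, 1, ])
  a12 <- -as.vector(zmat %*% A[1, 2, ])
  a21 <- -as.vector(zmat %*% A[2, 1, ])
  a22 <- 1 - as.vector(zmat %*% A[2, 2, ])
  det <- a11 * a22 - a12 * a21
  h11 <- a22 / det
  h12 <- -a12 / det
  s11 <- sigma[1, 1]
  s12 <- sigma[1, 2]
  s22 <- sigma[2, 2]
  gamma2 <- s22 - s12^2 / s11
  h11t <- h11 + (s12 / s11) * h12
  sxx <- Re(h11t * Conj(h11t)) * s11 + Re(h12 * Conj(h12)) * gamma2
  own <- Re(h11t * Conj(h11t)) * s11
  pmax(log(sxx / own), 0)
}

# Time-domain Granger causality source -> target at lag l (log variance
# ratio of the reduced and full models).
gc_time_domain <- function(xy, l) {
  xy <- as.matrix(xy)
  full <- var_ols(xy, l)
  if (is.null(full)) stop("singular VAR fit")
  red <- ar_ols(xy[, 1L], l)
  log(red$sigma2 / full$sigma[1, 1])
}

#' Bivariate Granger-causality spectrum of the channel product process
#'
#' Forms the product process `U(t) = Xi(t) * Xj(t)` and measures the spectral
#' Granger causality from `U` to `Xk` with Geweke's decomposition of a
#' bivariate VAR. With `mode = "welch"` (the default) the record is cut into
#' overlapping Welch segments, each segment pair is standardised, a VAR at
#' the selected lag is fitted per segment and the point-wise median spectrum
#' across segments is returned; `mode = "single"` fits one VAR on the whole
#' standardised record (much faster, and the estimator used by the reduced
#' study profile). The lag order is selected once on the whole record via
#' [select_lag()].
#'
#' @param series An [epoched_series()] with at least three channels.
#' @param i,j Interacting source channels (product process).
#' @param k Target channel.
#' @param plan A [segment_plan()]; only `segment_length`, `overlap` are used
#'   (the frequency grid is the Fourier grid of the segment length). Defaults
#'   to 500-sample segments with 50% overlap.
#' @param lag VAR lag order; `NULL` selects it by [select_lag()].
#' @param lag_max Maximum order scanned by the lag selection.
#' @param mode `"welch"` or `"single"`.
#' @return An object of class `gc_spectrum`: `freq` (Hz, the open interval
#'   `(0, f_nyquist)`), `bgcs` (median spectrum), `lag`, `L` (segments used),
#'   `skipped` (singular segments), plus the data needed for
#'   [bootstrap_significance()].
#' @examples
#' sim <- simulate_condition(condition_spec(8.5, 10.5, 9.5, W = 0.75,
#'                                          n_epochs = 4, seed = 2))
#' g <- bgcs(sim, mode = "single", lag_max = 10)
#' g
#' @export
bgcs <- function(series, i = 1L, j = 2L, k = 3L, plan = NULL, lag = NULL,
                 lag_max = 50L, mode = c("welch", "single")) {
  mode <- match.arg(mode)
  if (!inherits(series, "epoched_series")) {
    stop("'series' must be an epoched_series")
  }
  d <- dim(series$data)
  if (d[3] < max(i, j, k)) stop("three channels are required")
  fs <- series$fs
  u <- channel_vector(series, i) * channel_vector(series, j)
  v <- channel_vector(series, k)
  if (is.null(plan)) {
    plan <- segment_plan(fs, segment_length = min(length(u), 500L))
  }
  ns <- plan$segment_length
  freqs <- (fs / ns) * seq_len(ceiling(ns / 2) - 1L)

  whole <- cbind(scale(v)[, 1L], scale(u)[, 1L]) # target first
  if (is.null(lag)) lag <- as.integer(select_lag(whole, lag_max = lag_max))

  starts <- seq(1L, length(u) - ns + 1L, by = plan$step)
  spec <- gc_median_spectrum(u, v, starts, ns, lag, freqs, fs, mode)

  structure(list(freq = freqs, bgcs = spec$bgcs, lag = lag,
                 L = spec$L, skipped = spec$skipped, mode = mode,
                 fs = fs, f_nyquist = fs / 2,
                 delta_f_exp = fs / ns, segment_length = ns,
                 channels = c(i, j, k),
                 u = u, v = v, starts = starts),
            class = "gc_spectrum")
}

# Median (across segments) Geweke spectrum from u to v, or the single-fit
# spectrum on the whole record.
gc_median_spectrum <- function(u, v, starts, ns, lag, freqs, fs, mode,
                               zmat = NULL) {
  if (is.null(zmat)) zmat <- exp(-2i * pi * outer(freqs / fs, seq_len(lag)))
  if (mode == "single") {
    xy <- cbind(scale(v)[, 1L], scale(u)[, 1L])
    fit <- var_ols(xy, lag)
    if (is.null(fit)) stop("singular VAR fit on the whole record")
    return(list(bgcs = geweke_spectrum(fit$A, fit$sigma, freqs, fs, zmat),
                L = 1L, skipped = 0L))
  }
  L <- length(starts)
  mat <- matrix(NA_real_, nrow = length(freqs), ncol = L)
  skipped <- 0L
  for (s in seq_len(L)) {
    sel <- starts[s]:(starts[s] + ns - 1L)
    xy <- cbind(scale(v[sel])[, 1L], scale(u[sel])[, 1L])
    fit <- var_ols(xy, lag)
    if (is.null(fit) || !all(is.finite(fit$sigma)) ||
        fit$sigma[1, 1] <= 0) {
      skipped <- skipped + 1L
      next
    }
    mat[, s] <- geweke_spectrum(fit$A, fit$sigma, freqs, fs, zmat)
  }
  used <- colSums(is.na(mat)) == 0L
  if (skipped > L / 2) stop("more than half of the segments had singular VAR fits")
  list(bgcs = apply(mat[, used, drop = FALSE], 1L, stats::median),
       L = sum(used), skipped = skipped)
}

#' @export
print.gc_spectrum <- function(x, ...) {
  cat(sprintf("<gc_spectrum> BGCS over %d frequencies in (0, %g) Hz, VAR(%d), %s mode, L = %d\n",
              length(x$freq), x$f_nyquist, x$lag, x$mode, x$L))
  if (!is.null(x$q)) {
    th <- if (is.na(x$theta)) "undefined" else sprintf("%.7g", x$theta)
    cat(sprintf("  bootstrap: nboots = %d, %d significant frequencies (q < %g), theta = %s\n",
                x$nboots, sum(x$significant), x$q_threshold, th))
  }
  invisible(x)
}

#' @export
plot.gc_spectrum <- function(x, main = "Median bivariate GC spectrum", ...) {
  graphics::plot(x$freq, pmax(x$bgcs, 1e-12), type = "l", log = "y",
                 xlab = "f (Hz)", ylab = "BGCS", main = main, ...)
  if (!is.null(x$theta) && !is.na(x$theta)) {
    graphics::abline(h = x$theta, lty = 2)
  }
  invisible(x)
}

#' Bootstrap significance of a Granger-causality spectrum
#'
#' Residual bootstrap under the no-causality null: the reduced autoregressive
#' model of the target channel (its own history only) is fitted on the whole
#' record, its residuals are resampled with replacement and the target is
#' resimulated `nboots` times; the BGCS estimator of `spec` is recomputed
#' against the observed product process for each resimulation. Per-frequency
#' p-values are `(1 + #\{boot >= observed\}) / (nboots + 1)`, converted to
#' q-values with [qvalues()] (Storey pFDR with Benjamini-Hochberg fallback).
#' The causal-dependency threshold `theta` is the smallest observed BGCS
#' value among the `q < q_threshold` frequencies (undefined, `NA`, when none
#' is). `theta` then determines the significant values of the spectrum: the
#' retained curve `bgcs_bar` carries `BGCS(f)` wherever `BGCS(f) >= theta`
#' — the region of the curve at or above the threshold line — and 0
#' elsewhere.
#'
#' @param spec A [bgcs()] result.
#' @param nboots Bootstrap count; defaults to the [nboots_rule()] of the
#'   spectrum's experimental resolution. Below 100 a reduced-precision
#'   warning is issued.
#' @param q_threshold FDR threshold, default 0.05.
#' @param boot_mode Estimator mode used inside the bootstrap; defaults to the
#'   mode of `spec`.
#' @param boot_segment_stride In `"welch"` mode, recompute each bootstrap
#'   median over every `boot_segment_stride`-th segment only (default 1 =
#'   all segments). Subsampling widens the bootstrap null spread, so
#'   p-values become somewhat conservative; it is a compute/precision
#'   trade-off for long records.
#' @return `spec` updated with `p`, `q`, `q_significant` (the `q <
#'   q_threshold` mask), `theta`, `significant` (the `BGCS >= theta` mask),
#'   `bgcs_bar` (significant values, 0 elsewhere) and `nboots`.
#' @export
bootstrap_significance <- function(spec, nboots = NULL, q_threshold = 0.05,
                                   boot_mode = NULL,
                                   boot_segment_stride = 1L) {
  if (!inherits(spec, "gc_spectrum")) stop("'spec' must be a gc_spectrum")
  if (is.null(nboots)) nboots <- nboots_rule(spec$delta_f_exp)
  if (nboots < 100) {
    warning("nboots < 100: reduced-precision bootstrap p-values")
  }
  if (is.null(boot_mode)) boot_mode <- spec$mode
  l <- spec$lag
  v <- scale(spec$v)[, 1L]
  red <- ar_ols(v, l)
  res <- red$residuals - mean(red$residuals)
  n <- length(spec$v)
  starts <- spec$starts[seq(1L, length(spec$starts),
                            by = max(1L, as.integer(boot_segment_stride)))]
  zmat <- exp(-2i * pi * outer(spec$freq / spec$fs, seq_len(l)))
  exceed <- integer(length(spec$freq))
  for (b in seq_len(nboots)) {
    e <- sample(res, n, replace = TRUE)
    vb <- as.vector(stats::filter(e, red$coef, method = "recursive"))
    bs <- gc_median_spectrum(spec$u, vb, starts, spec$segment_length,
                             l, spec$freq, spec$fs, boot_mode, zmat)
    exceed <- exceed + (bs$bgcs >= spec$bgcs)
  }
  p <- (1 + exceed) / (nboots + 1)
  q <- qvalues(p, pfdr = TRUE)
  qsig <- q < q_threshold
  theta <- if (any(qsig)) min(spec$bgcs[qsig]) else NA_real_
  sig <- if (is.na(theta)) rep(FALSE, length(spec$bgcs)) else spec$bgcs >= theta
  spec$p <- p
  spec$q <- q
  spec$q_significant <- qsig
  spec$significant <- sig
  spec$bgcs_bar <- ifelse(sig, spec$bgcs, 0)
  spec$theta <- theta
  spec$nboots <- as.integer(nboots)
  spec$q_threshold <- q_threshold
  spec
}

#' Spectral interval of interest of a bifrequency interaction
#'
#' The sum frequency `f1 + f2` of an interacting bifrequency, folded by
#' aliasing (`fs - (f1 + f2)`) when the sum exceeds the Nyquist frequency,
#' extended by `2 d` on each side and clipped to `(0, f_nyquist)`.
#'
#' @param f1,f2 Interacting frequencies in Hz.
#' @param d Neighborhood half-width in Hz, >= 0.
#' @param f_nyquist Nyquist frequency in Hz.
#' @param fs Sampling rate in Hz (default `2 * f_nyquist`).
#' @return Numeric `c(lower, upper)` in Hz, with the folded centre in
#'   attribute `"center"`.
#' @examples
#' interval_of_interest(8.5, 10.5, 0.5, 50) # [18, 20]
#' @export
interval_of_interest <- function(f1, f2, d, f_nyquist, fs = 2 * f_nyquist) {
  if (d < 0) stop("'d' must be non-negative")
  s <- f1 + f2
  center <- if (s <= f_nyquist) s else fs - s
  lo <- max(center - 2 * d, 0)
  hi <- min(center + 2 * d, f_nyquist)
  if (hi <= 0 || lo >= f_nyquist || lo > hi) {
    stop("empty spectral interval after clipping to (0, f_nyquist)")
  }
  structure(c(lo, hi), center = center)
}

#' Ratio of bivariate Granger causality quadratic phase coupling (R_GQPC)
#'
#' Fraction of the significant Granger-causal spectral mass that falls in the
#' spectral interval of interest:
#' \deqn{R_{GQPC} = \sum_{f \in I} \overline{BGCS}(f) \Big/
#'   \sum_{f \in (0, f_{Nyq})} \overline{BGCS}(f).}
#' Undefined (flagged, not 0) when nothing is significant; ratios exactly 0
#' or 1 are flagged as boundary outliers.
#'
#' @param spec A [bgcs()] spectrum with [bootstrap_significance()] applied.
#' @param interval Numeric `c(lower, upper)` in Hz, e.g. from
#'   [interval_of_interest()].
#' @return An object of class `gqpc_result` with fields `R`, `numerator`,
#'   `denominator`, `interval`, `flag`.
#' @export
r_gqpc <- function(spec, interval) {
  if (!inherits(spec, "gc_spectrum")) stop("'spec' must be a gc_spectrum")
  if (is.null(spec$bgcs_bar)) {
    stop("significance not computed: run bootstrap_significance() first")
  }
  if (length(interval) != 2L || interval[1] > interval[2]) {
    stop("'interval' must be c(lower, upper)")
  }
  if (interval[2] < min(spec$freq) || interval[1] > max(spec$freq)) {
    stop("interval outside the frequency grid")
  }
  inside <- spec$freq >= interval[1] & spec$freq <= interval[2]
  num <- sum(spec$bgcs_bar[inside])
  den <- sum(spec$bgcs_bar)
  if (den <= 0) {
    R <- NA_real_
    flag <- "undefined"
  } else {
    R <- num / den
    flag <- if (R == 0) "zero" else if (R == 1) "one" else "ok"
  }
  structure(list(R = R, numerator = num, denominator = den,
                 interval = as.numeric(interval), flag = flag),
            class = "gqpc_result")
}

#' @export
print.gqpc_result <- function(x, ...) {
  if (is.na(x$R)) {
    cat(sprintf("R_GQPC undefined: no significant causal mass (interval [%.3g, %.3g] Hz)\n",
                x$interval[1], x$interval[2]))
  } else {
    cat(sprintf("R_GQPC = %.4g / %.4g = %.3f  [interval [%.3g, %.3g] Hz%s]\n",
                x$numerator, x$denominator, x$R, x$interval[1], x$interval[2],
                if (x$flag != "ok") paste0(", flag: ", x$flag) else ""))
  }
  invisible(x)
}
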