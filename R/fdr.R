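#' Empirical-Bayes null mixture fit for cross-bicoherence values
#'
#' Fits the two-class mixture `F(x) = p0 F0(x) + (1 - p0) FA(x)` to raw
#' cross-bicoherence values, where the null component `F0` is the
#' chi-squared(2) family on the `2 L b^2` scale with a free scale parameter.
#' Under the null hypothesis of zero true bicoherence, `2 L b^2` is
#' approximately chi-squared with 2 degrees of freedom, i.e. the raw values
#' are approximately exponential with rate `L`. The fit is by mode matching:
#' the values are histogrammed at bin width `delta`, the histogram mode is
#' located after 3-bin moving-average smoothing (ties resolved towards the
#' smaller statistic), and the null rate and null fraction are obtained by a
#' count-weighted log-linear fit of the histogram over the null bulk to the
#' right of the mode. The null fraction is constrained to `[0, 0.9]`.
#' Right-tail false discovery rate q-values are returned for every value.
#'
#' @param values Numeric sample of raw cross-bicoherence values (>= 500
#'   values; typically all principal-domain bins of a map).
#' @param L Segment count the values were estimated from.
#' @param delta Histogram bin width on the raw scale (default 0.001).
#' @param p0_max Upper box constraint on the null fraction (default 0.9).
#' @return An object of class `mixture_fit` with fields `p0`, `rate` (fitted
#'   exponential rate of the null on the raw scale; `L` corresponds to the
#'   theoretical chi-squared(2) null), `q` (q-value per input value), `delta`,
#'   and `fallback` (TRUE when the theoretical null was used).
#' @examples
#' set.seed(1)
#' fit <- fit_null_mixture(rexp(5000, rate = 100), L = 100)
#' fit$p0
#' @export
fit_null_mixture <- function(values, L, delta = 0.001, p0_max = 0.9) {
  if (length(values) < 500L) {
    stop("at least 500 values are required to fit the null mixture")
  }
  if (anyNA(values) || any(values < 0)) {
    stop("'values' must be non-negative and free of NA")
  }
  if (stats::var(values) < .Machine$double.eps) {
    stop("degenerate sample: all values are (numerically) identical")
  }
  stopifnot(L >= 1)

  n <- length(values)
  breaks <- seq(0, max(values) + delta, by = delta)
  counts <- graphics::hist(values, breaks = breaks, plot = FALSE)$counts
  nb <- length(counts)
  sm <- stats::filter(counts, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- counts[is.na(sm)]
  mode_bin <- which.max(sm) # which.max takes the first (smaller) tie
  centers <- breaks[-1] - delta / 2

  fallback <- FALSE
  rate <- NA_real_
  p0 <- NA_real_
  if (mode_bin == nb) {
    warning("histogram mode at the right edge; falling back to the theoretical chi-squared(2) null")
    fallback <- TRUE
  } else {
    # null bulk: from the mode to the first bin whose smoothed count falls
    # below exp(-3) of the mode (about 95% of an exponential null mass)
    lim <- sm[mode_bin] * exp(-3)
    right <- mode_bin + which(sm[(mode_bin + 1L):nb] <= lim)[1L]
    if (is.na(right)) right <- nb
    right <- max(right, mode_bin + 4L)
    reg <- mode_bin:min(right, nb)
    reg <- reg[counts[reg] > 0]
    if (length(reg) >= 4L) {
      fit <- stats::lm.wfit(cbind(1, centers[reg]),
                            log(counts[reg]), w = counts[reg])
      slope <- fit$coefficients[2L]
      if (is.finite(slope) && slope < 0) {
        rate <- -slope
        p0 <- exp(fit$coefficients[1L]) / (n * delta * rate)
      }
    }
    if (!is.finite(rate)) {
      warning("mode-matching fit failed; falling back to the theoretical chi-squared(2) null")
      fallback <- TRUE
    }
  }
  if (fallback) {
    rate <- L
    p0 <- p0_max
  }
  p0 <- min(max(p0, 0), p0_max)

  q <- tail_fdr_q(values, p0, rate)
  structure(list(p0 = p0, rate = rate, L = L, delta = delta,
                 fallback = fallback, q = q, n = n),
            class = "mixture_fit")
}

# Right-tail empirical-Bayes FDR: Fdr(t) = p0 * S0(t) / S_hat(t) with
# exponential null survival S0 and empirical survival S_hat, made monotone
# non-increasing in the statistic by taking the running minimum over
# thresholds below each value.
tail_fdr_q <- function(values, p0, rate) {
  n <- length(values)
  o <- order(values)
  x <- values[o]
  surv <- (n - seq_len(n) + 1L) / n # P(X >= x_(i)) including ties at x_(i)
  # ties: every tied value shares the survival of the first of the run
  first_of_run <- c(TRUE, diff(x) > 0)
  surv <- surv[cummax(seq_len(n) * first_of_run)]
  fdr <- pmin(p0 * exp(-rate * x) / surv, 1)
  q <- cummin(fdr)
  out <- numeric(n)
  out[o] <- q
  out
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> p0 = %.3f, null rate = %.3g (theoretical %g)%s\n",
              x$p0, x$rate, x$L,
              if (x$fallback) " [theoretical-null fallback]" else ""))
  cat(sprintf("  %d values, %d significant at q < 0.05\n", x$n,
              sum(x$q < 0.05)))
  invisible(x)
}

#' Significance map of a cross-bicoherence estimate
#'
#' Thresholds a [cross_bicoherence()] map at `q < q_threshold` using a
#' [fit_null_mixture()] fitted to the map's principal-domain values. The
#' returned map carries the raw `b2` at significant bins and 0 elsewhere.
#'
#' @param map A [cross_bicoherence()] result.
#' @param fit A [fit_null_mixture()] produced from `map` (fitted on the
#'   principal-domain values in column-major order); if `NULL` it is fitted
#'   here.
#' @param q_threshold FDR threshold, default 0.05.
#' @return An object of class `significance_map` with fields `b2bar`
#'   (significant values, 0 elsewhere), `significant` (logical mask), `q`
#'   (q-value matrix), plus the grid metadata of `map`.
#' @export
significance_map <- function(map, fit = NULL, q_threshold = 0.05) {
  if (!inherits(map, "bicoherence_map")) {
    stop("'map' must be a bicoherence_map")
  }
  keep <- map$principal & !map$zero_denominator
  if (is.null(fit)) fit <- fit_null_mixture(map$b2[keep], L = map$L)
  if (!inherits(fit, "mixture_fit")) stop("'fit' must be a mixture_fit")
  if (length(fit$q) != sum(keep)) {
    stop("grid mismatch: 'fit' was not fitted on this map's principal-domain values")
  }
  qmat <- matrix(NA_real_, nrow = nrow(map$b2), ncol = ncol(map$b2))
  qmat[keep] <- fit$q
  sig <- !is.na(qmat) & qmat < q_threshold
  b2bar <- ifelse(sig, map$b2, 0)
  structure(list(b2bar = b2bar, significant = sig, q = qmat,
                 q_threshold = q_threshold, fit = fit,
                 f1 = map$f1, f2 = map$f2, sector = map$sector,
                 principal = map$principal, L = map$L,
                 channels = map$channels, delta_f = map$delta_f,
                 f_nyquist = map$f_nyquist),
            class = "significance_map")
}

#' @export
print.significance_map <- function(x, ...) {
  cat(sprintf("<significance_map> %d of %d bins significant at q < %g\n",
              sum(x$significant), sum(x$principal), x$q_threshold))
  invisible(x)
}

#' @export
plot.significance_map <- function(x, main = "Cross-bicoherence significance map",
                                  ...) {
  graphics::image(x$f1, x$f2, x$significant * 1, xlab = "f1 (Hz)",
                  ylab = "f2 (Hz)", main = main, useRaster = TRUE,
                  col = c("white", "black"), ...)
  graphics::abline(a = x$f_nyquist, b = -1, lty = 2)
  invisible(x)
}

#' Storey-type q-values with Benjamini-Hochberg fallback
#'
#' Computes positive false discovery rate (pFDR) q-values from a sample of
#' p-values. The null proportion is estimated as
#' `pi0 = min(1, mean(p > lambda) / (1 - lambda))` with `lambda = 0.5`; with
#' `pfdr = TRUE` the denominator conditions on at least one discovery via
#' `1 - (1 - p)^n`. When the p-value sample is (numerically) constant — as
#' happens for discrete bootstrap p-values with too few resamples — the
#' procedure falls back to Benjamini-Hochberg (`pi0 = 1`).
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param pfdr Use the pFDR denominator (default TRUE).
#' @param lambda Tuning constant of the pi0 estimate.
#' @param var_tol Variance below which the BH fallback triggers.
#' @return Numeric vector of q-values, same order as the input.
#' @examples
#' qvalues(c(0.001, 0.01, 0.04, 0.2, 0.9))
#' @export
qvalues <- function(pvalues, pfdr = TRUE, lambda = 0.5, var_tol = 1e-10) {
  if (length(pvalues) == 0L) stop("empty p-value input")
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  n <- length(pvalues)
  if (n == 1L || stats::var(pvalues) < var_tol) {
    return(stats::p.adjust(pvalues, method = "BH"))
  }
  pi0 <- min(1, mean(pvalues > lambda) / (1 - lambda))
  if (pi0 <= 0) pi0 <- 1 / n # all p small: keep a defined, conservative floor
  o <- order(pvalues)
  p <- pvalues[o]
  # ties share the largest rank of the run (the next position where p
  # strictly increases)
  last_of_run <- c(diff(p) > 0, TRUE)
  rank <- rev(cummin(rev(ifelse(last_of_run, seq_len(n), n))))
  denom <- if (pfdr) (rank / n) * (1 - (1 - p)^n) else rank / n
  denom[denom <= 0] <- .Machine$double.eps
  qraw <- pmin(pi0 * p / denom, 1)
  q <- rev(cummin(rev(qraw)))
  out <- numeric(n)
  out[o] <- q
  out
}
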