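#' Sector of a bifrequency in the principal domain
#'
#' Partitions the bifrequency square `(0, f_nyquist]^2` into three mutually
#' exclusive sectors: `Q_I` when `f1 + f2 <= f_nyquist` (the boundary belongs
#' to `Q_I`), `Q_II` when the sum exceeds the Nyquist frequency and
#' `f1 > f2`, and `Q_III` when the sum exceeds the Nyquist frequency and
#' `f1 <= f2`.
#'
#' @param f1,f2 Frequencies in Hz (vectorised).
#' @param f_nyquist Nyquist frequency in Hz.
#' @return Character vector with values `"Q_I"`, `"Q_II"`, `"Q_III"`.
#' @examples
#' classify_sector(8.5, 10.5, 50)   # Q_I
#' classify_sector(48.4, 36.6, 50)  # Q_II
#' @export
classify_sector <- function(f1, f2, f_nyquist) {
  if (any(f1 <= 0 | f1 > f_nyquist) || any(f2 <= 0 | f2 > f_nyquist)) {
    stop("frequencies must lie in (0, f_nyquist]")
  }
  ifelse(f1 + f2 <= f_nyquist, "Q_I",
         ifelse(f1 > f2, "Q_II", "Q_III"))
}

#' Bifrequency grid with sector labels
#'
#' Builds the grid of bin centres at integer multiples of `delta_f` in
#' `(0, f_nyquist]` on both axes, with the sector label of every bin and the
#' principal-domain mask (the single corner bin whose sum frequency aliases
#' onto DC is excluded).
#'
#' @param delta_f Grid resolution in Hz.
#' @param f_nyquist Nyquist frequency in Hz.
#' @return A list of class `bifrequency_grid` with fields `f1`, `f2`
#'   (axes), `sector` (matrix), `principal` (logical matrix).
#' @export
bifrequency_grid <- function(delta_f, f_nyquist) {
  m <- round(f_nyquist / delta_f)
  stopifnot(m >= 1)
  f <- delta_f * seq_len(m)
  sector <- outer(f, f, function(a, b) classify_sector(a, b, f_nyquist))
  principal <- outer(seq_len(m), seq_len(m), "+") < 2L * m
  structure(list(f1 = f, f2 = f, sector = sector, principal = principal,
                 delta_f = delta_f, f_nyquist = f_nyquist),
            class = "bifrequency_grid")
}

#' Cross-spectrum between two channels
#'
#' Segment-averaged cross-spectrum `< Xi(f) Xj*(f) >` on the frequency grid
#' `0, delta_f, ..., f_nyquist`. For `i == j` this is the (real,
#' non-negative) Welch power spectrum.
#'
#' @param spectra A [segment_series()] result.
#' @param i,j Channel indices.
#' @return A data-frame-like list with `freq` (Hz) and complex `C`.
#' @export
cross_spectrum <- function(spectra, i, j) {
  check_channels(spectra, c(i, j))
  m <- round(spectra$f_nyquist / spectra$delta_f)
  idx <- seq_len(m + 1L) # DC .. Nyquist
  xi <- spectra$spectra[idx, , i, drop = TRUE]
  xj <- spectra$spectra[idx, , j, drop = TRUE]
  if (is.null(dim(xi))) { xi <- matrix(xi, ncol = 1L); xj <- matrix(xj, ncol = 1L) }
  C <- rowMeans(xi * Conj(xj))
  if (i == j) C <- complex(real = pmax(Re(C), 0))
  list(freq = spectra$delta_f * (idx - 1L), C = C)
}

check_channels <- function(spectra, ch) {
  nch <- dim(spectra$spectra)[3]
  if (any(ch < 1 | ch > nch)) stop("channel index out of range")
  invisible(TRUE)
}

# Shared accumulator for the third-order statistics on the bifrequency grid.
# Returns sums over segments of B = Xi(f1) Xj(f2) Xk*(f1+f2), |Xi Xj|^2 and
# |Xk(f1+f2)|^2, using the full-length DFT so sums above the Nyquist
# frequency alias automatically (conjugate fold of real input).
bispectral_sums <- function(spectra, i, j, k) {
  check_channels(spectra, c(i, j, k))
  n <- spectra$dft_length
  m <- round(spectra$f_nyquist / spectra$delta_f)
  idx_sum <- outer(seq_len(m), seq_len(m), "+")
  idx_r <- idx_sum + 1L
  idx_r[idx_sum == n] <- 1L # sum frequency aliased onto DC
  L <- spectra$L
  sum_b <- matrix(complex(real = 0), m, m)
  sum_p2 <- matrix(0, m, m)
  sum_s2 <- matrix(0, m, m)
  f_bins <- 2L:(m + 1L)
  for (s in seq_len(L)) {
    xi <- spectra$spectra[f_bins, s, i]
    xj <- spectra$spectra[f_bins, s, j]
    xk <- spectra$spectra[, s, k]
    p <- outer(xi, xj)
    sk <- matrix(xk[idx_r], m, m)
    sum_b <- sum_b + p * Conj(sk)
    sum_p2 <- sum_p2 + Re(p * Conj(p))
    sum_s2 <- sum_s2 + Re(sk * Conj(sk))
  }
  list(sum_b = sum_b, sum_p2 = sum_p2, sum_s2 = sum_s2, m = m, L = L)
}

#' Cross-bispectrum estimate
#'
#' Segment-averaged cross-bispectrum
#' `< Xi(f1) Xj(f2) Xk*(f1 + f2) >` on the bifrequency grid. With
#' `i == j == k` it reduces to the single-channel bispectrum. Sum frequencies
#' above the Nyquist frequency are folded by aliasing of the real-input DFT.
#'
#' @param spectra A [segment_series()] result.
#' @param i,j,k Channel indices (defaults 1, 2, 3).
#' @return A list of class `cross_bispectrum` with the complex matrix `B`
#'   (`f1` rows, `f2` columns), the axes and the segment count `L`.
#' @export
cross_bispectrum <- function(spectra, i = 1L, j = 2L, k = 3L) {
  acc <- bispectral_sums(spectra, i, j, k)
  f <- spectra$delta_f * seq_len(acc$m)
  structure(list(B = acc$sum_b / acc$L, f1 = f, f2 = f, L = acc$L,
                 channels = c(i, j, k), delta_f = spectra$delta_f,
                 f_nyquist = spectra$f_nyquist),
            class = "cross_bispectrum")
}

#' Magnitude-squared cross-bicoherence
#'
#' Normalised cross-bispectrum on the bifrequency grid:
#' \deqn{\hat b^2_{ijk}(f_1,f_2) =
#'   \frac{|\langle \hat B_{ijk}(f_1,f_2)\rangle|^2}
#'        {\langle |\tilde X_i(f_1)\tilde X_j(f_2)|^2\rangle
#'         \langle |\tilde X_k(f_1+f_2)|^2\rangle}}
#' with sample averages over Welch segments in the numerator and both
#' denominator factors; the Cauchy-Schwarz inequality bounds the value in
#' \[0, 1\]. Bins with a zero denominator are set to 0 and flagged.
#'
#' @param spectra A [segment_series()] result with at least 2 segments.
#' @param i,j,k Channel indices: the coupling of `i` and `j` onto `k`.
#' @return An object of class `bicoherence_map`: matrix `b2` (`f1` rows,
#'   `f2` columns), axes, sector labels, principal-domain mask, zero-denominator
#'   flags and the segment count `L`.
#' @examples
#' sim <- simulate_condition(condition_spec(8.5, 10.5, 9.5, W = 0.5,
#'                                          n_epochs = 8, seed = 7))
#' bc <- cross_bicoherence(segment_series(sim))
#' range(bc$b2)
#' @export
cross_bicoherence <- function(spectra, i = 1L, j = 2L, k = 3L) {
  if (spectra$L < 2L) stop("at least 2 segments are required for bicoherence")
  acc <- bispectral_sums(spectra, i, j, k)
  den <- acc$sum_p2 * acc$sum_s2
  flag <- den <= 0
  b2 <- matrix(0, acc$m, acc$m)
  b2[!flag] <- Re(acc$sum_b[!flag] * Conj(acc$sum_b[!flag])) / den[!flag]
  b2 <- pmin(b2, 1)
  grid <- bifrequency_grid(spectra$delta_f, spectra$f_nyquist)
  structure(list(b2 = b2, f1 = grid$f1, f2 = grid$f2,
                 sector = grid$sector, principal = grid$principal,
                 zero_denominator = flag, L = acc$L,
                 channels = c(i, j, k), delta_f = spectra$delta_f,
                 f_nyquist = spectra$f_nyquist),
            class = "bicoherence_map")
}

#' @export
print.bicoherence_map <- function(x, ...) {
  cat(sprintf("<bicoherence_map> channels (%s) over %d x %d bifrequency bins, L = %d\n",
              paste(x$channels, collapse = ","), length(x$f1), length(x$f2),
              x$L))
  cat(sprintf("  delta_f = %g Hz, Nyquist = %g Hz, max b2 = %.4f\n",
              x$delta_f, x$f_nyquist, max(x$b2)))
  invisible(x)
}

#' @export
as.data.frame.bicoherence_map <- function(x, ...) {
  data.frame(f1 = rep(x$f1, times = length(x$f2)),
             f2 = rep(x$f2, each = length(x$f1)),
             sector = as.vector(x$sector),
             b2 = as.vector(x$b2))
}

#' @export
plot.bicoherence_map <- function(x, main = "Cross-bicoherence", ...) {
  graphics::image(x$f1, x$f2, x$b2, xlab = "f1 (Hz)", ylab = "f2 (Hz)",
                  main = main, useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  graphics::abline(a = x$f_nyquist, b = -1, lty = 2)
  invisible(x)
}
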