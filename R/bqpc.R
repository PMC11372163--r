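#' Bifrequency neighborhood of interest
#'
#' Selects the grid bins whose centres fall in the closed square
#' `[f1 - d, f1 + d] x [f2 - d, f2 + d]`, clipped to the sector of the centre
#' bifrequency so that the neighborhood is always a subset of the relevant
#' sector.
#'
#' @param f1,f2 Centre bifrequency in Hz (inside the principal domain).
#' @param d Half-width in Hz, >= 0. With `d = 0` the single nearest grid bin
#'   is selected.
#' @param grid A [bifrequency_grid()] (or any object carrying `f1`, `f2`,
#'   `sector`, `f_nyquist`, such as a [significance_map()]).
#' @return An object of class `neighborhood`: logical bin mask `bins`, the
#'   centre, `d` and the sector label.
#' @examples
#' g <- bifrequency_grid(0.25, 50)
#' nb <- neighborhood_bins(8.5, 10.5, 0.5, g)
#' sum(nb$bins) # 5 x 5 bins in [8,9] x [10,11]
#' @export
neighborhood_bins <- function(f1, f2, d, grid) {
  if (d < 0) stop("'d' must be non-negative")
  if (f1 <= 0 || f1 > grid$f_nyquist || f2 <= 0 || f2 > grid$f_nyquist) {
    stop("centre bifrequency outside the principal domain")
  }
  sector <- classify_sector(f1, f2, grid$f_nyquist)
  if (d == 0) {
    in1 <- seq_along(grid$f1) == which.min(abs(grid$f1 - f1))
    in2 <- seq_along(grid$f2) == which.min(abs(grid$f2 - f2))
  } else {
    in1 <- grid$f1 >= f1 - d & grid$f1 <= f1 + d
    in2 <- grid$f2 >= f2 - d & grid$f2 <= f2 + d
  }
  bins <- outer(in1, in2, "&") & grid$sector == sector
  structure(list(bins = bins, f1 = f1, f2 = f2, d = d, sector = sector),
            class = "neighborhood")
}

#' @export
print.neighborhood <- function(x, ...) {
  cat(sprintf("<neighborhood> centre (%.3f, %.3f) Hz, d = %g Hz, %d bins in sector %s\n",
              x$f1, x$f2, x$d, sum(x$bins), x$sector))
  invisible(x)
}

#' Ratio of bispectral quadratic phase coupling (R_BQPC)
#'
#' Numerical integration of the significant cross-bicoherence values inside
#' the neighborhood of interest divided by all significant cross-bicoherence
#' values in the relevant sector:
#' \deqn{R_{BQPC}(f_1, f_2; d) =
#'   \sum_{G(f_1,f_2;d)} \overline{b^2} \Big/
#'   \sum_{Q(f_1,f_2)} \overline{b^2}.}
#' Since the neighborhood is a subset of the sector, the ratio is bounded by
#' 1. When the sector carries no significant mass the ratio is undefined and
#' flagged rather than reported as 0; ratios exactly 0 or 1 are flagged as
#' boundary outliers so downstream aggregation can exclude them.
#'
#' @param sig A [significance_map()].
#' @param nbhd A [neighborhood_bins()] selection on the same grid, or `NULL`
#'   to build it from `f1`, `f2`, `d`.
#' @param f1,f2,d Centre bifrequency and half-width used when `nbhd` is NULL
#'   (default `d = 0.5` Hz).
#' @return An object of class `bqpc_result` with fields `R` (the ratio, `NA`
#'   when undefined), `numerator`, `denominator`, `sector`, `flag` (one of
#'   `"ok"`, `"undefined"`, `"zero"`, `"one"`).
#' @examples
#' g <- bifrequency_grid(0.25, 50)
#' @export
r_bqpc <- function(sig, nbhd = NULL, f1 = NULL, f2 = NULL, d = 0.5) {
  if (!inherits(sig, "significance_map")) {
    stop("'sig' must be a significance_map")
  }
  if (is.null(nbhd)) {
    if (is.null(f1) || is.null(f2)) stop("either 'nbhd' or (f1, f2) is required")
    nbhd <- neighborhood_bins(f1, f2, d, sig)
  }
  if (!inherits(nbhd, "neighborhood")) stop("'nbhd' must be a neighborhood")
  if (!all(dim(nbhd$bins) == dim(sig$b2bar))) {
    stop("grid mismatch between the significance map and the neighborhood")
  }
  sector_bins <- sig$sector == nbhd$sector
  num <- sum(sig$b2bar[nbhd$bins])
  den <- sum(sig$b2bar[sector_bins])
  if (den <= 0) {
    R <- NA_real_
    flag <- "undefined"
  } else {
    R <- num / den
    flag <- if (R == 0) "zero" else if (R == 1) "one" else "ok"
  }
  structure(list(R = R, numerator = num, denominator = den,
                 sector = nbhd$sector, f1 = nbhd$f1, f2 = nbhd$f2,
                 d = nbhd$d, flag = flag),
            class = "bqpc_result")
}

#' @export
print.bqpc_result <- function(x, ...) {
  if (is.na(x$R)) {
    cat(sprintf("R_BQPC(%.3f, %.3f; %g) undefined: no significant mass in sector %s\n",
                x$f1, x$f2, x$d, x$sector))
  } else {
    cat(sprintf("R_BQPC(%.3f, %.3f; %g) = %.4g / %.4g = %.3f  [sector %s%s]\n",
                x$f1, x$f2, x$d, x$numerator, x$denominator, x$R, x$sector,
                if (x$flag != "ok") paste0(", flag: ", x$flag) else ""))
  }
  invisible(x)
}
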