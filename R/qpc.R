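#' Full QPC analysis of a three-channel series
#'
#' The main front door: runs the cross-bicoherence arm (Welch segmentation,
#' cross-bicoherence of channels (i, j) onto k, empirical-Bayes FDR
#' significance, R_BQPC at the declared interacting bifrequency) and the
#' Granger arm (bivariate GC spectrum of the product process, bootstrap
#' significance, R_GQPC over the spectral interval of interest) on an epoched
#' series.
#'
#' @param series An [epoched_series()].
#' @param f1,f2 The interacting bifrequency of interest in Hz. Defaults to
#'   the condition the series was simulated under, when available.
#' @param d Neighborhood half-width in Hz (default 0.5).
#' @param q_threshold FDR threshold (default 0.05).
#' @param plan A [segment_plan()] (default: study plan).
#' @param arms Which arms to run, subset of `c("bicoherence", "granger")`.
#' @param gc_mode Estimator mode of the Granger arm, see [bgcs()].
#' @param nboots Bootstrap count for the Granger arm (default: the
#'   [nboots_rule()]).
#' @param lag_max Maximum VAR order scanned.
#' @param i,j,k Channel roles: coupling of `i` and `j` onto `k`.
#' @return An object of class `qpc` collecting the significance map, the
#'   `bqpc_result`, the `gc_spectrum` and the `gqpc_result`.
#' @examples
#' \donttest{
#' sim <- simulate_condition(condition_spec(8.5, 10.5, 9.5, W = 0.3,
#'                                          n_epochs = 16, seed = 1))
#' fit <- qpc(sim, gc_mode = "single", nboots = 100, lag_max = 10)
#' fit
#' }
#' @export
qpc <- function(series, f1 = NULL, f2 = NULL, d = 0.5, q_threshold = 0.05,
                plan = NULL, arms = c("bicoherence", "granger"),
                gc_mode = c("welch", "single"), nboots = NULL, lag_max = 50L,
                i = 1L, j = 2L, k = 3L) {
  gc_mode <- match.arg(gc_mode)
  arms <- match.arg(arms, several.ok = TRUE)
  if (!inherits(series, "epoched_series")) {
    stop("'series' must be an epoched_series")
  }
  cond <- series$condition
  if (is.null(f1)) f1 <- cond$F1
  if (is.null(f2)) f2 <- cond$F2
  if (is.null(f1) || is.null(f2)) {
    stop("the interacting bifrequency (f1, f2) is required")
  }
  if (is.null(plan)) {
    plan <- segment_plan(series$fs,
                         segment_length = min(dim(series$data)[1], 500L))
  }
  out <- list(f1 = f1, f2 = f2, d = d, q_threshold = q_threshold,
              condition = cond)
  if ("bicoherence" %in% arms) {
    sp <- segment_series(series, plan)
    bc <- cross_bicoherence(sp, i, j, k)
    sig <- significance_map(bc, q_threshold = q_threshold)
    out$significance <- sig
    out$bqpc <- r_bqpc(sig, f1 = f1, f2 = f2, d = d)
  }
  if ("granger" %in% arms) {
    g <- bgcs(series, i, j, k, plan = plan, lag_max = lag_max,
              mode = gc_mode)
    g <- bootstrap_significance(g, nboots = nboots,
                                q_threshold = q_threshold)
    out$gc <- g
    out$interval <- interval_of_interest(f1, f2, d, g$f_nyquist, g$fs)
    out$gqpc <- r_gqpc(g, out$interval)
  }
  structure(out, class = "qpc")
}

#' @export
print.qpc <- function(x, ...) {
  cat(sprintf("Quadratic phase coupling analysis at (f1, f2) = (%.3f, %.3f) Hz, d = %g Hz\n",
              x$f1, x$f2, x$d))
  if (!is.null(x$bqpc)) print(x$bqpc)
  if (!is.null(x$gqpc)) {
    th <- if (is.na(x$gc$theta)) "undefined" else sprintf("%.7g", x$gc$theta)
    cat(sprintf("  [GC arm: VAR(%d), nboots = %d, theta = %s]\n",
                x$gc$lag, x$gc$nboots, th))
    print(x$gqpc)
  }
  invisible(x)
}

#' @export
summary.qpc <- function(object, ...) {
  x <- object
  cat("Specific quadratic phase coupling summary\n")
  print(x)
  if (!is.null(x$significance)) {
    cat(sprintf("  bicoherence: %d significant bins of %d (L = %d segments), p0 = %.3f\n",
                sum(x$significance$significant),
                sum(x$significance$principal),
                x$significance$L, x$significance$fit$p0))
  }
  invisible(x)
}

#' @export
plot.qpc <- function(x, which = c("significance", "gc"), ...) {
  which <- match.arg(which)
  if (which == "significance" && !is.null(x$significance)) {
    plot(x$significance, ...)
  } else if (which == "gc" && !is.null(x$gc)) {
    plot(x$gc, ...)
  } else {
    stop("requested arm was not computed")
  }
  invisible(x)
}
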