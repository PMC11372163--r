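#' Enumerate the conditions of the simulation study
#'
#' Builds all experimental conditions from a frequency set: unordered pairs
#' `(F1, F2)` of distinct frequencies combined with every admissible carrier
#' `F3` from the same set, excluding `F3` in `{F1, F2, F1 + F2}`. The
#' realized condition count is attached as an attribute and reported by
#' `print()`; with the study frequency set the rule yields 58 conditions.
#'
#' @param freqs Numeric vector of at least 3 distinct frequencies (Hz);
#'   defaults to [study_frequencies()].
#' @return A data frame of class `condition_grid` with columns `F1`, `F2`,
#'   `F3` and `sector` (sector of `(F1, F2)` at a 50 Hz Nyquist frequency).
#' @examples
#' g <- build_condition_grid(c(1, 2, 3))
#' nrow(g) # 2
#' @export
build_condition_grid <- function(freqs = study_frequencies()) {
  freqs <- as.numeric(freqs)
  if (length(freqs) < 3L) stop("at least 3 frequencies are required")
  if (anyDuplicated(round(freqs * 1e9))) {
    stop("duplicate frequencies in input")
  }
  tol <- 1e-9
  rows <- list()
  nf <- length(freqs)
  for (a in seq_len(nf - 1L)) {
    for (b in (a + 1L):nf) {
      f1 <- freqs[a]; f2 <- freqs[b]
      excl <- c(f1, f2, f1 + f2)
      admissible <- freqs[vapply(freqs, function(f) all(abs(f - excl) > tol),
                                 logical(1))]
      for (f3 in admissible) {
        rows[[length(rows) + 1L]] <- c(f1, f2, f3)
      }
    }
  }
  if (length(rows) == 0L) stop("empty condition grid")
  m <- do.call(rbind, rows)
  out <- data.frame(F1 = m[, 1], F2 = m[, 2], F3 = m[, 3])
  out$sector <- classify_sector(pmin(out$F1, 50), pmin(out$F2, 50), 50)
  class(out) <- c("condition_grid", "data.frame")
  attr(out, "n_conditions") <- nrow(out)
  out
}

#' @export
print.condition_grid <- function(x, ...) {
  cat(sprintf("<condition_grid> %d conditions (F3 distinct from F1, F2, F1+F2)\n",
              nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE,
                   digits = 4)
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Run one study condition
#'
#' Simulates one condition and computes the requested analyses: the
#' bicoherence arm (significance map and R_BQPC at `(F1, F2)`), the Granger
#' arm (BGCS, bootstrap significance, R_GQPC over the interval of interest)
#' and the SNR report. Errors in an arm are caught and recorded; the row is
#' retained with `NA` values and an error flag.
#'
#' @param cond A [condition_spec()].
#' @param config Analysis configuration, see [default_config()].
#' @return A one-row data frame (see [run_study()] for the columns).
#' @export
run_condition <- function(cond, config = default_config()) {
  series <- simulate_condition(cond)
  arms <- config$arms
  row <- data.frame(F1 = cond$F1, F2 = cond$F2, F3 = cond$F3, W = cond$W,
                    seed = cond$seed,
                    sector = classify_sector(cond$F1, cond$F2, cond$fs / 2),
                    R_BQPC = NA_real_, bqpc_flag = NA_character_,
                    R_GQPC = NA_real_, gqpc_flag = NA_character_,
                    theta = NA_real_, lag = NA_integer_,
                    snr_X1 = NA_real_, snr_X2 = NA_real_, snr_X3 = NA_real_,
                    expected_snr_X3 = expected_snr(3, cond$W),
                    efficiency = NA_real_)
  plan <- segment_plan(cond$fs,
                       segment_length = min(dim(series$data)[1],
                                            config$segment_length))
  if ("bicoherence" %in% arms) {
    res <- tryCatch({
      sp <- segment_series(series, plan)
      sig <- significance_map(cross_bicoherence(sp),
                              q_threshold = config$q_threshold)
      r_bqpc(sig, f1 = cond$F1, f2 = cond$F2, d = config$d)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$bqpc_flag <- paste0("error: ", conditionMessage(res))
    } else {
      row$R_BQPC <- res$R
      row$bqpc_flag <- res$flag
    }
  }
  if ("granger" %in% arms) {
    res <- tryCatch({
      g <- bgcs(series, plan = plan, lag_max = config$lag_max,
                mode = config$gc_mode)
      g <- bootstrap_significance(g, nboots = config$nboots,
                                  q_threshold = config$q_threshold,
                                  boot_segment_stride =
                                    if (is.null(config$gc_boot_stride)) 1L
                                    else config$gc_boot_stride)
      iv <- interval_of_interest(cond$F1, cond$F2, config$d, g$f_nyquist,
                                 g$fs)
      list(g = g, r = r_gqpc(g, iv))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$gqpc_flag <- paste0("error: ", conditionMessage(res))
    } else {
      row$R_GQPC <- res$r$R
      row$gqpc_flag <- res$r$flag
      row$theta <- res$g$theta
      row$lag <- res$g$lag
    }
  }
  if ("snr" %in% arms) {
    res <- tryCatch(empirical_snr(series, cond), error = function(e) e)
    if (!inherits(res, "error")) {
      row$snr_X1 <- res$empirical[1]
      row$snr_X2 <- res$empirical[2]
      row$snr_X3 <- res$empirical[3]
      row$efficiency <- attr(res, "efficiency")
    }
  }
  row
}

#' Run the simulation study over a condition grid
#'
#' Simulates every condition of the grid at every coupling strength and
#' collects one row per run. Per-condition seeds are derived deterministically
#' from `seed`, so results do not depend on execution order.
#'
#' @param grid A [build_condition_grid()] result (or data frame with columns
#'   `F1`, `F2`, `F3`).
#' @param couplings Coupling strengths; defaults to [study_couplings()].
#' @param config Analysis configuration, see [default_config()].
#' @param seed Master seed; the run of condition `c` at coupling index `w`
#'   uses seed `seed * 997 + w * 100 + c` (modulo 2^31).
#' @param verbose Print one line per condition.
#' @return A data frame of class `study_table`.
#' @export
run_study <- function(grid, couplings = study_couplings(),
                      config = default_config(), seed = 1L,
                      verbose = FALSE) {
  rows <- vector("list", nrow(grid) * length(couplings))
  idx <- 0L
  for (wi in seq_along(couplings)) {
    for (ci in seq_len(nrow(grid))) {
      idx <- idx + 1L
      cond_seed <- (abs(seed) * 997 + wi * 100000 + ci) %% 2147483647
      cond <- condition_spec(F1 = grid$F1[ci], F2 = grid$F2[ci],
                             F3 = grid$F3[ci], W = couplings[wi],
                             fs = config$fs,
                             epoch_duration = config$epoch_duration,
                             n_epochs = config$n_epochs,
                             seed = cond_seed)
      rows[[idx]] <- run_condition(cond, config)
      if (verbose) {
        r <- rows[[idx]]
        message(sprintf("W = %.3f condition %d/%d: R_BQPC = %s, R_GQPC = %s",
                        couplings[wi], ci, nrow(grid),
                        format(r$R_BQPC, digits = 3),
                        format(r$R_GQPC, digits = 3)))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("study_table", "data.frame")
  out
}

#' Per-coupling medians of the study indices
#'
#' Aggregates a study table into per-coupling-strength medians of R_BQPC and
#' R_GQPC (excluding undefined ratios and the boundary outliers 0 and 1, as
#' in the study's outlier rule) and of the X3 SNR efficiency (all defined
#' rows).
#'
#' @param table A [run_study()] result.
#' @return A data frame with one row per coupling strength: the group sizes
#'   and medians. Empty groups are omitted with a warning.
#' @export
aggregate_medians <- function(table) {
  ws <- sort(unique(table$W))
  rows <- lapply(ws, function(w) {
    sub <- table[table$W == w, , drop = FALSE]
    rb <- sub$R_BQPC[!is.na(sub$R_BQPC) & sub$bqpc_flag == "ok"]
    rg <- sub$R_GQPC[!is.na(sub$R_GQPC) & sub$gqpc_flag == "ok"]
    eff <- sub$efficiency[!is.na(sub$efficiency)]
    data.frame(W = w,
               n_bqpc = length(rb),
               median_R_BQPC = if (length(rb)) stats::median(rb) else NA_real_,
               n_gqpc = length(rg),
               median_R_GQPC = if (length(rg)) stats::median(rg) else NA_real_,
               median_efficiency = if (length(eff)) stats::median(eff)
                                   else NA_real_)
  })
  out <- do.call(rbind, rows)
  empty <- is.na(out$median_R_BQPC) & is.na(out$median_R_GQPC)
  if (any(empty)) {
    warning("no defined ratios for W in {",
            paste(out$W[empty], collapse = ", "), "}; groups omitted")
    out <- out[!empty, , drop = FALSE]
  }
  out
}
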