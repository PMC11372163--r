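test_that("the bootstrap-count rule follows the spectral resolution", {
  expect_equal(nboots_rule(0.2), 447L)
  expect_equal(nboots_rule(1), 1000L)
  expect_equal(nboots_rule(0.25), 500L)
  expect_error(nboots_rule(0), "positive")
})

test_that("the spectral interval of interest folds and clips correctly", {
  iv <- interval_of_interest(8.5, 10.5, 0.5, 50)
  expect_equal(as.numeric(iv), c(18, 20))
  expect_equal(attr(iv, "center"), 19)

  iv0 <- interval_of_interest(8, 10, 0, 50)
  expect_equal(as.numeric(iv0), c(18, 18))

  # aliased sum frequency: 48.4 + 36.6 = 85 folds to fs - 85 = 15 Hz
  ivf <- interval_of_interest(48.4, 36.6, 0.5, 50, fs = 100)
  expect_equal(attr(ivf, "center"), 15, tolerance = 1e-9)
  expect_equal(as.numeric(ivf), c(14, 16), tolerance = 1e-9)

  # clipped at the band edges
  ivc <- interval_of_interest(24.8, 24.9, 0.5, 50)
  expect_equal(ivc[2], 50)
  expect_error(interval_of_interest(25, 25, -1, 50), "non-negative")
})

test_that("lag selection prefers small orders and never exceeds the arg-min", {
  picks <- vapply(1:10, function(s) {
    set.seed(s)
    xy <- cbind(rnorm(5000), rnorm(5000))
    as.integer(select_lag(xy, lag_max = 20))
  }, integer(1))
  expect_gte(mean(picks <= 2), 0.95)

  recov <- vapply(1:10, function(s) {
    xy <- simulate_var2(5000, c1 = 0.5, c2 = 0.3, seed = s)
    l <- select_lag(xy, lag_max = 20)
    sc <- attr(l, "sc")
    expect_lte(as.integer(l), which.min(sc))
    as.integer(l)
  }, integer(1))
  expect_gte(mean(recov == 2), 0.9)

  expect_warning(select_lag(cbind(rnorm(60), rnorm(60)), lag_max = 50),
                 "reducing lag_max")
})

test_that("the Geweke spectrum integrates to the time-domain statistic", {
  xy <- simulate_var2(10000, c1 = 0.4, c2 = 0.25, seed = 1)
  fit <- qpcoupling:::var_ols(xy, 2)
  freqs <- seq(0.05, 49.95, by = 0.1)
  spec <- qpcoupling:::geweke_spectrum(fit$A, fit$sigma, freqs, 100)
  expect_true(all(spec >= 0))
  f_int <- mean(spec)
  f_td <- qpcoupling:::gc_time_domain(xy, 2)
  expect_lt(abs(f_int - f_td) / f_td, 0.05)
})

test_that("estimated-coefficient BGCS matches the true-coefficient oracle", {
  xy <- simulate_var2(10000, c1 = 0.5, c2 = 0, seed = 1)
  fit <- qpcoupling:::var_ols(xy, 2)
  freqs <- seq(0.05, 49.95, by = 0.1)
  est <- qpcoupling:::geweke_spectrum(fit$A, fit$sigma, freqs, 100)
  A <- array(0, c(2, 2, 2))
  A[1, 1, ] <- c(0.5, -0.3)
  A[1, 2, ] <- c(0.5, 0)
  A[2, 2, ] <- c(0.55, -0.2)
  truth <- qpcoupling:::geweke_spectrum(A, diag(2), freqs, 100)
  expect_lt(max(abs(est - truth) / truth), 0.10)
})

test_that("BGCS is non-negative, carries causal mass at the sum frequency,
           and shifts toward the output carrier as coupling grows", {
  cond <- condition_spec(8.5, 10.5, 9.5, W = 0.3, n_epochs = 32, seed = 2)
  g <- bgcs(simulate_condition(cond), mode = "welch", lag_max = 15)
  expect_true(all(g$bgcs >= 0))
  expect_equal(g$L, 63L) # 32 epochs, 50% overlap
  sum_band <- g$freq >= 18 & g$freq <= 20      # around f1 + f2 = 19
  carrier_band <- g$freq >= 8.5 & g$freq <= 10.5 # around F3 = 9.5
  ref_band <- g$freq >= 28 & g$freq <= 30      # no model structure
  # the coupling line leaves visible causal mass at the sum frequency
  expect_gt(sum(g$bgcs[sum_band]), sum(g$bgcs[ref_band]))

  strong <- condition_spec(8.5, 10.5, 9.5, W = 0.75, n_epochs = 32, seed = 2)
  gs <- bgcs(simulate_condition(strong), mode = "welch", lag_max = 15)
  # spurious causal mass concentrates near F3 as coupling strengthens
  ratio_w <- sum(g$bgcs[carrier_band]) / sum(g$bgcs[sum_band])
  ratio_s <- sum(gs$bgcs[carrier_band]) / sum(gs$bgcs[sum_band])
  expect_gt(ratio_s, ratio_w)
})

test_that("null data produce no significant frequencies in most replicates", {
  clean <- vapply(1:15, function(r) {
    es <- white_series(ns = 500, ne = 8, seed = 300 + r)
    g <- bgcs(es, mode = "single", lag_max = 10)
    set.seed(r)
    g <- suppressWarnings(bootstrap_significance(g, nboots = 80))
    sum(g$significant) == 0
  }, logical(1))
  expect_gte(mean(clean), 0.8)
})

test_that("theta determines the retained significant spectrum", {
  cond <- condition_spec(8.5, 10.5, 9.5, W = 0.3, n_epochs = 8, seed = 4)
  g <- bgcs(simulate_condition(cond), mode = "single", lag_max = 10)
  set.seed(1)
  g <- suppressWarnings(bootstrap_significance(g, nboots = 80))
  if (!is.na(g$theta)) {
    expect_equal(g$significant, g$bgcs >= g$theta)
    expect_true(all(g$bgcs_bar[!g$significant] == 0))
    expect_equal(min(g$bgcs[g$q_significant]), g$theta)
  }
  expect_warning(bootstrap_significance(g, nboots = 50), "nboots < 100")
})

test_that("R_GQPC reproduces the worked-example ratio of printed sums", {
  spec <- worked_example_gc_spectrum()
  res <- r_gqpc(spec, c(18, 20))
  expect_equal(res$numerator, 0.128, tolerance = 1e-12)
  expect_equal(res$denominator, 0.552, tolerance = 1e-12)
  expect_equal(res$R, 0.128 / 0.552, tolerance = 1e-12)
})

test_that("R_GQPC honours its contracts", {
  spec <- worked_example_gc_spectrum()
  # all significant mass inside the interval
  all_in <- planted_gc_spectrum(replace(numeric(249), 91:99, 0.05))
  expect_equal(r_gqpc(all_in, c(18, 20))$R, 1)
  # nothing significant: undefined flag
  none <- planted_gc_spectrum(numeric(249))
  res0 <- r_gqpc(none, c(18, 20))
  expect_true(is.na(res0$R))
  expect_equal(res0$flag, "undefined")
  expect_error(r_gqpc(spec, c(60, 70)), "outside")
  expect_error(r_gqpc(bgcs(simulate_condition(
    condition_spec(8.5, 10.5, 9.5, n_epochs = 2, seed = 1)),
    mode = "single", lag_max = 5), c(18, 20)), "significance not computed")
})
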