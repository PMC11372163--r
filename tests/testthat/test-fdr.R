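test_that("the mode-matching fit recovers the null fraction", {
  L <- 200
  for (p0 in c(0.5, 0.7, 0.9)) {
    est <- vapply(1:20, function(r) {
      set.seed(r)
      n0 <- round(p0 * 5000)
      vals <- c(rexp(n0, rate = L), runif(5000 - n0, 0.1, 0.6))
      fit_null_mixture(vals, L)$p0
    }, numeric(1))
    expect_lt(abs(mean(est) - p0), 0.1)
  }
})

test_that("degenerate and undersized samples are rejected", {
  expect_error(fit_null_mixture(rep(0.01, 1000), L = 100), "degenerate")
  expect_error(fit_null_mixture(rexp(100, 50), L = 50), "500 values")
})

test_that("pure-null samples yield almost no discoveries", {
  frac <- vapply(1:10, function(r) {
    set.seed(r)
    mean(fit_null_mixture(rexp(20000, rate = 200), 200)$q < 0.05)
  }, numeric(1))
  expect_lt(max(frac), 0.01)
})

test_that("q-values are monotone in the statistic and planted bins are found", {
  set.seed(3)
  vals <- c(rexp(5000, rate = 200), runif(500, 0.2, 0.6))
  fit <- fit_null_mixture(vals, 200)
  o <- order(vals)
  expect_true(all(diff(fit$q[o]) <= 1e-12))
  # planted (alternative) values are essentially all discovered
  expect_gt(mean(fit$q[5001:5500] < 0.05), 0.99)
})

test_that("the q < 0.05 mask is stable under a linear rescaling of the statistic", {
  set.seed(4)
  vals <- c(rexp(5000, rate = 200), runif(300, 0.2, 0.6))
  m1 <- fit_null_mixture(vals, 200)$q < 0.05
  m2 <- fit_null_mixture(vals / 2, 200)$q < 0.05
  expect_identical(m1, m2)
})

test_that("significance maps mask by q and respect monotonicity in b2", {
  sp <- segment_series(white_series(ns = 500, ne = 64, seed = 21),
                       segment_plan(100, 500, overlap = 0))
  bc <- cross_bicoherence(sp)
  sig <- significance_map(bc)
  expect_true(all(sig$b2bar[!sig$significant] == 0))
  expect_true(all(sig$b2bar[sig$significant] ==
                    bc$b2[sig$significant]))
  if (any(sig$significant)) {
    thr <- min(bc$b2[sig$significant])
    keep <- sig$principal & !bc$zero_denominator
    expect_true(all(sig$significant[keep][bc$b2[keep] > thr]))
  }
  # fitting on a different map's values is a grid mismatch
  sp2 <- segment_series(white_series(ns = 400, ne = 64, fs = 80, seed = 2),
                        segment_plan(80, 400, overlap = 0, delta_f = 0.25))
  bc2 <- cross_bicoherence(sp2)
  fit2 <- fit_null_mixture(bc2$b2[bc2$principal & !bc2$zero_denominator],
                           sp2$L)
  expect_error(significance_map(bc, fit2), "grid mismatch")
})

test_that("Storey q-values reduce to BH in the fallback and calibrate on nulls", {
  p <- seq(0.01, 1, by = 0.01)
  expect_equal(qvalues(p[1:5] * 0 + 0.2), rep(0.2, 5)) # constant: BH with ties
  # BH fallback equals an independent textbook implementation exactly
  set.seed(5)
  p_fixed <- round(runif(50), 3)
  expect_equal(stats::p.adjust(p_fixed, "BH"), textbook_bh(p_fixed))
  expect_equal(qvalues(rep(0.37, 8)), textbook_bh(rep(0.37, 8)))
  # uniform nulls produce (almost) no q < 0.05
  hits <- vapply(1:20, function(r) {
    set.seed(r)
    sum(qvalues(runif(1000)) < 0.05)
  }, numeric(1))
  expect_lt(mean(hits > 0), 0.1)
  expect_error(qvalues(numeric(0)), "empty")
  expect_error(qvalues(c(0.1, 1.2)), "0, 1")
})
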