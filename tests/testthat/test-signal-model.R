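test_that("carrier waveforms follow their piecewise/trig definitions", {
  # triangular peak, rectangular first branch, cosine at zero phase
  expect_equal(waveform_sample(waveform_spec("triangular", 1), 0.25), pi)
  expect_equal(waveform_sample(waveform_spec("rectangular", 1), 0), 1)
  expect_equal(waveform_sample(waveform_spec("cosine", 3), 0), 1)

  t <- seq(0, 2, by = 1 / 97)
  tri <- waveform_sample(waveform_spec("triangular", 1.7, 0.3), t)
  rect <- waveform_sample(waveform_spec("rectangular", 2.3, 5.1), t)
  cosn <- waveform_sample(waveform_spec("cosine", 0.9, 1.0), t)
  expect_true(all(tri >= -pi & tri <= pi))
  expect_true(all(rect %in% c(-1, 1)))
  expect_true(all(abs(cosn) <= 1))
  # half-open modular condition of the rectangular wave: the boundary point
  # 2 pi F t + omega = pi belongs to the negative branch
  expect_equal(waveform_sample(waveform_spec("rectangular", 1, 0), 0.5), -1)

  expect_error(waveform_spec("sawtooth", 1), "arg")
  expect_error(waveform_spec("cosine", -1), "positive")
})

test_that("the simulator is reproducible and respects the model equations", {
  cond <- condition_spec(8.5, 10.5, 9.5, W = 0.3, n_epochs = 4, seed = 11)
  s1 <- simulate_condition(cond)
  s2 <- simulate_condition(cond)
  expect_identical(s1$data, s2$data)
  expect_equal(dim(s1$data), c(500L, 4L, 3L))

  # X3 is exactly W * X1 * X2 plus carrier plus noise: with the same seed and
  # W = 0 subtracted off, the difference between a coupled and an uncoupled
  # run is W * X1 * X2
  c0 <- condition_spec(8.5, 10.5, 9.5, W = 0, n_epochs = 4, seed = 11)
  s0 <- simulate_condition(c0)
  expect_equal(s1$data[, , 3] - s0$data[, , 3],
               0.3 * s1$data[, , 1] * s1$data[, , 2], tolerance = 1e-12)

  # F3 constraint and its override
  expect_error(condition_spec(8, 10, 18, W = 0.1), "distinct")
  expect_s3_class(condition_spec(8, 10, 18, W = 0.1,
                                 allow_degenerate = TRUE),
                  "condition_spec")
})

test_that("uncoupled X3 variance matches carrier-plus-noise additivity", {
  cond <- condition_spec(19.1, 11.1, 12.7, W = 0, n_epochs = 64, seed = 2)
  v <- var(as.vector(simulate_condition(cond)$data[, , 3]))
  expect_equal(v, 1.5, tolerance = 0.05) # cosine 1/2 + unit noise
})

test_that("coupling increases X3 variance across seeds", {
  more <- vapply(1:20, function(s) {
    c0 <- condition_spec(19.1, 11.1, 12.7, W = 0, n_epochs = 8, seed = s)
    c1 <- condition_spec(19.1, 11.1, 12.7, W = 0.75, n_epochs = 8, seed = s)
    var(as.vector(simulate_condition(c1)$data[, , 3])) >
      var(as.vector(simulate_condition(c0)$data[, , 3]))
  }, logical(1))
  expect_true(all(more))
})

test_that("per-epoch phases are uniform on [0, 2 pi)", {
  cond <- condition_spec(8.5, 10.5, 9.5, fs = 100, epoch_duration = 0.05,
                         n_epochs = 3400, seed = 99)
  phases <- as.vector(attr(simulate_condition(cond), "phases"))[1:10000]
  ks <- suppressWarnings(ks.test(phases, punif, 0, 2 * pi))
  expect_gt(ks$p.value, 0.01)
})

test_that("analytic SNR formulas and monotonicity hold", {
  expect_equal(expected_snr(1), pi^2 / 3)
  expect_equal(expected_snr(2), 1)
  expect_equal(expected_snr(3, 0), 0.5)
  expect_equal(expected_snr(3, 0.3), (2 * pi^2 / 3 + 2) * 0.09 + 0.5)
  w <- seq(0, 1, by = 0.05)
  expect_true(all(diff(vapply(w, function(x) expected_snr(3, x),
                              numeric(1))) > 0))
  expect_error(expected_snr(4), "channel")
})

test_that("empirical SNR converges to the analytic values for X1 and X2", {
  reps <- vapply(1:8, function(s) {
    cond <- condition_spec(120 / (2 * pi), 70 / (2 * pi), 80 / (2 * pi),
                           W = 0, n_epochs = 64, seed = s)
    r <- empirical_snr(simulate_condition(cond), cond)
    c(r$empirical[1], r$empirical[2])
  }, numeric(2))
  se1 <- sd(reps[1, ]) / sqrt(ncol(reps))
  se2 <- sd(reps[2, ]) / sqrt(ncol(reps))
  expect_lt(abs(mean(reps[1, ]) - pi^2 / 3), 3 * se1 + 0.02)
  expect_lt(abs(mean(reps[2, ]) - 1), 3 * se2 + 0.02)
})

test_that("SNR efficiency of the coupled channel falls below 1", {
  cond <- condition_spec(120 / (2 * pi), 70 / (2 * pi), 80 / (2 * pi),
                         W = 0.3, n_epochs = 64, seed = 5)
  r <- empirical_snr(simulate_condition(cond), cond)
  expect_lt(attr(r, "efficiency"), 1)
  expect_gt(attr(r, "efficiency"), 0)
})

test_that("the periodogram SNR method recovers the right order of magnitude", {
  cond <- condition_spec(120 / (2 * pi), 70 / (2 * pi), 80 / (2 * pi),
                         W = 0, n_epochs = 64, seed = 3)
  r <- empirical_snr(simulate_condition(cond), cond, method = "periodogram")
  expect_gt(r$empirical[1], 2)   # pi^2/3 minus leakage loss
  expect_lt(r$empirical[1], 4.5)
  # a noiseless on-grid cosine has a zero noise floor
  c0 <- condition_spec(10, 11.3, 12.7, W = 0, noise_sd = 0, n_epochs = 4,
                       seed = 1)
  expect_error(empirical_snr(simulate_condition(c0), c0,
                             method = "periodogram"),
               "noise floor")
})
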