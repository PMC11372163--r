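test_that("the power-of-two resolution rule matches the study settings", {
  expect_equal(bispectral_resolution(100, 500), 0.25)
  expect_equal(bispectral_resolution(100, 400), 0.25)  # exact power of two
  expect_equal(bispectral_resolution(128, 128), 1)
  plan <- segment_plan(100, 500)
  expect_equal(plan$dft_length, 400L)
  expect_equal(plan$delta_f, 0.25)
  expect_equal(plan$f_nyquist, 50)
})

test_that("Welch segmentation counts follow the sliding rule", {
  cond <- condition_spec(19.1, 11.1, 12.7, n_epochs = 128, seed = 1)
  sp <- segment_series(simulate_condition(cond))
  expect_equal(sp$L, 255L) # (64000 - 500) / 250 + 1

  one <- white_series(ns = 500, ne = 1)
  expect_equal(segment_series(one)$L, 1L)
  two <- white_series(ns = 500, ne = 2)
  expect_equal(segment_series(two)$L, 3L)

  short <- white_series(ns = 100, ne = 1)
  expect_error(segment_series(short, segment_plan(100, 500)),
               "shorter than one segment")
})

test_that("segments are standardised and the DC bin vanishes", {
  sp <- segment_series(white_series(ns = 500, ne = 4, seed = 3))
  expect_true(all(Mod(sp$spectra[1, , ]) < 1e-8))
})

test_that("cross-spectra are Hermitian and vanish for independent noise", {
  sp <- segment_series(white_series(ns = 500, ne = 100, seed = 4),
                       segment_plan(100, 500, overlap = 0))
  auto <- cross_spectrum(sp, 1, 1)
  expect_true(all(Re(auto$C) >= 0))
  expect_true(all(abs(Im(auto$C)) < 1e-12))
  c12 <- cross_spectrum(sp, 1, 2)
  c21 <- cross_spectrum(sp, 2, 1)
  expect_equal(c12$C, Conj(c21$C))
  # independent channels: coherence-scale magnitude ~ 1/sqrt(L)
  mid <- 10:190
  expect_lt(mean(Mod(c12$C[mid])) / mean(Re(auto$C[mid])), 3 / sqrt(sp$L))
  expect_error(cross_spectrum(sp, 1, 9), "out of range")
})

test_that("vectorised bispectral estimators equal the naive triple loop", {
  sp <- segment_series(white_series(ns = 64, ne = 8, fs = 64, seed = 7),
                       segment_plan(64, 64, overlap = 0, delta_f = 1))
  expect_equal(dim(sp$spectra)[1], 64L) # 32-point bifrequency grid
  oracle <- naive_bicoherence(sp, 1, 2, 3)
  bc <- cross_bicoherence(sp, 1, 2, 3)
  bs <- cross_bispectrum(sp, 1, 2, 3)
  expect_lt(max(abs(bc$b2 - oracle$b2)), 1e-10)
  expect_lt(max(Mod(bs$B - oracle$B)), 1e-10)
  # i = j = k reduces to the single-channel bispectrum
  or1 <- naive_bicoherence(sp, 1, 1, 1)
  bs1 <- cross_bispectrum(sp, 1, 1, 1)
  expect_lt(max(Mod(bs1$B - or1$B)), 1e-10)
})

test_that("cross-bicoherence is bounded in [0, 1] and detects locked QPC", {
  sp <- segment_series(qpc_locked_series(noise_sd = 0.1),
                       segment_plan(128, 128, overlap = 0, delta_f = 1))
  bc <- cross_bicoherence(sp)
  expect_true(all(bc$b2 >= 0 & bc$b2 <= 1))
  expect_gte(bc$b2[8, 12], 0.99)
  expect_error(cross_bicoherence(segment_series(white_series(ne = 1))),
               "2 segments")
})

test_that("the null level of cross-bicoherence is 1/L", {
  sp <- segment_series(white_series(ns = 500, ne = 200, seed = 5),
                       segment_plan(100, 500, overlap = 0))
  bc <- cross_bicoherence(sp)
  vals <- bc$b2[bc$principal & !bc$zero_denominator]
  expect_gt(mean(vals), 0.8 / sp$L)
  expect_lt(mean(vals), 1.25 / sp$L)
})

test_that("2L b2 follows a chi-squared(2) null in distribution", {
  sp <- segment_series(white_series(ns = 500, ne = 200, seed = 42),
                       segment_plan(100, 500, overlap = 0))
  bc <- cross_bicoherence(sp)
  vals <- 2 * sp$L * bc$b2[bc$principal & !bc$zero_denominator]
  set.seed(42)
  ks <- suppressWarnings(ks.test(sample(vals, 1500), pchisq, df = 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("cross-bicoherence is invariant to per-segment channel rescaling", {
  base <- qpc_locked_series(noise_sd = 0.5, seed = 9)
  plan <- segment_plan(128, 128, overlap = 0, delta_f = 1)
  b_ref <- cross_bicoherence(segment_series(base, plan))$b2
  scaled <- base
  set.seed(1)
  for (e in seq_len(dim(scaled$data)[2])) {
    scaled$data[, e, 2] <- scaled$data[, e, 2] * runif(1, 0.2, 5)
  }
  b_scaled <- cross_bicoherence(segment_series(scaled, plan))$b2
  expect_equal(b_scaled, b_ref, tolerance = 1e-10)
})

test_that("sectors partition the bifrequency grid", {
  expect_equal(classify_sector(8.5, 10.5, 50), "Q_I")
  expect_equal(classify_sector(48.4, 36.6, 50), "Q_II")
  expect_equal(classify_sector(10, 45, 50), "Q_III")
  expect_equal(classify_sector(20, 30, 50), "Q_I")   # boundary sum = Nyquist
  expect_equal(classify_sector(30, 30, 50), "Q_III") # f1 = f2 above Nyquist
  expect_error(classify_sector(0, 10, 50), "0, f_nyquist")
  expect_error(classify_sector(10, 60, 50), "0, f_nyquist")

  grid <- bifrequency_grid(0.25, 50)
  counts <- table(grid$sector)
  expect_equal(sum(counts), 200L * 200L)
  expect_equal(sort(names(counts)), c("Q_I", "Q_II", "Q_III"))
})
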