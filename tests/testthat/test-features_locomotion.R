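test_that("autocovariance uses the biased, demeaned estimator", {
  x <- c(1, 2, 3, 4, 2)
  r <- autocorrelation(x, 2)
  n <- length(x); xb <- mean(x)
  manual <- sapply(0:2, function(k)
    sum((x[(1 + k):n] - xb) * (x[1:(n - k)] - xb)) / n)
  expect_equal(r, manual, tolerance = 1e-12)
  expect_equal(r[1], mean((x - xb)^2))
  # white noise decorrelates
  w <- generate_ar_series(numeric(0), 20000, seed = 8)
  rw <- autocorrelation(w, 1)
  expect_lt(abs(rw[2] / rw[1]), 0.05)
  # AR(1) lag-1 autocorrelation equals phi
  a1 <- generate_ar_series(0.6, 10000, seed = 9)
  ra <- autocorrelation(a1, 1)
  expect_equal(ra[2] / ra[1], 0.6, tolerance = 0.03)
})

test_that("Levinson-Durbin solves the Yule-Walker system", {
  # direct Toeplitz solve as the independent oracle
  set.seed(10)
  for (i in 1:10) {
    x <- generate_ar_series(c(0.5, -0.2), 500, seed = 100 + i)
    p <- sample(2:6, 1)
    a <- lpc_yule_walker(x, p)
    r <- autocorrelation(x, p)
    oracle <- solve(stats::toeplitz(r[1:p]), r[2:(p + 1)])
    expect_equal(a, as.numeric(oracle), tolerance = 1e-8)
    expect_length(a, p)
  }
  # and matches stats::ar.yw on a demeaned series
  x <- generate_ar_series(0.6, 5000, seed = 12)
  fit <- stats::ar.yw(x, aic = FALSE, order.max = 3)
  expect_equal(lpc_yule_walker(x, 3), as.numeric(fit$ar),
               tolerance = 1e-6)
  expect_error(lpc_yule_walker(rep(1, 50), 2), "constant")
  expect_error(lpc_yule_walker(1:3, 3), "longer")
})

test_that("LPC recovers AR generator coefficients", {
  for (s in 1:5) {
    x1 <- generate_ar_series(0.6, 10000, seed = 200 + s)
    expect_equal(lpc_yule_walker(x1, 1), 0.6, tolerance = 0.05)
    x2 <- generate_ar_series(c(0.5, -0.3), 10000, seed = 300 + s)
    expect_equal(lpc_yule_walker(x2, 2), c(0.5, -0.3), tolerance = 0.05)
  }
})

test_that("the LPCC recursion matches hand-unrolled values", {
  a <- c(0.8, -0.3, 0.1)
  cc <- lpcc(a, 5)
  expect_identical(cc[1], a[1])                      # c1 = a1 exactly
  expect_equal(lpcc(0.7, 2)[2], 0.7^2 / 2, tolerance = 1e-12)
  # hand-unrolled j = 2: c2 = a2 + (1/2) c1 a1
  expect_equal(cc[2], a[2] + 0.5 * a[1]^2, tolerance = 1e-12)
  expect_equal(lpcc(rep(0, 4), 6), rep(0, 6))
  expect_error(lpcc(c(0.5, 0.2), 1), ">=")
})

test_that("reference patterns are element-wise class means", {
  w1 <- c(1, 2, 3); w2 <- c(3, 2, 1)
  expect_equal(build_reference(list(w1)), w1)
  expect_equal(build_reference(list(w1, w2)), c(2, 2, 2))
  expect_equal(build_reference(list(w1, w1, w1)), w1)
  expect_error(build_reference(list()), "no windows")
  expect_error(build_reference(list(w1, c(1, 2))), "ragged")
})

test_that("DTW matches worked examples and the exhaustive path oracle", {
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dtw_distance(0, 3), 3)
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 2, 3)), 0)
  expect_error(dtw_distance(numeric(0), 1), "non-empty")
  set.seed(13)
  for (i in 1:100) {
    P <- round(rnorm(sample(1:6, 1)), 2)
    R <- round(rnorm(sample(1:6, 1)), 2)
    expect_equal(dtw_distance(P, R), bf_dtw(P, R), tolerance = 1e-12)
  }
})

test_that("reference-bank distances are per-class and order-invariant", {
  bank <- structure(list(a = c(0, 1, 0, -1), b = c(2, 2, 2, 2)),
                    class = "reference_bank")
  d <- dtw_features(c(0, 1, 0, -1), bank, normalize = FALSE)
  expect_equal(unname(d["a"]), 0)
  expect_gt(d["b"], 0)
  expect_length(d, 2)
  bank_rev <- structure(rev(unclass(bank)), class = "reference_bank")
  expect_equal(dtw_features(c(0.3, 1, 0, -1), bank, normalize = FALSE),
               dtw_features(c(0.3, 1, 0, -1), bank_rev, normalize = FALSE))
})

test_that("power spectrogram localizes tones and scales quadratically", {
  fs <- 64
  t <- (0:511) / fs
  x <- sin(2 * pi * 8 * t)
  sp <- power_spectrogram(x, 64, 32, fs)
  expect_equal(max(sp$freq_hz), fs / 2)
  peak_bins <- apply(sp$S, 1L, which.max)
  expect_true(all(sp$freq_hz[peak_bins] == 8))
  sp2 <- power_spectrogram(2 * x, 64, 32, fs)
  expect_equal(sum(sp2$S), 4 * sum(sp$S), tolerance = 1e-9)
  z <- power_spectrogram(rep(0, 128), 64, 32, fs)
  expect_true(all(z$S == 0))
  expect_error(power_spectrogram(rep(0, 32), 64, 32, fs), "exceeds")
})

test_that("band summaries isolate the tone's band", {
  fs <- 64
  x <- sin(2 * pi * 12 * (0:511) / fs)
  sp <- power_spectrogram(x, 64, 32, fs)
  bands <- spectral_band_features(sp, c(0, 8, 16, 32))
  expect_length(bands, 3)
  expect_equal(which.max(bands), 2L)
  z <- power_spectrogram(rep(0, 128), 64, 32, fs)
  expect_equal(spectral_band_features(z, c(0, 16, 32)),
               rep(log(1e-12), 2))
  expect_error(spectral_band_features(sp, c(0.1, 0.9, 8)), "no bins")
})

test_that("magnitude and delay embedding follow their definitions", {
  expect_equal(magnitude3(3, 4, 0), 5)
  expect_equal(magnitude3(0, 0, 0), 0)
  expect_equal(magnitude3(1, 1, 1), sqrt(3))
  expect_error(magnitude3(1:2, 1:3, 1:3), "equal lengths")
  e <- embed_series(1:7, m = 3, tau = 1)
  expect_equal(nrow(e$vectors), 5)
  expect_equal(e$vectors[1, ], c(1, 2, 3))
  expect_equal(embed_series(1:5, m = 1)$vectors[, 1], 1:5)
  set.seed(14)
  for (i in 1:10) {
    n <- sample(20:50, 1); m <- sample(2:5, 1); tau <- sample(1:3, 1)
    if (n - (m - 1) * tau < m) next
    expect_equal(nrow(embed_series(rnorm(n), m, tau)$vectors),
                 n - (m - 1) * tau)
  }
  expect_error(embed_series(1:4, m = 5), "too short")
})

test_that("SSCE hits its closed forms and entropy bounds", {
  # five dimensions with exactly equal variances -> ln 5
  base <- rep(c(1, -1), 10)
  eq <- matrix(base, nrow = 20, ncol = 5)
  expect_equal(ssce(eq), log(5), tolerance = 1e-9)
  # all variance in one dimension -> 0
  one <- cbind(rnorm(20), matrix(1, 20, 4))
  expect_equal(ssce(one), 0)
  # bounds and scale invariance on random embeddings
  set.seed(15)
  for (i in 1:20) {
    e <- embed_series(rnorm(60), m = 5)
    v <- ssce(e)
    expect_gte(v, 0)
    expect_lte(v, log(5) + 1e-12)
    e2 <- e; e2$vectors <- e$vectors * runif(1, 0.1, 10)
    expect_equal(ssce(e2), v, tolerance = 1e-9)
  }
  expect_error(ssce(matrix(1, 10, 5)), "constant")
})

test_that("phase angles are quadrant-aware degrees", {
  expect_equal(phase_angle_series(1, 1), 45)
  expect_equal(phase_angle_series(1, 0), 0)
  expect_equal(phase_angle_series(0, 1), 90)
  expect_equal(phase_angle_series(-1, 0), 180)
  expect_equal(phase_angle_series(1, -1), -45)
  expect_warning(phase_angle_series(0, 0), "undefined")
})

test_that("skewness and kurtosis match the adjusted sample formulas", {
  expect_equal(skewness(1:5), 0)
  set.seed(16)
  x <- rnorm(50)
  expect_equal(skewness(-x), -skewness(x), tolerance = 1e-12)
  expect_equal(kurtosis(3 * x), kurtosis(x), tolerance = 1e-10)
  # independent library implementations of the same estimators
  skip_if_not_installed("e1071")
  for (i in 1:10) {
    y <- rnorm(sample(10:200, 1))
    expect_equal(skewness(y), e1071::skewness(y, type = 2),
                 tolerance = 1e-10)
    expect_equal(kurtosis(y), e1071::kurtosis(y, type = 2),
                 tolerance = 1e-10)
  }
})

test_that("moment estimators behave on reference samples", {
  set.seed(17)
  z <- rnorm(10000)
  expect_lt(abs(skewness(z)), 0.1)
  expect_lt(abs(kurtosis(z)), 0.2)
  # two-point +-1 sample: direct evaluation of the estimator
  tp <- rep(c(-1, 1), 50)
  n <- 100
  s <- sd(tp)
  expected <- (n * (n + 1) / ((n - 1) * (n - 2) * (n - 3))) *
    sum(((tp - mean(tp)) / s)^4) - 3 * (n - 1)^2 / ((n - 2) * (n - 3))
  expect_equal(kurtosis(tp), expected, tolerance = 1e-12)
  expect_equal(kurtosis(tp), -2.0, tolerance = 0.15)
  expect_error(skewness(c(1, 2)), "n >= 3")
  expect_error(kurtosis(rep(2, 10)), "constant")
})

test_that("circular statistics handle wrap-around", {
  expect_equal(circular_mean(c(350, 10)), 0, tolerance = 1e-9)
  expect_equal(circular_mean(c(80, 100)), 90, tolerance = 1e-9)
  expect_equal(circular_sd(rep(33, 10)), 0, tolerance = 1e-6)
  expect_gt(circular_sd(c(0, 90, 180, 270)), 100)
})

test_that("locomotion feature extraction yields the announced schema", {
  scen <- default_scenario(cycles = 1, bout_s = 6, seed = 21)
  rec <- generate_recording(scen)
  ws <- segment(rec, 100, 50)
  bank <- build_reference_bank(ws)
  ft <- extract_locomotion_features(ws, bank,
                                    list(lpc_order = 8, n_cepstra = 8))
  k <- length(bank)
  expect_equal(length(feature_names(ft)), 8 + k + 1 + 2 + 2)
  expect_true(all(grepl("^[a-z_]+__[a-z_]+__", feature_names(ft))))
  expect_equal(nrow(ft), n_windows(ws))
  # determinism: identical windows give identical rows
  ft2 <- extract_locomotion_features(ws, bank,
                                     list(lpc_order = 8, n_cepstra = 8))
  expect_equal(feature_matrix(ft), feature_matrix(ft2))
})
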