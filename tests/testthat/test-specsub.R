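test_that("noise power estimation averages the leading frames", {
  p <- frame_params(8L, 8L, "rectangular", 100)
  mag <- matrix(2, 4, 8)
  sf <- structure(list(magnitude = mag, phase = mag * 0, params = p),
                  class = "spectral_frames")
  prof <- estimate_noise_power(sf, 4)
  expect_equal(prof$power, rep(4, 8))
  expect_equal(prof$mean_amplitude, rep(2, 8))

  sf$magnitude[1, ] <- sqrt(2)
  sf$magnitude[2, ] <- 2
  prof2 <- estimate_noise_power(sf, 2)       # powers {2, 4} -> mean 3
  expect_equal(prof2$power, rep(3, 8))

  prof1 <- estimate_noise_power(sf, 1)
  expect_equal(prof1$power, rep(2, 8))
  expect_error(estimate_noise_power(sf, 5), "exceeds")
})

test_that("basic subtraction applies the two-branch rule", {
  prof <- list(power = 1)
  expect_equal(subtract_basic(4, prof, a = 2, b = 0.01), 2)
  expect_equal(subtract_basic(1, prof, a = 2, b = 0.01), 0.01)
  x <- matrix(runif(20), 4, 5)
  prof5 <- list(power = rep(0.5, 5))
  expect_equal(subtract_basic(x, prof5, a = 0, b = 0.3), x)
  expect_error(subtract_basic(-1, prof, 1, 0), "non-negative")
})

test_that("basic spectral subtraction removes stationary noise and helps at 0 dB", {
  p <- frame_params()
  sp <- scene_spec(1.5, list(), noise_spec("fan_hum", 0, 0), seed = 11)
  noise_only <- generate_scene(sp)$noisy
  y <- denoise_basic(noise_only, subtraction_config(a = 1, b = 0),
                     params = p, nis = nis_frames(0.5, p))
  expect_lt(sum(y^2), 0.10 * sum(noise_only^2))

  sc <- quick_scene(snr_db = 0, seed = 2)
  out <- denoise_basic(sc$noisy, params = p, nis = nis_frames(0.5, p))
  expect_gt(snr_db(sc$clean, out), snr_db(sc$clean, sc$noisy))

  # all-zero noise profile: subtraction is a no-op up to the round trip
  prof0 <- list(power = numeric(p$frame_len), mean_amplitude = numeric(p$frame_len))
  y0 <- denoise_basic(sc$noisy, subtraction_config(a = 8, b = 0), p,
                      nis_frames(0.5, p), profile = prof0)
  n_cov <- (n_frames(length(sc$noisy), p) - 1L) * p$hop + p$frame_len
  expect_lt(max(abs(y0[1:n_cov] - sc$noisy[1:n_cov])), 1e-9)
})

test_that("Slepian tapers are orthonormal and match the sinc-kernel oracle", {
  ts <- slepian_tapers(64, NW = 3, L = 5)
  G <- ts$tapers %*% t(ts$tapers)
  expect_lt(max(abs(G - diag(5))), 1e-8)

  # leading taper is positive and unimodal
  t1 <- slepian_tapers(33, NW = 2.5, L = 1)$tapers[1, ]
  expect_true(all(t1 > 0))
  expect_equal(sum(diff(sign(diff(t1))) != 0), 1L)

  # oracle: top eigenvectors of the dense spectral concentration matrix
  N <- 64; W <- 3 / N
  i <- outer(0:(N - 1), 0:(N - 1), `-`)
  K <- ifelse(i == 0, 2 * W, sin(2 * pi * W * i) / (pi * i))
  eo <- eigen(K, symmetric = TRUE)
  for (k in 1:5) {
    v <- eo$vectors[, k]
    u <- ts$tapers[k, ]
    if (sum(v * u) < 0) v <- -v
    expect_lt(max(abs(v - u)), 1e-6)
  }

  expect_error(slepian_tapers(16, 3, 20), "more tapers")
})

test_that("multitaper PSD reduces to the single-taper periodogram and is >= 0", {
  ts1 <- slepian_tapers(64, NW = 3, L = 1)
  set.seed(5)
  x <- stats::rnorm(64)
  P1 <- multitaper_psd(x, ts1)
  expect_equal(P1, Mod(stats::fft(ts1$tapers[1, ] * x))^2, tolerance = 1e-12)
  expect_true(all(multitaper_psd(numeric(64), slepian_tapers(64, 3, 5)) == 0))
  expect_error(multitaper_psd(numeric(32), ts1), "match")
})

test_that("frame smoothing averages over 2M+1 frames with truncated edges", {
  expect_equal(smooth_frames(c(1, 2, 3), M = 0), c(1, 2, 3))
  expect_equal(smooth_frames(c(1, 2, 3), M = 1), c(1.5, 2, 2.5))
  cons <- matrix(4, 6, 3)
  expect_equal(smooth_frames(cons, M = 2), cons)
})

test_that("improved gain follows the two-branch rule with alpha = 0 identity", {
  expect_equal(improved_gain(2, 1, alpha = 1, beta = 0.5), 0.5)
  expect_equal(improved_gain(1, 1, alpha = 2, beta = 0.25), 0.25)
  Py <- matrix(runif(12) + 0.5, 3, 4)
  expect_equal(improved_gain(Py, rep(0.2, 4), alpha = 0, beta = 0.5),
               matrix(1, 3, 4))
  expect_equal(improved_gain(0, 1, 1, 0.5), 0)
})

test_that("improved subtraction suppresses noise-only input and helps at 0 dB", {
  p <- frame_params()
  sp <- scene_spec(1.5, list(), noise_spec("fan_hum", 0, 0), seed = 12)
  noise_only <- generate_scene(sp)$noisy
  y <- denoise_improved(noise_only, subtraction_config(alpha = 1, beta = 0),
                        params = p, nis = nis_frames(0.5, p))
  expect_lt(sum(y^2), 0.10 * sum(noise_only^2))

  sc <- quick_scene(snr_db = 0, seed = 6)
  out <- denoise_improved(sc$noisy, params = p, nis = nis_frames(0.5, p))
  expect_gt(snr_db(sc$clean, out), snr_db(sc$clean, sc$noisy))
})
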