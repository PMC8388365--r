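test_that("noise statistics initialize from the preamble frames", {
  p <- frame_params(8L, 8L, "rectangular", 100)
  mag <- matrix(2, 4, 8)
  mag[1, ] <- sqrt(2)
  sf <- structure(list(magnitude = mag, phase = mag * 0, params = p),
                  class = "spectral_frames")
  st <- init_noise_stats(sf, 2)              # powers {2, 4} -> 3
  expect_equal(st$lambda_d, rep(3, 8))
  expect_equal(st$xi_prev, rep(0, 8))
  st1 <- init_noise_stats(sf, 1)
  expect_equal(st1$lambda_d, rep(2, 8))
  expect_error(init_noise_stats(sf, 9), "exceeds")
})

test_that("posterior SNR, decision-directed prior and gain are exact", {
  expect_equal(posterior_snr(4, 2), 2)
  expect_equal(posterior_snr(0, 2), 0)
  expect_true(is.finite(posterior_snr(1, 0)))   # floored division

  expect_equal(prior_snr_dd(3, 7, alpha_dd = 1), 7)
  expect_equal(prior_snr_dd(3, 7, alpha_dd = 0), 2)
  expect_equal(prior_snr_dd(0.5, 7, alpha_dd = 0), 0)  # floored at 0

  expect_equal(wiener_gain(0), 0)
  expect_equal(wiener_gain(1), 0.5)
  expect_equal(wiener_gain(3), 0.75)

  # with alpha_dd = 0 the filter reduces to H = (gamma - 1)/gamma for gamma > 1
  gamma <- c(0.5, 1, 2, 10)
  H <- wiener_gain(prior_snr_dd(gamma, 0, alpha_dd = 0))
  expect_equal(H, pmax(gamma - 1, 0) / pmax(gamma, 1e-12) * (gamma > 1) +
                 0 * (gamma <= 1), tolerance = 1e-12)
})

test_that("Wiener filtering attenuates noise-only input and helps at 0 dB", {
  p <- frame_params()
  sp <- scene_spec(1.5, list(), noise_spec("fan_hum", 0, 0), seed = 13)
  noise_only <- generate_scene(sp)$noisy
  y <- denoise_wiener(noise_only, p, nis_frames(0.5, p))
  skip_n <- 10L * p$hop + p$frame_len
  expect_lt(sum(y[-seq_len(skip_n)]^2),
            0.15 * sum(noise_only[-seq_len(skip_n)]^2))

  sc <- quick_scene(snr_db = 0, seed = 8)
  nis <- nis_frames(0.5, p)
  out <- denoise_wiener(sc$noisy, p, nis)
  ot <- trim_leading_transient(out, nis, p)
  ct <- trim_leading_transient(sc$clean, nis, p)
  expect_gt(snr_db(ct, ot), snr_db(sc$clean, sc$noisy))

  # gain never exceeds 1: output magnitude bounded by input bin-wise
  sfo <- stft(out, p); sfi <- stft(sc$noisy, p)
  n_ok <- min(nrow(sfo$magnitude), nrow(sfi$magnitude))
  expect_lt(max(sfo$magnitude[2, ] - sfi$magnitude[2, ]), 1e-6)
})

test_that("leading-transient trimming removes exactly the preamble span", {
  p <- frame_params()
  x <- stats::rnorm(96000)
  expect_identical(trim_leading_transient(x, 0, p), x)
  nis <- 39L
  tr <- nis * p$hop + p$frame_len - p$hop
  y <- trim_leading_transient(x, nis, p)
  expect_length(y, length(x) - tr)
  expect_error(trim_leading_transient(x[1:1000], nis, p), "whole signal")

  # removing error-only preamble samples can only raise the SNR
  sc <- quick_scene(snr_db = 0, seed = 14)
  out <- denoise_wiener(sc$noisy, p, nis)
  expect_gte(snr_db(trim_leading_transient(sc$clean, nis, p),
                    trim_leading_transient(out, nis, p)),
             snr_db(sc$clean, out))
})
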