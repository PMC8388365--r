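test_that("events are seeded, sized and spectrally shaped as designed", {
  fs <- 32000
  crow <- event_spec("crow", onset_s = 0, duration_s = 0.25)
  w1 <- generate_event(crow, fs, seed = 1)
  w2 <- generate_event(crow, fs, seed = 1)
  expect_identical(w1, w2)
  expect_length(w1, 8000L)

  cough <- event_spec("cough", onset_s = 0)
  purr <- event_spec("purr", onset_s = 0)
  flap <- event_spec("flap", onset_s = 0)
  wc <- generate_event(cough, fs, seed = 1)
  wp <- generate_event(purr, fs, seed = 1)
  wf <- generate_event(flap, fs, seed = 1)

  expect_gt(spectral_centroid(w1, fs), 2000)
  expect_lt(spectral_centroid(wc, fs), 1500)
  expect_lt(spectral_centroid(wc, fs), spectral_centroid(w1, fs))

  # purr: amplitude-envelope modulation depth > 0.3 over the interior
  seg <- matrix(wp[321:(320 + 96 * 320)], nrow = 320)  # 10 ms blocks
  rmsb <- sqrt(colMeans(seg^2))
  depth <- (max(rmsb) - min(rmsb)) / (max(rmsb) + min(rmsb))
  expect_gt(depth, 0.3)

  # flap: broadband (flatter spectrum than purr) and at least crow-long
  expect_gt(spectral_flatness(wf), spectral_flatness(wp))
  expect_gte(flap$duration_s, crow$duration_s)

  expect_error(event_spec("bark", onset_s = 0), "arg")
  expect_error(event_spec("crow", onset_s = 0, duration_s = 0), "positive")
})

test_that("scenes are additive, annotated, seeded and SNR-exact", {
  sc <- quick_scene(snr_db = 0, seed = 3)
  expect_equal(length(sc$clean), length(sc$noisy))
  expect_lt(max(abs(sc$noisy - sc$clean - sc$noise)), 1e-12)
  expect_equal(snr_db(sc$clean, sc$noisy), 0, tolerance = 0.1)
  expect_equal(sc$annotations$kind, c("crow", "cough"))
  expect_true(all(diff(sc$annotations$start_sample) > 0))
  expect_true(all(sc$annotations$end_sample <= length(sc$clean)))

  sc2 <- quick_scene(snr_db = 0, seed = 3)
  expect_identical(sc$noisy, sc2$noisy)

  # no events: clean is all-zero, noisy is pure noise
  sp0 <- scene_spec(1.0, list(), noise_spec("white", 0, 0), seed = 9)
  sc0 <- generate_scene(sp0)
  expect_true(all(sc0$clean == 0))
  expect_identical(sc0$noisy, sc0$noise)

  # overlap rejected
  e1 <- event_spec("crow", onset_s = 0.6, duration_s = 0.5)
  e2 <- event_spec("cough", onset_s = 0.7)
  expect_error(generate_scene(scene_spec(2.5, list(e1, e2))), "overlap")
  expect_error(scene_spec(2.0, list(event_spec("crow", onset_s = 0.1))),
               "preamble")
})

test_that("add_noise hits the target SNR and is seeded and stationary", {
  fs <- 32000
  x <- sin(2 * pi * 440 * (0:31999) / fs)
  attr(x, "sample_rate") <- fs
  ns <- noise_spec("white", 0, 10)
  y <- add_noise(x, ns, seed = 4)
  d <- attr(y, "noise")
  expect_equal(sum(d^2), sum(x^2) / 10, tolerance = 0.02)
  expect_equal(snr_db(as.numeric(x), as.numeric(y)), 10, tolerance = 0.1)

  y2 <- add_noise(x, ns, seed = 4)
  expect_identical(attr(y2, "noise"), d)

  # stationarity: segment variances of the pure-noise residue within 3x
  segv <- apply(matrix(d, ncol = 16), 2, stats::var)
  expect_lt(max(segv) / min(segv), 3)

  expect_error(add_noise(numeric(100), ns, seed = 1), "zero energy")
})
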