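test_that("frame counting and slicing follow floor((n - N)/hop) + 1", {
  p <- frame_params(frame_len = 400L, hop = 200L, window = "rectangular",
                    sample_rate = 1000)
  x <- seq_len(1000) / 1000
  fr <- frame_signal(x, p)
  expect_equal(nrow(fr), 4L)
  expect_error(frame_signal(x[1:100], p), "shorter")

  # rectangular window, hop = N: concatenating rows reproduces x (truncated)
  p2 <- frame_params(400L, 400L, "rectangular", 1000)
  fr2 <- frame_signal(x, p2)
  expect_equal(as.numeric(t(fr2)), x[1:800])

  # constant signal + hamming: every row identical
  p3 <- frame_params(64L, 32L, "hamming", 1000)
  fr3 <- frame_signal(rep(1, 512), p3)
  expect_true(all(abs(sweep(fr3, 2L, fr3[1, ])) < 1e-15))
})

test_that("analyze returns modulus and phase of the per-frame DFT", {
  p <- frame_params(64L, 64L, "rectangular", 1000)
  z <- analyze(matrix(0, 2, 64), p)
  expect_true(all(z$magnitude == 0))
  expect_true(all(z$phase == 0))

  imp <- matrix(0, 1, 64); imp[1, 1] <- 1
  zi <- analyze(imp, p)
  expect_equal(as.numeric(zi$magnitude), rep(1, 64))

  k0 <- 5
  fr <- matrix(cos(2 * pi * k0 * (0:63) / 64), 1, 64)
  zc <- analyze(fr, p)
  mag <- as.numeric(zc$magnitude)
  expect_equal(mag[k0 + 1], 32, tolerance = 1e-10)
  expect_equal(mag[64 - k0 + 1], 32, tolerance = 1e-10)
  expect_lt(max(mag[-c(k0 + 1, 64 - k0 + 1)]), 1e-9)
})

test_that("synthesize inverts analyze and is linear in magnitude", {
  p <- frame_params(128L, 64L, "hamming", 8000)
  set.seed(42)
  x <- stats::rnorm(2000)
  sf <- stft(x, p)
  n_cov <- (nrow(sf$magnitude) - 1L) * p$hop + p$frame_len
  xr <- synthesize(sf)
  expect_lt(max(abs(xr - x[seq_len(n_cov)])) / max(abs(x)), 1e-9)

  sf0 <- sf; sf0$magnitude[] <- 0
  expect_true(all(synthesize(sf0) == 0))

  sf2 <- sf; sf2$magnitude <- 2 * sf$magnitude
  expect_equal(synthesize(sf2), 2 * xr, tolerance = 1e-12)

  bad <- sf; bad$phase <- bad$phase[, 1:10]
  expect_error(synthesize(bad), "mismatch")
})

test_that("per-frame Parseval identity holds", {
  p <- frame_params(256L, 128L, "hanning", 8000)
  set.seed(7)
  fr <- frame_signal(stats::rnorm(3000), p)
  sf <- analyze(fr, p)
  lhs <- rowSums(sf$magnitude^2) / p$frame_len
  rhs <- rowSums(fr^2)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})
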