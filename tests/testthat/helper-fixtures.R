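# Shared fixtures. Heavy computations (the 20-scene benchmark) are memoized
# in this environment so that several test files can reuse them within one
# test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# independent brute-force oracle for atom selection: enumerate the printed
# gene grid and evaluate the Gabor formula inline (no package dictionary code)
brute_force_best <- function(residual, N) {
  t <- 0:(N - 1)
  best <- list(fitness = -1, gene = NULL)
  for (j in 1:log2(N)) {
    s <- 2^j
    for (p in 0:(N * 2^(1 - j) - 1)) {
      mu <- p * s / 2
      for (k in 0:(2^(j + 1) - 1)) {
        v <- k * pi / s
        for (i in 0:12) {
          a <- (1 / sqrt(s)) * exp(-pi * ((t - mu) / s)^2) * cos(v * t + i * pi / 6)
          nrm <- sqrt(sum(a^2))
          if (nrm < 1e-10) next
          fit <- abs(sum(residual * a / nrm))
          if (fit > best$fitness + 1e-12) {
            best <- list(fitness = fit, gene = c(j = j, p = p, k = k, i = i))
          }
        }
      }
    }
  }
  best
}

# a small, fast scene: 2 s, crow + cough, fan hum @ given SNR
quick_scene <- function(snr_db = 0, seed = 1, impulsive_rate = 0) {
  e1 <- event_spec("crow", onset_s = 0.6)
  e2 <- event_spec("cough", onset_s = 1.1)
  generate_scene(scene_spec(2.0, list(e1, e2),
                            noise_spec("fan_hum", impulsive_rate, snr_db),
                            seed = seed))
}

# spectral centroid in Hz of a waveform
spectral_centroid <- function(x, fs) {
  n <- length(x)
  mag <- Mod(stats::fft(x))[seq_len(n %/% 2)]
  freqs <- (seq_len(n %/% 2) - 1) * fs / n
  sum(freqs * mag) / sum(mag)
}

# geometric-mean / arithmetic-mean spectral flatness
spectral_flatness <- function(x) {
  p <- Mod(stats::fft(x))[2:(length(x) %/% 2)]^2
  exp(mean(log(p + 1e-30))) / mean(p)
}

# the package's standard study conditions (20 scenes, 0 dB), denoised by all
# five methods; returns per-scene SNR/RMSE tables plus trimmed-Wiener metrics
benchmark_fixture <- function() {
  memo("benchmark20", {
    specs <- benchmark_scene_specs(20, snr_db = 0, seeds = 1:20)
    run_benchmark(specs, classifiers = FALSE)
  })
}

# Wiener-filtered labeled dataset over the same 20 scenes (recognition angle)
dataset_fixture <- function() {
  memo("dataset_wf", {
    specs <- benchmark_scene_specs(20, snr_db = 0, seeds = 1:20)
    params <- frame_params()
    sets <- lapply(specs, function(sp) {
      scene <- generate_scene(sp)
      nis <- nis_frames(scene$preamble_s, params)
      y <- denoise_wiener(scene$noisy, params, nis)
      segs <- annotations_to_segments(scene$annotations, params,
                                      n_frames(length(y), params))
      build_dataset(scene, y, "wf", segs, params)
    })
    combine_datasets(sets)
  })
}
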