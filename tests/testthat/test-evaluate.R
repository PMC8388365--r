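test_that("SNR follows the energy-ratio definition with an Inf sentinel", {
  s <- sin(2 * pi * 0.01 * (0:999))
  e <- stats::rnorm(1000)
  e <- e * sqrt(sum(s^2) / sum(e^2))          # error energy = signal energy
  expect_equal(snr_db(s, s + e), 0, tolerance = 1e-12)
  e10 <- e / sqrt(10)
  expect_equal(snr_db(s, s + e10), 10, tolerance = 1e-12)
  expect_identical(snr_db(s, s), Inf)
  expect_error(snr_db(numeric(10), stats::rnorm(10)), "zero energy")
  expect_error(snr_db(s, s[1:10]), "mismatch")

  # invariant to common scaling of both signals
  expect_equal(snr_db(3 * s, 3 * (s + e)), snr_db(s, s + e))
})

test_that("RMSE is the pre-vs-post root mean square difference", {
  x <- stats::rnorm(500)
  expect_equal(rmse(x, x), 0)
  expect_equal(rmse(x, x + 0.3), 0.3, tolerance = 1e-12)
  y <- stats::rnorm(500)
  expect_equal(rmse(2 * x, 2 * y), 2 * rmse(x, y), tolerance = 1e-12)
  expect_error(rmse(x, y[1:10]), "mismatch")
})

test_that("dataset rows count frames inclusively and merge by label", {
  p <- frame_params()
  sc <- quick_scene(snr_db = 10, seed = 61)
  segs <- data.frame(start_frame = c(10L, 60L, 80L),
                     end_frame = c(55L, 69L, 84L),
                     label = c("crow", "crow", "cough"),
                     stringsAsFactors = FALSE)
  ds <- build_dataset(sc, sc$noisy, "none", segs, p)
  expect_equal(ncol(ds$features), 39L)
  expect_equal(sum(ds$labels == "crow"), 46L + 10L)
  expect_equal(sum(ds$labels == "cough"), 5L)

  empty <- build_dataset(sc, sc$noisy, "none", segs[0, ], p)
  expect_length(empty$labels, 0L)

  segs$label[1] <- NA
  expect_error(build_dataset(sc, sc$noisy, "none", segs, p), "labeled")
})

test_that("classifier protocol computes consistent accuracies on separable data", {
  set.seed(62)
  n <- 60
  X <- rbind(matrix(stats::rnorm(n * 39, mean = 0), n, 39),
             matrix(stats::rnorm(n * 39, mean = 6), n, 39))
  ds <- structure(list(features = X,
                       labels = rep(c("crow", "purr"), each = n),
                       provenance = data.frame(scene = 1, method = "x",
                                               segment = 1)[rep(1, 2 * n), ]),
                  class = "labeled_dataset")
  rep5 <- evaluate_classifiers(ds, n_repeats = 5)
  expect_equal(nrow(rep5$per_repeat), 5L)
  expect_equal(rep5$summary$correct + rep5$summary$incorrect,
               rep5$summary$total)
  expect_equal(rep5$summary$accuracy,
               100 * rep5$summary$correct / rep5$summary$total)
  # trivially separable clusters: everything correct
  expect_equal(unname(rep5$mean_accuracy["knn"]), 100)
  expect_error(evaluate_classifiers(
    structure(list(features = X[1:60, ], labels = rep("crow", 60)),
              class = "labeled_dataset")), "two classes")
})

test_that("run_benchmark emits the expected report shapes", {
  specs <- benchmark_scene_specs(1, snr_db = 0, seeds = 5)
  rep1 <- run_benchmark(specs, methods = c("bss", "wf"), classifiers = FALSE)
  expect_equal(nrow(rep1$signal), 1L)
  expect_named(rep1$signal, c("scene", "snr_bss", "rmse_bss", "snr_wf",
                              "rmse_wf"))
  expect_equal(length(rep1$signal_mean), 4L)
  expect_equal(nrow(rep1$wiener_trimmed), 1L)
  expect_error(run_benchmark(list()), "at least one scene")
})
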