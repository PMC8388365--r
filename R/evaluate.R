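#' Signal-to-noise ratio in dB
#'
#' `SNR = 10*log10(sum(s^2) / sum((x - s)^2))` with `s` the clean reference
#' and `x` the processed (or noisy) signal. Returns `Inf` when the error
#' energy is exactly zero.
#'
#' @param clean Clean reference waveform.
#' @param processed Processed waveform of the same length.
#' @return SNR in decibels.
#' @export
snr_db <- function(clean, processed) {
  if (length(clean) != length(processed)) stop("length mismatch")
  es <- sum(clean^2)
  if (es <= 0) stop("clean signal has zero energy")
  ee <- sum((processed - clean)^2)
  if (ee == 0) return(Inf)
  10 * log10(es / ee)
}

#' Root-mean-square error between pre- and post-filter signals
#'
#' `RMSE = sqrt(mean((x - f)^2))` with `x` the signal before filtering and
#' `f` after. Note this is deliberately the pre-vs-post difference, not an
#' error against the clean reference: it measures how much the filter changed
#' the signal.
#'
#' @param before Waveform before filtering.
#' @param after Waveform after filtering, same length.
#' @return RMSE value.
#' @export
rmse <- function(before, after) {
  if (length(before) != length(after)) stop("length mismatch")
  if (length(before) == 0L) stop("empty signals")
  sqrt(mean((before - after)^2))
}

#' Build a labeled MFCC dataset from one filtered scene
#'
#' Extracts 39-dimensional MFCC rows from every frame between each segment's
#' start and end frame (inclusive) of the filtered waveform, labeling rows
#' with the segment label.
#'
#' @param scene A `scene_pair` (used for provenance).
#' @param filtered The denoised waveform features are extracted from.
#' @param method_id Method identifier recorded in the provenance.
#' @param segments Labeled `event_segments` (e.g. from
#'   [annotations_to_segments()]); an unlabeled segment is an error.
#' @param params A [frame_params()] object.
#' @param mfcc_cfg An [mfcc_config()] object.
#' @return A `labeled_dataset`: list with `features` (`[m x 39]`), `labels`
#'   (character) and `provenance` (data.frame scene/method/segment per row).
#' @export
build_dataset <- function(scene, filtered, method_id, segments,
                          params = frame_params(), mfcc_cfg = mfcc_config()) {
  if (nrow(segments) == 0L) {
    return(structure(list(features = matrix(numeric(0), 0, 3 * mfcc_cfg$n_ceps),
                          labels = character(0),
                          provenance = data.frame(scene = integer(0),
                                                  method = character(0),
                                                  segment = integer(0))),
                     class = "labeled_dataset"))
  }
  if (anyNA(segments$label)) stop("all segments must be labeled")
  feats <- mfcc_features(filtered, params, mfcc_cfg)
  rows <- list(); labs <- list(); prov <- list()
  for (s in seq_len(nrow(segments))) {
    if (segments$start_frame[s] > nrow(feats)) next
    fr <- segments$start_frame[s]:min(segments$end_frame[s], nrow(feats))
    rows[[s]] <- feats[fr, , drop = FALSE]
    labs[[s]] <- rep(segments$label[s], length(fr))
    prov[[s]] <- data.frame(scene = scene$seed, method = method_id,
                            segment = s)[rep(1, length(fr)), ]
  }
  structure(list(features = do.call(rbind, rows),
                 labels = unlist(labs),
                 provenance = do.call(rbind, prov)),
            class = "labeled_dataset")
}

#' Pool labeled datasets
#'
#' @param ... `labeled_dataset` objects (or a single list of them).
#' @return A pooled `labeled_dataset`.
#' @export
combine_datasets <- function(...) {
  ds <- list(...)
  if (length(ds) == 1L && !inherits(ds[[1]], "labeled_dataset")) ds <- ds[[1]]
  structure(list(features = do.call(rbind, lapply(ds, `[[`, "features")),
                 labels = unlist(lapply(ds, `[[`, "labels")),
                 provenance = do.call(rbind, lapply(ds, `[[`, "provenance"))),
            class = "labeled_dataset")
}

#' Per-class row counts of a labeled dataset
#'
#' @param ds A `labeled_dataset`.
#' @return One-row data.frame: one column per class plus `total`.
#' @export
dataset_summary <- function(ds) {
  classes <- c("crow", "cough", "purr", "flap")
  counts <- vapply(classes, function(k) sum(ds$labels == k), integer(1))
  out <- as.data.frame(as.list(counts))
  out$total <- length(ds$labels)
  out
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset:", length(x$labels), "rows x",
      ncol(x$features), "features\n")
  print(dataset_summary(x))
  invisible(x)
}

#' Repeated stratified kNN / random-forest evaluation
#'
#' For each repeat a stratified random train/test split (70/30 by default) is
#' drawn with that repeat's seed, a k-nearest-neighbour classifier (majority
#' vote, Euclidean metric, k = 5) and a random forest (100 trees) are fit
#' under fixed default settings, and test accuracy -- the fraction of test
#' rows whose predicted label equals the true label -- is recorded together
#' with the correct/incorrect counts.
#'
#' @param ds A `labeled_dataset` with at least two classes.
#' @param n_repeats Number of repeats (default 10).
#' @param train_frac Training fraction of each class.
#' @param seeds Integer seeds, one per repeat (default `1:n_repeats`).
#' @param k Number of neighbours for kNN.
#' @param n_trees Number of random-forest trees.
#' @return A `prediction_report`: `per_repeat` (data.frame repeat x classifier
#'   accuracies, percent), `summary` (per classifier: total/correct/incorrect
#'   test counts over all repeats and mean accuracy, percent).
#' @export
evaluate_classifiers <- function(ds, n_repeats = 10L, train_frac = 0.7,
                                 seeds = seq_len(n_repeats), k = 5L,
                                 n_trees = 100L) {
  labels <- factor(ds$labels)
  if (nlevels(labels) < 2L) stop("need at least two classes")
  counts <- table(labels)
  if (any(counts < 4L)) stop("need at least 4 rows per class for the split")
  X <- ds$features
  per_repeat <- data.frame(repeat_id = seq_len(n_repeats),
                           knn = NA_real_, rf = NA_real_)
  totals <- c(knn = 0L, rf = 0L)
  corrects <- c(knn = 0L, rf = 0L)
  for (r in seq_len(n_repeats)) {
    split <- withr::with_seed(as.integer(seeds[r]), {
      train_idx <- unlist(lapply(levels(labels), function(lv) {
        idx <- which(labels == lv)
        sample(idx, max(2L, round(train_frac * length(idx))))
      }))
      train_idx
    })
    test_idx <- setdiff(seq_along(labels), split)
    pred_knn <- withr::with_seed(as.integer(seeds[r]), {
      class::knn(X[split, , drop = FALSE], X[test_idx, , drop = FALSE],
                 labels[split], k = k)
    })
    rf <- withr::with_seed(as.integer(seeds[r]), {
      randomForest::randomForest(X[split, , drop = FALSE], labels[split],
                                 ntree = n_trees)
    })
    pred_rf <- stats::predict(rf, X[test_idx, , drop = FALSE])
    truth <- labels[test_idx]
    per_repeat$knn[r] <- 100 * mean(pred_knn == truth)
    per_repeat$rf[r] <- 100 * mean(pred_rf == truth)
    totals <- totals + length(test_idx)
    corrects <- corrects + c(knn = sum(pred_knn == truth),
                             rf = sum(pred_rf == truth))
  }
  summ <- data.frame(classifier = c("knn", "rf"),
                     total = as.integer(totals),
                     correct = as.integer(corrects),
                     incorrect = as.integer(totals - corrects),
                     accuracy = 100 * corrects / totals,
                     row.names = NULL)
  structure(list(per_repeat = per_repeat, summary = summ,
                 mean_accuracy = c(knn = mean(per_repeat$knn),
                                   rf = mean(per_repeat$rf))),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("prediction_report (accuracy %):\n")
  print(x$summary)
  invisible(x)
}

#' Apply one of the five denoising methods by identifier
#'
#' Identifiers: `bss` (basic spectral subtraction), `iss` (improved,
#' multitaper), `wf` (decision-directed Wiener), `sd30`/`sd50` (sparse
#' decomposition with 30/50 atoms per frame).
#'
#' @param x Noisy waveform.
#' @param method Method id.
#' @param params STFT [frame_params()] (spectral methods).
#' @param nis Leading noise-frame count.
#' @param sub_cfg [subtraction_config()] for `bss`/`iss`.
#' @param ga_cfg [ga_config()] for the sparse methods.
#' @param sparse_N Sparse-module frame length.
#' @return Denoised waveform.
#' @export
denoise <- function(x, method = c("bss", "iss", "wf", "sd30", "sd50"),
                    params = frame_params(), nis = nis_frames(0.5, params),
                    sub_cfg = subtraction_config(), ga_cfg = ga_config(),
                    sparse_N = 256L) {
  method <- match.arg(method)
  switch(method,
         bss = denoise_basic(x, sub_cfg, params, nis),
         iss = denoise_improved(x, sub_cfg, params, nis),
         wf = denoise_wiener(x, params, nis),
         sd30 = denoise_sparse(x, 30L, sparse_N, cfg = ga_cfg),
         sd50 = denoise_sparse(x, 50L, sparse_N, cfg = ga_cfg))
}

#' Run the full multi-perspective benchmark
#'
#' For every scene and method: denoise the noisy waveform, compute the SNR
#' against the known clean reference and the pre-vs-post RMSE; for the Wiener
#' method additionally compute both metrics after trimming the leading
#' transient (with the reference trimmed identically). Optionally build a
#' labeled MFCC dataset per method from the annotation-derived segments and
#' run the repeated kNN/random-forest protocol.
#'
#' @param scene_specs List of `scene_spec` objects (>= 1).
#' @param methods Character vector of method ids.
#' @param params STFT [frame_params()].
#' @param classifiers Run the recognition-angle evaluation (default TRUE).
#' @param n_repeats Classifier repeats.
#' @param classifier_seeds Integer seeds for the repeated splits (default
#'   `1:n_repeats`).
#' @param verbose Print progress.
#' @param ... Passed to [denoise()].
#' @return A `benchmark_report`: `signal` (per-scene SNR/RMSE per method plus
#'   a mean row, wide), `signal_mean`, `wiener_trimmed` (SNR/RMSE after
#'   trimming), `datasets` (per-method class-count summaries),
#'   `predictions` (per-method `prediction_report`s, if requested).
#' @export
run_benchmark <- function(scene_specs,
                          methods = c("bss", "iss", "wf", "sd30", "sd50"),
                          params = frame_params(), classifiers = TRUE,
                          n_repeats = 10L, classifier_seeds = seq_len(n_repeats),
                          verbose = FALSE, ...) {
  if (length(scene_specs) < 1L) stop("need at least one scene")
  n_sc <- length(scene_specs)
  snr_tab <- matrix(NA_real_, n_sc, length(methods),
                    dimnames = list(NULL, methods))
  rmse_tab <- snr_tab
  trim_snr <- numeric(n_sc)
  trim_rmse <- numeric(n_sc)
  datasets <- stats::setNames(vector("list", length(methods)), methods)
  for (si in seq_len(n_sc)) {
    scene <- generate_scene(scene_specs[[si]])
    nis <- nis_frames(scene$preamble_s, params)
    nf <- n_frames(length(scene$noisy), params)
    segs <- annotations_to_segments(scene$annotations, params, nf)
    for (m in methods) {
      if (verbose) message(sprintf("scene %d/%d: %s", si, n_sc, m))
      y <- denoise(scene$noisy, m, params = params, nis = nis, ...)
      snr_tab[si, m] <- snr_db(scene$clean, y)
      rmse_tab[si, m] <- rmse(scene$noisy, y)
      if (m == "wf") {
        yt <- trim_leading_transient(y, nis, params)
        ct <- trim_leading_transient(scene$clean, nis, params)
        nt <- trim_leading_transient(scene$noisy, nis, params)
        trim_snr[si] <- snr_db(ct, yt)
        trim_rmse[si] <- rmse(nt, yt)
      }
      if (classifiers) {
        d <- build_dataset(scene, y, m, segs, params)
        datasets[[m]] <- c(datasets[[m]], list(d))
      }
    }
  }
  signal <- data.frame(scene = seq_len(n_sc))
  for (m in methods) {
    signal[[paste0("snr_", m)]] <- snr_tab[, m]
    signal[[paste0("rmse_", m)]] <- rmse_tab[, m]
  }
  signal_mean <- colMeans(signal[, -1, drop = FALSE])
  predictions <- NULL
  ds_summaries <- NULL
  pooled <- NULL
  if (classifiers) {
    pooled <- lapply(datasets, combine_datasets)
    ds_summaries <- do.call(rbind, lapply(pooled, dataset_summary))
    ds_summaries <- cbind(method = methods, ds_summaries)
    rownames(ds_summaries) <- NULL
    predictions <- lapply(pooled, evaluate_classifiers, n_repeats = n_repeats,
                          seeds = classifier_seeds)
  }
  wt <- if ("wf" %in% methods) {
    data.frame(scene = seq_len(n_sc), snr_wf_trimmed = trim_snr,
               rmse_wf_trimmed = trim_rmse)
  } else NULL
  structure(list(signal = signal, signal_mean = signal_mean,
                 wiener_trimmed = wt, datasets = ds_summaries,
                 pooled_datasets = pooled,
                 predictions = predictions, methods = methods),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("benchmark_report over", nrow(x$signal), "scenes\n")
  cat("mean signal metrics:\n")
  print(round(x$signal_mean, 4))
  if (!is.null(x$wiener_trimmed)) {
    cat(sprintf("trimmed Wiener: mean SNR %.4f dB, mean RMSE %.4f\n",
                mean(x$wiener_trimmed$snr_wf_trimmed),
                mean(x$wiener_trimmed$rmse_wf_trimmed)))
  }
  if (!is.null(x$predictions)) {
    for (m in names(x$predictions)) {
      acc <- x$predictions[[m]]$mean_accuracy
      cat(sprintf("%s: kNN %.2f%%, RF %.2f%%\n", m, acc["knn"], acc["rf"]))
    }
  }
  invisible(x)
}
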