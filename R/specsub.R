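#' Estimate the noise profile from leading noise-only frames
#'
#' Averages the power `|X_i(k)|^2` and the amplitude `|X_i(k)|` of the first
#' `nis` frames, which by construction lie inside the noise-only preamble.
#'
#' @param spec A `spectral_frames` object from [stft()].
#' @param nis Number of leading noise frames (NIS); must not exceed the frame
#'   count.
#' @return A `noise_profile` object: list with `power` D(k), `mean_amplitude`,
#'   and `nis`.
#' @export
estimate_noise_power <- function(spec, nis) {
  nf <- nrow(spec$magnitude)
  nis <- as.integer(nis)
  if (nis < 1L) stop("nis must be >= 1")
  if (nis > nf) stop("nis exceeds the number of frames")
  mag <- spec$magnitude[seq_len(nis), , drop = FALSE]
  structure(list(power = colMeans(mag^2), mean_amplitude = colMeans(mag),
                 nis = nis),
            class = "noise_profile")
}

#' Configuration of the spectral-subtraction denoisers
#'
#' @param a Over-subtraction factor of basic spectral subtraction (> 0).
#' @param b Gain-compensation (spectral floor) factor of basic subtraction.
#' @param alpha Over-subtraction factor of the improved (multitaper) variant.
#' @param beta Gain-compensation factor of the improved variant.
#' @param M Smoothing half-width in frames; averaging runs over 2M+1 frames
#'   (M = 1, i.e. three frames, is the conventional choice).
#' @param L Number of Slepian tapers.
#' @param NW Time-bandwidth product of the taper family.
#' @return A `subtraction_config` object.
#' @export
subtraction_config <- function(a = 4, b = 0.001, alpha = 4, beta = 0.01,
                               M = 1L, L = 5L, NW = 3) {
  if (a < 0 || alpha <= 0) stop("over-subtraction factors must be positive")
  if (b < 0 || b >= 1 || beta < 0 || beta >= 1) {
    stop("compensation factors must lie in [0, 1)")
  }
  if (M < 0) stop("M must be >= 0")
  structure(list(a = a, b = b, alpha = alpha, beta = beta,
                 M = as.integer(M), L = as.integer(L), NW = NW),
            class = "subtraction_config")
}

#' Basic power spectral subtraction rule
#'
#' Applies the two-branch rule: where the frame power exceeds `a` times the
#' noise power it is reduced by that amount, elsewhere it is floored at `b`
#' times the frame power.
#'
#' @param power Per-frame power matrix `[n_frames x N]` (or a vector for one
#'   frame), all values >= 0.
#' @param profile A [estimate_noise_power()] result.
#' @param a Over-subtraction factor (> 0 allowed to be 0 for the identity).
#' @param b Gain-compensation factor (>= 0).
#' @return Subtracted power, same shape as `power`, non-negative.
#' @export
subtract_basic <- function(power, profile, a = 4, b = 0.001) {
  if (any(power < 0)) stop("power must be non-negative")
  if (a < 0 || b < 0) stop("a and b must be non-negative")
  vec <- is.null(dim(power))
  if (vec) power <- matrix(power, nrow = 1L)
  sub <- sweep(power, 2L, a * profile$power, `-`)
  out <- ifelse(sub >= 0, sub, b * power)
  if (vec) out <- drop(out)
  out
}

#' Denoise by basic spectral subtraction
#'
#' STFT analysis, noise power estimation from the first `nis` frames,
#' power-domain subtraction, and overlap-add resynthesis using the noisy
#' phase.
#'
#' @param x Noisy waveform.
#' @param cfg A [subtraction_config()] (uses `a`, `b`).
#' @param params A [frame_params()] object.
#' @param nis Number of leading noise frames; default assumes a 0.5 s
#'   preamble.
#' @param profile Optional precomputed [estimate_noise_power()] result;
#'   estimated from `x` when `NULL`.
#' @return Denoised waveform, same length as `x`.
#' @export
denoise_basic <- function(x, cfg = subtraction_config(),
                          params = frame_params(),
                          nis = nis_frames(0.5, params), profile = NULL) {
  spec <- stft(x, params)
  if (is.null(profile)) profile <- estimate_noise_power(spec, nis)
  p_hat <- subtract_basic(spec$magnitude^2, profile, cfg$a, cfg$b)
  spec$magnitude <- sqrt(p_hat)
  synthesize(spec, length_out = length(x))
}

.taper_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `L` unit-norm, mutually orthogonal Slepian sequences of
#' length `N` with half-bandwidth `W = NW/N`, via the eigenvectors of the
#' classical symmetric tridiagonal operator that commutes with the spectral
#' concentration kernel. Results are cached per `(N, NW, L)`.
#'
#' @param N Sequence length.
#' @param NW Time-bandwidth product (typical 2-4).
#' @param L Number of tapers to return; the usual recommendation is
#'   `L <= 2*NW - 1`.
#' @return A `taper_set` object: list with `tapers` (`[L x N]`, rows are the
#'   sequences), `NW`, `N`.
#' @export
slepian_tapers <- function(N, NW = 3, L = 5L) {
  N <- as.integer(N)
  L <- as.integer(L)
  if (L > N) stop("cannot request more tapers than the sequence length")
  if (L < 1L) stop("L must be >= 1")
  if (L > 2 * NW - 1) {
    warning("L > 2*NW - 1: higher-order tapers are poorly concentrated")
  }
  key <- sprintf("N%d_NW%g_L%d", N, NW, L)
  if (!is.null(.taper_cache[[key]])) return(.taper_cache[[key]])
  W <- NW / N
  t <- 0:(N - 1)
  A <- matrix(0, N, N)
  diag(A) <- ((N - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
  off <- t[-1] * (N - t[-1]) / 2
  A[cbind(2:N, 1:(N - 1))] <- off
  A[cbind(1:(N - 1), 2:N)] <- off
  eg <- eigen(A, symmetric = TRUE)
  tap <- t(eg$vectors[, seq_len(L), drop = FALSE])
  # polarity convention: each taper positive at its largest-magnitude sample
  for (k in seq_len(L)) {
    if (tap[k, which.max(abs(tap[k, ]))] < 0) tap[k, ] <- -tap[k, ]
  }
  out <- structure(list(tapers = tap, NW = NW, N = N), class = "taper_set")
  .taper_cache[[key]] <- out
  out
}

#' Multitaper power spectral density of one frame
#'
#' Averages the `L` single-taper periodograms `|DFT(a_k * x)|^2`; with
#' orthogonal tapers this cuts the estimator variance by roughly `1/L`
#' relative to a single-window periodogram, which is what suppresses musical
#' noise in the improved subtraction.
#'
#' @param frame Numeric vector of length `N` (unwindowed frame).
#' @param tapers A [slepian_tapers()] result with matching `N`.
#' @return Non-negative PSD vector of length `N` (two-sided).
#' @export
multitaper_psd <- function(frame, tapers) {
  if (length(frame) != tapers$N) stop("frame length does not match taper length")
  tap <- tapers$tapers
  acc <- numeric(tapers$N)
  for (k in seq_len(nrow(tap))) {
    acc <- acc + Mod(stats::fft(tap[k, ] * frame))^2
  }
  acc / nrow(tap)
}

# multitaper PSD of every row of a frame matrix (vectorized over frames)
multitaper_psd_frames <- function(frames, tapers) {
  tap <- tapers$tapers
  acc <- matrix(0, nrow(frames), ncol(frames))
  tf <- t(frames)
  for (k in seq_len(nrow(tap))) {
    acc <- acc + t(Mod(stats::mvfft(tap[k, ] * tf))^2)
  }
  acc / nrow(tap)
}

#' Moving average across frames
#'
#' Centered moving average over `2M+1` frames applied independently per bin;
#' boundary frames use truncated windows renormalized by the actual frame
#' count.
#'
#' @param series Matrix `[n_frames x K]` (or vector treated as one-bin
#'   series).
#' @param M Half-width in frames; `M = 0` is the identity.
#' @return Smoothed series, same shape.
#' @export
smooth_frames <- function(series, M = 1L) {
  M <- as.integer(M)
  if (M < 0) stop("M must be >= 0")
  vec <- is.null(dim(series))
  if (vec) series <- matrix(series, ncol = 1L)
  if (M == 0L) return(if (vec) drop(series) else series)
  nf <- nrow(series)
  acc <- matrix(0, nf, ncol(series))
  cnt <- numeric(nf)
  for (j in -M:M) {
    src <- seq_len(nf) + j
    ok <- src >= 1L & src <= nf
    acc[ok, ] <- acc[ok, ] + series[src[ok], , drop = FALSE]
    cnt[ok] <- cnt[ok] + 1
  }
  out <- acc / cnt
  if (vec) drop(out) else out
}

#' Gain of improved spectral subtraction
#'
#' Two-branch gain computed from the smoothed noisy PSD and the noise PSD:
#' `(Py - alpha*Pn)/Py` where non-negative, else `beta*Pn/Py`. Bins with
#' `Py = 0` get gain 0.
#'
#' @param Py Smoothed noisy PSD (matrix `[n_frames x N]` or vector).
#' @param Pn Noise PSD vector (length N, recycled across frames).
#' @param alpha Over-subtraction factor.
#' @param beta Gain-compensation factor.
#' @return Non-negative gain, same shape as `Py`.
#' @export
improved_gain <- function(Py, Pn, alpha = 4, beta = 0.01) {
  vec <- is.null(dim(Py))
  if (vec) Py <- matrix(Py, nrow = 1L)
  sub <- sweep(Py, 2L, alpha * Pn, `-`)
  flo <- sweep(1 / pmax(Py, .Machine$double.xmin), 2L, beta * Pn, `*`)
  g <- ifelse(sub >= 0, sub / pmax(Py, .Machine$double.xmin), flo)
  g[Py == 0] <- 0
  if (vec) drop(g) else g
}

#' Denoise by improved spectral subtraction (multitaper)
#'
#' Pipeline: STFT magnitude/phase; 3-frame amplitude smoothing; per-frame
#' multitaper PSD (Slepian tapers applied to the unwindowed frames, since the
#' tapers are themselves the analysis windows); 3-frame PSD smoothing; noise
#' PSD from the first `nis` smoothed frames; two-branch gain; subtracted
#' amplitude `g * |Xbar|`; resynthesis with the original noisy phase.
#'
#' @inheritParams denoise_basic
#' @param cfg A [subtraction_config()] (uses `alpha`, `beta`, `M`, `L`, `NW`).
#' @return Denoised waveform, same length as `x`.
#' @export
denoise_improved <- function(x, cfg = subtraction_config(),
                             params = frame_params(),
                             nis = nis_frames(0.5, params)) {
  spec <- stft(x, params)
  nf <- nrow(spec$magnitude)
  if (nis > nf) stop("nis exceeds the number of frames")
  xbar <- smooth_frames(spec$magnitude, cfg$M)
  raw_params <- frame_params(params$frame_len, params$hop, "rectangular",
                             params$sample_rate)
  raw_frames <- frame_signal(x, raw_params)
  tapers <- slepian_tapers(params$frame_len, cfg$NW, cfg$L)
  P <- multitaper_psd_frames(raw_frames, tapers)
  Py <- smooth_frames(P, cfg$M)
  Pn <- colMeans(Py[seq_len(nis), , drop = FALSE])
  g <- improved_gain(Py, Pn, cfg$alpha, cfg$beta)
  spec$magnitude <- g * xbar
  synthesize(spec, length_out = length(x))
}
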