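#' Framing parameters for short-time analysis
#'
#' Bundles the frame length, hop, analysis window and sample rate used by all
#' frequency-domain methods in the package. Defaults are 25 ms frames with 50%
#' overlap at 32 kHz and a Hamming window, the usual speech-processing choice.
#'
#' @param frame_len Frame length N in samples.
#' @param hop Hop size in samples; must satisfy `0 < hop <= frame_len`.
#' @param window One of `"hamming"`, `"hanning"`, `"rectangular"`.
#' @param sample_rate Sampling frequency in Hz.
#' @return An object of class `frame_params`.
#' @export
#' @examples
#' p <- frame_params()
#' p$frame_len
frame_params <- function(frame_len = 800L, hop = 400L,
                         window = c("hamming", "hanning", "rectangular"),
                         sample_rate = 32000) {
  window <- match.arg(window)
  frame_len <- as.integer(frame_len)
  hop <- as.integer(hop)
  if (frame_len <= 0L) stop("frame_len must be positive")
  if (hop <= 0L || hop > frame_len) stop("hop must satisfy 0 < hop <= frame_len")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  structure(list(frame_len = frame_len, hop = hop, window = window,
                 sample_rate = sample_rate),
            class = "frame_params")
}

#' @export
print.frame_params <- function(x, ...) {
  cat(sprintf("frame_params: N=%d, hop=%d, %s window, fs=%g Hz (%.1f ms frames)\n",
              x$frame_len, x$hop, x$window, x$sample_rate,
              1000 * x$frame_len / x$sample_rate))
  invisible(x)
}

window_vector <- function(params) {
  N <- params$frame_len
  switch(params$window,
         hamming = as.numeric(signal::hamming(N)),
         hanning = as.numeric(signal::hanning(N)),
         rectangular = rep(1, N))
}

#' Number of analysis frames for a signal length
#'
#' @param n_samples Signal length in samples.
#' @param params A [frame_params()] object.
#' @return Integer frame count `floor((n - N)/hop) + 1`.
#' @export
n_frames <- function(n_samples, params) {
  if (n_samples < params$frame_len) stop("signal shorter than one frame")
  as.integer((n_samples - params$frame_len) %/% params$hop + 1L)
}

#' Slice a waveform into windowed frames
#'
#' Row i of the result is `window * x[(i-1)*hop + 1:N]`; trailing samples that
#' do not fill a frame are dropped.
#'
#' @param x Numeric waveform.
#' @param params A [frame_params()] object.
#' @return Numeric matrix `[n_frames x frame_len]`.
#' @export
frame_signal <- function(x, params) {
  N <- params$frame_len
  hop <- params$hop
  nf <- n_frames(length(x), params)
  idx <- outer((seq_len(nf) - 1L) * hop, seq_len(N), `+`)
  frames <- matrix(x[idx], nrow = nf, ncol = N)
  sweep(frames, 2L, window_vector(params), `*`)
}

#' Per-frame Fourier analysis
#'
#' Computes the full-length (two-sided) DFT of each frame and returns its
#' modulus and phase angle. The pair (magnitude, phase) is the currency of all
#' spectral denoisers in the package; phase is retained untouched so that every
#' method can resynthesize with the noisy phase.
#'
#' @param frames Windowed frame matrix from [frame_signal()].
#' @param params The [frame_params()] used to produce `frames`.
#' @return An object of class `spectral_frames` with elements `magnitude` and
#'   `phase` (both `[n_frames x frame_len]`) and `params`.
#' @export
analyze <- function(frames, params) {
  if (!is.matrix(frames) || nrow(frames) < 1L) stop("frames must be a nonempty matrix")
  if (ncol(frames) != params$frame_len) stop("frame width does not match params")
  X <- stats::mvfft(t(frames))          # columns = frames
  structure(list(magnitude = t(Mod(X)), phase = t(Arg(X)), params = params),
            class = "spectral_frames")
}

#' @export
print.spectral_frames <- function(x, ...) {
  cat(sprintf("spectral_frames: %d frames x %d bins\n",
              nrow(x$magnitude), ncol(x$magnitude)))
  invisible(x)
}

#' Short-time analysis of a waveform
#'
#' Convenience composition of [frame_signal()] and [analyze()].
#' @inheritParams frame_signal
#' @return A `spectral_frames` object.
#' @export
stft <- function(x, params) analyze(frame_signal(x, params), params)

#' Overlap-add resynthesis from magnitude and phase
#'
#' Per-frame inverse DFT followed by window-compensated overlap-add: the output
#' is `sum_i w * xhat_i / sum_i w^2`, with the denominator floored at 1e-12.
#' For unmodified spectra this reproduces the input exactly (including edges),
#' since the analysis window appears once in `xhat_i` and once in the
#' compensation numerator.
#'
#' @param spec A `spectral_frames` object (possibly with modified magnitude).
#' @param length_out Optional output length; shorter output is zero-padded,
#'   longer output truncated. Defaults to the natural OLA length.
#' @return Numeric waveform.
#' @export
synthesize <- function(spec, length_out = NULL) {
  mag <- spec$magnitude
  ph <- spec$phase
  if (!all(dim(mag) == dim(ph))) stop("magnitude/phase shape mismatch")
  params <- spec$params
  N <- params$frame_len
  hop <- params$hop
  nf <- nrow(mag)
  w <- window_vector(params)
  X <- t(mag) * exp(1i * t(ph))                   # N x nf
  xi <- Re(stats::mvfft(X, inverse = TRUE)) / N   # framed (already windowed) signal
  n_out <- (nf - 1L) * hop + N
  num <- numeric(n_out)
  den <- numeric(n_out)
  for (i in seq_len(nf)) {
    pos <- (i - 1L) * hop + seq_len(N)
    num[pos] <- num[pos] + w * xi[, i]
    den[pos] <- den[pos] + w * w
  }
  out <- num / pmax(den, 1e-12)
  if (!is.null(length_out)) {
    if (length_out <= n_out) out <- out[seq_len(length_out)]
    else out <- c(out, numeric(length_out - n_out))
  }
  out
}
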