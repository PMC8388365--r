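#' Frequency to mel scale
#'
#' `mel = 2595 * log10(1 + f/700)`.
#'
#' @param f Frequency in Hz (>= 0).
#' @return Mel value(s).
#' @export
hz_to_mel <- function(f) {
  if (any(f < 0)) stop("frequency must be non-negative")
  2595 * log10(1 + f / 700)
}

#' Mel scale to frequency
#'
#' Inverse of [hz_to_mel()]: `f = 700 * (10^(mel/2595) - 1)`.
#'
#' @param mel Mel value(s) (>= 0).
#' @return Frequency in Hz.
#' @export
mel_to_hz <- function(mel) {
  if (any(mel < 0)) stop("mel value must be non-negative")
  700 * (10^(mel / 2595) - 1)
}

#' MFCC extraction configuration
#'
#' Conventional values: 26 triangular mel filters between 20 Hz and 16 kHz,
#' 13 kept cepstral coefficients (DCT terms 1..13, excluding the 0th energy
#' term), pre-emphasis 0.97, delta regression half-width 2 frames.
#'
#' @param n_filters Number of mel filterbank bands.
#' @param n_ceps Number of kept cepstral coefficients.
#' @param pre_emphasis Pre-emphasis coefficient in \[0, 1).
#' @param delta_window Regression half-width (frames) for the differences.
#' @param fmin,fmax Filterbank edge frequencies in Hz.
#' @param log_floor Floor applied inside the log to keep coefficients finite.
#' @return An `mfcc_config` object.
#' @export
mfcc_config <- function(n_filters = 26L, n_ceps = 13L, pre_emphasis = 0.97,
                        delta_window = 2L, fmin = 20, fmax = 16000,
                        log_floor = 1e-10) {
  if (n_ceps > n_filters) stop("n_ceps must not exceed n_filters")
  if (pre_emphasis < 0 || pre_emphasis >= 1) stop("pre_emphasis must be in [0, 1)")
  structure(list(n_filters = as.integer(n_filters), n_ceps = as.integer(n_ceps),
                 pre_emphasis = pre_emphasis, delta_window = as.integer(delta_window),
                 fmin = fmin, fmax = fmax, log_floor = log_floor),
            class = "mfcc_config")
}

#' Triangular mel filterbank matrix
#'
#' `n_filters` triangles equally spaced on the mel scale between `fmin` and
#' `fmax`, evaluated at the one-sided FFT bin centers.
#'
#' @param cfg An [mfcc_config()] object.
#' @param N FFT length (frame length).
#' @param sample_rate Sampling frequency in Hz.
#' @return Matrix `[n_filters x (N/2 + 1)]`.
#' @export
mel_filterbank <- function(cfg, N, sample_rate) {
  if (cfg$fmax > sample_rate / 2) stop("fmax exceeds the Nyquist frequency")
  n_bins <- N %/% 2 + 1L
  bin_hz <- (seq_len(n_bins) - 1L) * sample_rate / N
  edges_hz <- mel_to_hz(seq(hz_to_mel(cfg$fmin), hz_to_mel(cfg$fmax),
                            length.out = cfg$n_filters + 2L))
  fb <- matrix(0, cfg$n_filters, n_bins)
  for (m in seq_len(cfg$n_filters)) {
    lo <- edges_hz[m]; cen <- edges_hz[m + 1L]; hi <- edges_hz[m + 2L]
    up <- (bin_hz - lo) / (cen - lo)
    down <- (hi - bin_hz) / (hi - cen)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# orthonormal DCT-II matrix selecting coefficients 1..n_ceps (0th excluded)
dct_matrix <- function(n_ceps, n_filters) {
  k <- seq_len(n_ceps)                     # DCT terms 1..n_ceps
  m <- seq_len(n_filters) - 0.5
  sqrt(2 / n_filters) * cos(pi / n_filters * outer(k, m))
}

#' Static 13-dimensional MFCCs
#'
#' Pre-emphasis, framing/windowing, one-sided power spectrum, triangular mel
#' filterbank, log (floored), orthonormal DCT-II, keeping coefficients 1..13.
#' The 0th (energy) coefficient is excluded, which makes the static
#' coefficients invariant to an overall amplitude scaling.
#'
#' @param x Waveform.
#' @param params A [frame_params()] object.
#' @param cfg An [mfcc_config()] object.
#' @return Matrix `[n_frames x n_ceps]`.
#' @export
mfcc_static <- function(x, params = frame_params(), cfg = mfcc_config()) {
  if (cfg$pre_emphasis > 0) {
    x <- c(x[1], x[-1] - cfg$pre_emphasis * x[-length(x)])
  }
  frames <- frame_signal(x, params)
  N <- params$frame_len
  n_bins <- N %/% 2 + 1L
  P <- t(Mod(stats::mvfft(t(frames)))^2)[, seq_len(n_bins), drop = FALSE]
  fb <- mel_filterbank(cfg, N, params$sample_rate)
  loge <- log(pmax(P %*% t(fb), cfg$log_floor))
  D <- dct_matrix(cfg$n_ceps, cfg$n_filters)
  loge %*% t(D)
}

#' Append first- and second-order differences
#'
#' Regression deltas over `+/- delta_window` frames with replicated edge
#' padding; the second-order difference is the delta of the delta. Columns are
#' `[static | delta | delta-delta]`, tripling the width (13 -> 39 with the
#' defaults).
#'
#' @param static Matrix `[T x n_ceps]` of static coefficients.
#' @param delta_window Regression half-width in frames.
#' @return Matrix `[T x 3*n_ceps]`.
#' @export
add_deltas <- function(static, delta_window = 2L) {
  if (is.null(dim(static))) static <- matrix(static, nrow = 1L)
  W <- as.integer(delta_window)
  delta_of <- function(m) {
    T <- nrow(m)
    pad <- rbind(m[rep(1L, W), , drop = FALSE], m, m[rep(T, W), , drop = FALSE])
    num <- matrix(0, T, ncol(m))
    for (d in seq_len(W)) {
      num <- num + d * (pad[W + seq_len(T) + d, , drop = FALSE] -
                        pad[W + seq_len(T) - d, , drop = FALSE])
    }
    num / (2 * sum(seq_len(W)^2))
  }
  d1 <- delta_of(static)
  d2 <- delta_of(d1)
  cbind(static, d1, d2)
}

#' Full 39-dimensional MFCC features
#'
#' @inheritParams mfcc_static
#' @return Matrix `[n_frames x 39]` with column names
#'   `c1..c13, d1..d13, dd1..dd13`.
#' @export
mfcc_features <- function(x, params = frame_params(), cfg = mfcc_config()) {
  out <- add_deltas(mfcc_static(x, params, cfg), cfg$delta_window)
  nc <- cfg$n_ceps
  colnames(out) <- c(paste0("c", seq_len(nc)), paste0("d", seq_len(nc)),
                     paste0("dd", seq_len(nc)))
  out
}
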