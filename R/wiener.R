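#' Initialize Wiener noise statistics from the preamble
#'
#' The average noise power spectral density `lambda_d(k)` and the mean noise
#' amplitude are estimated from the first `nis` frames; the previous-frame
#' prior SNR starts at zero.
#'
#' @param spec A `spectral_frames` object.
#' @param nis Number of leading noise frames.
#' @param alpha_dd Decision-directed smoothing constant in \[0, 1).
#' @return A `wiener_state` object: `lambda_d`, `noise_amp`, `xi_prev`,
#'   `alpha_dd`.
#' @export
init_noise_stats <- function(spec, nis, alpha_dd = 0.98) {
  prof <- estimate_noise_power(spec, nis)
  structure(list(lambda_d = prof$power, noise_amp = prof$mean_amplitude,
                 xi_prev = numeric(length(prof$power)), alpha_dd = alpha_dd),
            class = "wiener_state")
}

#' Posterior SNR
#'
#' `gamma = |Y|^2 / lambda_d`, with the noise power floored at 1e-12 so the
#' ratio stays finite.
#'
#' @param Y_power Per-bin noisy power `|Y_i(k)|^2`.
#' @param lambda_d Noise power vector.
#' @return Posterior SNR, same shape as `Y_power`.
#' @export
posterior_snr <- function(Y_power, lambda_d) {
  Y_power / pmax(lambda_d, 1e-12)
}

#' Decision-directed prior SNR
#'
#' `xi_hat = alpha * xi_prev + (1 - alpha) * max(gamma - 1, 0)`. The flooring
#' of `gamma - 1` at zero keeps the prior SNR non-negative.
#'
#' @param gamma Posterior SNR (vector).
#' @param xi_prev Previous-frame prior SNR (vector).
#' @param alpha_dd Smoothing constant in \[0, 1\].
#' @return Prior SNR estimate, non-negative.
#' @export
prior_snr_dd <- function(gamma, xi_prev, alpha_dd = 0.98) {
  alpha_dd * xi_prev + (1 - alpha_dd) * pmax(gamma - 1, 0)
}

#' Wiener gain from the prior SNR
#'
#' `H = xi_hat / (xi_hat + 1)`, always in \[0, 1).
#'
#' @param xi_hat Prior SNR estimate (>= 0).
#' @return Gain vector.
#' @export
wiener_gain <- function(xi_hat) {
  xi_hat / (xi_hat + 1)
}

#' Denoise by decision-directed Wiener filtering
#'
#' Frames are first classified as sound or noise by energy-based endpoint
#' detection ([detect_events()]); on noise-classified frames the noise power
#' and amplitude statistics are updated by exponential averaging
#' (`lambda_d <- 0.9 lambda_d + 0.1 |Y|^2`). On every frame the posterior SNR,
#' decision-directed prior SNR and gain `H = xi/(xi+1)` are computed, the
#' magnitude is scaled by `H`, and the signal is resynthesized with the noisy
#' phase. The running prior uses `xi_prev = H^2 * gamma`, i.e.
#' `|S|^2 / lambda_d` of the filtered frame.
#'
#' @param x Noisy waveform.
#' @param params A [frame_params()] object.
#' @param nis Number of leading noise frames.
#' @param alpha_dd Decision-directed smoothing constant.
#' @param update_rate Exponential-averaging weight of the current frame in the
#'   noise-statistic update.
#' @return Denoised waveform, same length as `x`.
#' @export
denoise_wiener <- function(x, params = frame_params(),
                           nis = nis_frames(0.5, params),
                           alpha_dd = 0.98, update_rate = 0.1) {
  spec <- stft(x, params)
  nf <- nrow(spec$magnitude)
  if (nis + 1L > nf) stop("signal must cover at least nis + 1 frames")
  state <- init_noise_stats(spec, nis, alpha_dd)
  segs <- detect_events(x, params, nis)
  sound <- segment_frame_mask(segs, nf)
  out_mag <- spec$magnitude
  lambda_d <- state$lambda_d
  noise_amp <- state$noise_amp
  xi_prev <- state$xi_prev
  for (i in seq_len(nf)) {
    Y2 <- spec$magnitude[i, ]^2
    if (!sound[i]) {
      lambda_d <- (1 - update_rate) * lambda_d + update_rate * Y2
      noise_amp <- (1 - update_rate) * noise_amp + update_rate * spec$magnitude[i, ]
    }
    gamma <- posterior_snr(Y2, lambda_d)
    xi_hat <- prior_snr_dd(gamma, xi_prev, alpha_dd)
    H <- wiener_gain(xi_hat)
    out_mag[i, ] <- H * spec$magnitude[i, ]
    xi_prev <- H^2 * gamma
  }
  spec$magnitude <- out_mag
  synthesize(spec, length_out = length(x))
}

#' Trim the leading transient of a filtered waveform
#'
#' The decision-directed estimator is unconverged over the first frames, which
#' leaves audible warm-up noise at the start of the Wiener output. This
#' removes the span covered exclusively by the first `nis` frames,
#' `nis*hop + N - hop` samples; paired metric computations must trim the same
#' span from the clean reference.
#'
#' @param x_filtered Filtered waveform.
#' @param nis Number of leading noise frames (0 = identity).
#' @param params A [frame_params()] object.
#' @return The waveform with the leading span removed.
#' @export
trim_leading_transient <- function(x_filtered, nis, params = frame_params()) {
  nis <- as.integer(nis)
  if (nis == 0L) return(x_filtered)
  trim <- nis * params$hop + params$frame_len - params$hop
  if (trim >= length(x_filtered)) stop("trim span covers the whole signal")
  x_filtered[-seq_len(trim)]
}
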