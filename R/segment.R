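#' Per-frame energy
#'
#' Sum of squares of each windowed frame.
#'
#' @param x Waveform.
#' @param params A [frame_params()] object.
#' @return Numeric vector of length `n_frames`.
#' @export
frame_energy <- function(x, params = frame_params()) {
  rowSums(frame_signal(x, params)^2)
}

#' Energy-based pulse extraction / endpoint detection
#'
#' The detection threshold is 1.5 times (by default) the mean per-frame energy
#' of the first `nis` (leading noise-segment) frames. Contiguous runs of
#' frames above threshold are events; runs separated by gaps of at most
#' `hangover_frames` are merged, and events shorter than `min_len_frames` are
#' dropped.
#'
#' @param x Waveform.
#' @param params A [frame_params()] object.
#' @param nis Number of leading noise frames used for the threshold (>= 1).
#' @param threshold_factor Multiplier on the mean preamble frame energy.
#' @param min_len_frames Minimum event length in frames.
#' @param hangover_frames Maximum below-threshold gap merged into an event.
#' @return A data.frame of class `event_segments` with columns `start_frame`,
#'   `end_frame` (1-based, inclusive) and `label` (NA), ordered by start.
#' @export
detect_events <- function(x, params = frame_params(),
                          nis = nis_frames(0.5, params),
                          threshold_factor = 1.5,
                          min_len_frames = 3L, hangover_frames = 2L) {
  e <- frame_energy(x, params)
  nis <- as.integer(nis)
  if (nis < 1L) stop("nis must be >= 1")
  if (nis > length(e)) stop("nis exceeds the number of frames")
  thr <- threshold_factor * mean(e[seq_len(nis)])
  mask <- e > thr
  # merge gaps <= hangover_frames
  r <- rle(mask)
  if (hangover_frames > 0L && length(r$lengths) > 2L) {
    interior <- seq_along(r$values)[-c(1L, length(r$values))]
    fill <- interior[!r$values[interior] & r$lengths[interior] <= hangover_frames]
    r$values[fill] <- TRUE
    mask <- inverse.rle(r)
    r <- rle(mask)
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len_frames
  segs <- data.frame(start_frame = starts[keep], end_frame = ends[keep],
                     label = rep(NA_character_, sum(keep)),
                     stringsAsFactors = FALSE)
  class(segs) <- c("event_segments", "data.frame")
  segs
}

#' Per-frame sound/noise mask from segments
#'
#' @param segs An `event_segments` data.frame.
#' @param nf Total number of frames.
#' @return Logical vector: TRUE for frames inside any event ("sound").
#' @export
segment_frame_mask <- function(segs, nf) {
  mask <- logical(nf)
  for (i in seq_len(nrow(segs))) {
    mask[segs$start_frame[i]:min(segs$end_frame[i], nf)] <- TRUE
  }
  mask
}

#' Convert sample-level annotations to labeled frame segments
#'
#' A frame belongs to an event when its center lies inside the event's sample
#' range. Used to turn generator ground truth into the labeled segments that
#' feed dataset construction, and to score detected boundaries.
#'
#' @param annotations Data.frame with `kind`, `start_sample`, `end_sample`
#'   (1-based inclusive), as produced by [generate_scene()].
#' @param params A [frame_params()] object.
#' @param nf Total number of frames available.
#' @return An `event_segments` data.frame with `label` filled in.
#' @export
annotations_to_segments <- function(annotations, params, nf) {
  N <- params$frame_len
  hop <- params$hop
  centers <- (seq_len(nf) - 1L) * hop + N / 2
  segs <- do.call(rbind, lapply(seq_len(nrow(annotations)), function(i) {
    inside <- which(centers >= annotations$start_sample[i] &
                    centers <= annotations$end_sample[i])
    if (length(inside) == 0L) return(NULL)
    data.frame(start_frame = min(inside), end_frame = max(inside),
               label = annotations$kind[i], stringsAsFactors = FALSE)
  }))
  if (is.null(segs)) {
    segs <- data.frame(start_frame = integer(0), end_frame = integer(0),
                       label = character(0), stringsAsFactors = FALSE)
  }
  class(segs) <- c("event_segments", "data.frame")
  segs
}

#' Write event segments to CSV
#'
#' @param segs An `event_segments` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_segments_csv <- function(segs, path) {
  utils::write.csv(as.data.frame(segs), path, row.names = FALSE)
  invisible(path)
}
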