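#' Write a mono waveform to a WAV file
#'
#' Supports 16-bit PCM and 32-bit IEEE float encodings. Float samples are
#' written as-is; PCM samples are clipped to \[-1, 1\] and quantized.
#' Quantization happens only at this boundary: the whole pipeline runs on
#' float waveforms.
#'
#' @param x Numeric waveform in \[-1, 1\].
#' @param path Output file path.
#' @param sample_rate Sampling frequency in Hz.
#' @param format `"float32"` (default) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, sample_rate = 32000,
                      format = c("float32", "pcm16")) {
  format <- match.arg(format)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x)
  bits <- if (format == "pcm16") 16L else 32L
  bytes_per <- bits %/% 8L
  data_size <- n * bytes_per
  audio_fmt <- if (format == "pcm16") 1L else 3L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(audio_fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                  # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "pcm16") {
    q <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Reads 16-bit PCM or 32-bit IEEE float mono files written by [write_wav()]
#' (and standard files of those encodings); multi-channel files are averaged
#' to mono.
#'
#' @param path WAV file path.
#' @return Numeric waveform with attribute `"sample_rate"`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (riff != "RIFF") stop("not a RIFF/WAVE file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (readChar(con, 4, useBytes = TRUE) != "WAVE") stop("not a WAVE file")
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk found")
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_fmt = sum(as.integer(raw[1:2]) * c(1, 256)),
        channels = sum(as.integer(raw[3:4]) * c(1, 256)),
        sample_rate = sum(as.integer(raw[5:8]) * 256^(0:3)),
        bits = sum(as.integer(raw[15:16]) * c(1, 256)))
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt chunk")
      x <- if (fmt$audio_fmt == 1L && fmt$bits == 16L) {
        readBin(con, "integer", size %/% 2, size = 2, signed = TRUE,
                endian = "little") / 32767
      } else if (fmt$audio_fmt == 3L && fmt$bits == 32L) {
        readBin(con, "numeric", size %/% 4, size = 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (need PCM16 or float32)")
      }
      if (fmt$channels > 1L) {
        x <- colMeans(matrix(x, nrow = fmt$channels))
      }
      attr(x, "sample_rate") <- fmt$sample_rate
      return(x)
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
  }
}

#' Write scene annotations to CSV
#'
#' Columns `kind`, `start_sample`, `end_sample` (1-based inclusive).
#'
#' @param annotations Annotation data.frame from [generate_scene()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations_csv <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a scene specification to JSON or YAML
#'
#' @param spec A `scene_spec` object.
#' @param path Output path; format chosen by extension (`.json`, `.yaml`,
#'   `.yml`).
#' @return `path`, invisibly.
#' @export
write_scene_spec <- function(spec, path) {
  obj <- list(duration_s = spec$duration_s, sample_rate = spec$sample_rate,
              preamble_s = spec$preamble_s, seed = spec$seed,
              allow_overlap = spec$allow_overlap,
              noise = unclass(spec$noise),
              events = lapply(spec$events, function(e) {
                list(kind = e$kind, onset_s = e$onset_s,
                     duration_s = e$duration_s, level = e$level,
                     shape = e$shape)
              }))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path, precision = 17L)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a scene specification from JSON or YAML
#'
#' @param path Path written by [write_scene_spec()] (or hand-authored in the
#'   same layout).
#' @return A `scene_spec` object.
#' @export
read_scene_spec <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  events <- lapply(obj$events, function(e) {
    event_spec(e$kind, e$onset_s, e$duration_s, e$level,
               shape = lapply(e$shape %||% list(), unlist))
  })
  scene_spec(duration_s = obj$duration_s, events = events,
             noise = noise_spec(obj$noise$stationary_kind,
                                obj$noise$impulsive_rate,
                                obj$noise$target_snr_db),
             sample_rate = obj$sample_rate, preamble_s = obj$preamble_s,
             seed = obj$seed, allow_overlap = isTRUE(obj$allow_overlap))
}
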