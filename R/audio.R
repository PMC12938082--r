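#' Mono audio recording
#'
#' Lightweight container for a single-channel waveform, the unit every stage
#' of the pipeline consumes. Auscultation recordings are expected at 44.1 kHz;
#' other rates are accepted but the segmentation and featurization defaults
#' assume 44100 Hz.
#'
#' @param samples numeric vector of finite sample values.
#' @param sample_rate sampling rate in Hz (default 44100).
#' @return an object of class `audio_recording` with elements `samples` and
#'   `sample_rate`.
#' @export
audio_recording <- function(samples, sample_rate = 44100) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("audio must contain at least one sample")
  if (!all(is.finite(samples))) stop("audio samples must be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a positive scalar")
  structure(list(samples = samples, sample_rate = as.numeric(sample_rate)),
            class = "audio_recording")
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording: %d samples, %.0f Hz, %.2f s>\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' @export
length.audio_recording <- function(x) length(x$samples)

as_audio <- function(x, sample_rate = 44100) {
  if (inherits(x, "audio_recording")) x else audio_recording(x, sample_rate)
}

#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader supporting uncompressed PCM-16 and IEEE float-32
#' mono files, the two formats this package writes.
#'
#' @param path file path.
#' @return an [audio_recording()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        n_channels   = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        sample_rate  = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(raw[15:16], "integer", 1, 2, endian = "little"))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      if (fmt$n_channels != 1L)
        stop("only mono WAV files are supported (got ",
             fmt$n_channels, " channels)")
      if (fmt$audio_format == 1L && fmt$bits == 16L) {
        v <- readBin(con, "integer", sz %/% 2L, size = 2, signed = TRUE,
                     endian = "little")
        samples <- v / 32768
      } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "double", sz %/% 4L, size = 4,
                           endian = "little")
      } else {
        stop("unsupported WAV encoding (format ", fmt$audio_format,
             ", ", fmt$bits, " bits)")
      }
    } else {
      readBin(con, "raw", sz + (sz %% 2L))  # skip unknown chunk (word-aligned)
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  audio_recording(samples, fmt$sample_rate)
}

#' Write a mono WAV file
#'
#' @param audio an [audio_recording()] or numeric vector.
#' @param path output file path.
#' @param bit_depth `"float32"` (default, stores amplitudes verbatim) or
#'   `"pcm16"` (clips to \[-1, 1\] and quantizes).
#' @param sample_rate used when `audio` is a bare numeric vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, bit_depth = c("float32", "pcm16"),
                      sample_rate = 44100) {
  audio <- as_audio(audio, sample_rate)
  bit_depth <- match.arg(bit_depth)
  x <- audio$samples
  sr <- as.integer(round(audio$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  if (bit_depth == "pcm16") {
    fmt_code <- 1L; bits <- 16L
    pcm <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
    data_size <- 2L * length(pcm)
  } else {
    fmt_code <- 3L; bits <- 32L
    data_size <- 4L * length(x)
  }
  block_align <- as.integer(bits / 8)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * block_align, con, size = 4, endian = "little")
  writeBin(block_align, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == "pcm16") {
    writeBin(pcm, con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}
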