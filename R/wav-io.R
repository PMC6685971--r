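#' Read a PCM WAV file
#'
#' Minimal RIFF/WAVE reader covering the formats produced by clinical
#' recorders and by [generate_cohort()]: integer PCM (16/24/32 bit) and
#' IEEE float (32 bit), any number of channels. Samples are returned on
#' the scale \[-1, 1\] (integer data divided by full scale).
#'
#' @param path path to a `.wav` file.
#' @param channel for multichannel files, 1-based channel to extract.
#'   Mono files ignore it. A multichannel file without `channel` is an
#'   error: tracheal sound analysis is single-channel.
#' @return list with `samples` (numeric vector in \[-1, 1\]),
#'   `sample_rate` (Hz), `bit_depth`, `n_channels`.
#' @seealso [write_wav()], [load_audio()]
#' @export
read_wav <- function(path, channel = NULL) {
  if (!file.exists(path)) stop("audio file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(sz) == 0L) break
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        n_channels   = readBin(raw[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        sample_rate  = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bit_depth    = readBin(raw[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (length(data_raw) < sz) stop("truncated WAV data chunk: ", path)
      break
    } else {
      skipped <- readBin(con, "raw", sz + sz %% 2L)  # chunks are word-aligned
      if (length(skipped) < sz) stop("truncated WAV file: ", path)
    }
  }
  if (is.null(fmt)) stop("WAV file has no fmt chunk: ", path)
  if (is.null(data_raw)) stop("WAV file has no data chunk: ", path)

  bytes <- fmt$bit_depth %/% 8L
  n_frames <- length(data_raw) %/% (bytes * fmt$n_channels)
  if (n_frames < 1L) stop("WAV file contains no samples: ", path)
  usable <- n_frames * bytes * fmt$n_channels
  data_raw <- data_raw[seq_len(usable)]

  x <- if (fmt$audio_format == 3L && fmt$bit_depth == 32L) {
    readBin(data_raw, "numeric", n_frames * fmt$n_channels, 4, endian = "little")
  } else if (fmt$audio_format == 1L && fmt$bit_depth == 16L) {
    readBin(data_raw, "integer", n_frames * fmt$n_channels, 2, signed = TRUE,
            endian = "little") / 32768
  } else if (fmt$audio_format == 1L && fmt$bit_depth == 32L) {
    readBin(data_raw, "integer", n_frames * fmt$n_channels, 4, endian = "little") / 2147483648
  } else if (fmt$audio_format == 1L && fmt$bit_depth == 24L) {
    m <- matrix(as.integer(data_raw), nrow = 3L)
    v <- m[1L, ] + 256L * m[2L, ] + 65536L * m[3L, ]
    (ifelse(v >= 8388608, v - 16777216, v)) / 8388608
  } else {
    stop("unsupported WAV encoding (format ", fmt$audio_format, ", ",
         fmt$bit_depth, " bit): ", path)
  }

  if (fmt$n_channels > 1L) {
    if (is.null(channel))
      stop("multichannel WAV (", fmt$n_channels,
           " channels) requires an explicit `channel`: ", path)
    if (channel < 1L || channel > fmt$n_channels)
      stop("channel ", channel, " out of range 1..", fmt$n_channels)
    x <- x[seq(channel, length(x), by = fmt$n_channels)]
  }
  list(samples = x, sample_rate = fmt$sample_rate,
       bit_depth = fmt$bit_depth, n_channels = fmt$n_channels)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples numeric vector; values are clipped to \[-1, 1\] and
#'   quantised to 16-bit integers.
#' @param path output path.
#' @param sample_rate sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate) {
  x <- pmin(1, pmax(-1, samples))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, 4, endian = "little")
  writeBin(as.integer(1), con, 2, endian = "little")   # PCM
  writeBin(as.integer(1), con, 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, 4, endian = "little")
  writeBin(as.integer(2), con, 2, endian = "little")   # block align
  writeBin(as.integer(16), con, 2, endian = "little")  # bit depth
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

#' Load one breathing-sound recording
#'
#' Thin wrapper around [read_wav()] that returns the amplitude sequence
#' and its sampling rate, selecting a channel when asked.
#'
#' @inheritParams read_wav
#' @return list with `samples` and `sample_rate`.
#' @export
load_audio <- function(path, channel = NULL) {
  w <- read_wav(path, channel = channel)
  list(samples = w$samples, sample_rate = w$sample_rate)
}
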