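#' Sampled audio waveform
#'
#' Lightweight container for a mono waveform: amplitude samples in `[-1, 1]`
#' and a sample rate in Hz.
#'
#' @param samples numeric vector of amplitudes.
#' @param sample_rate sampling rate, Hz.
#' @return an object of class `audio_track` with fields `samples`,
#'   `sample_rate` and `duration` (s).
#' @export
audio_track <- function(samples, sample_rate) {
  check_scalar(sample_rate, "sample_rate")
  if (!is.numeric(samples)) stop_invalid("samples must be numeric")
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate,
                 duration = length(samples) / sample_rate),
            class = "audio_track")
}

#' @export
print.audio_track <- function(x, ...) {
  cat(sprintf("Audio track: %.4g s, %g Hz (%d samples), peak %.3f\n",
              x$duration, x$sample_rate, length(x$samples),
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' @export
plot.audio_track <- function(x, ...) {
  t <- seq_along(x$samples) / x$sample_rate
  plot(t, x$samples, type = "l", xlab = "time (s)", ylab = "amplitude", ...)
  invisible(x)
}

#' Read a mono WAV file
#'
#' Supports PCM 8/16/32-bit and IEEE float32 mono or stereo files; stereo
#' channels are averaged to mono with a warning.
#'
#' @param path path to a `.wav` file.
#' @return an [audio_track()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop_invalid("audio file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_invalid("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop_invalid("not a WAV file: ", path)
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate = readBin(con, "integer", 1, 4, endian = "little"),
        block_align = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE))
      extra <- size - 16L
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      dat <- readBin(con, "raw", size)
      if (size %% 2L == 1L) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(fmt) || is.null(dat))
    stop_invalid("malformed WAV (missing fmt or data chunk): ", path)
  n_bytes <- fmt$bits %/% 8L
  if (fmt$format == 1L && fmt$bits == 16L) {
    x <- readBin(dat, "integer", length(dat) %/% 2L, 2, signed = TRUE,
                 endian = "little") / 32768
  } else if (fmt$format == 1L && fmt$bits == 32L) {
    x <- readBin(dat, "integer", length(dat) %/% 4L, 4,
                 endian = "little") / 2147483648
  } else if (fmt$format == 1L && fmt$bits == 8L) {
    x <- (readBin(dat, "integer", length(dat), 1, signed = FALSE) - 128) / 128
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    x <- readBin(dat, "double", length(dat) %/% 4L, 4, endian = "little")
  } else {
    stop_invalid("unsupported WAV encoding (format ", fmt$format,
                 ", ", fmt$bits, " bits): ", path)
  }
  if (fmt$channels > 1L) {
    warning("averaging ", fmt$channels, " channels to mono")
    x <- rowMeans(matrix(x, ncol = fmt$channels, byrow = TRUE))
  }
  audio_track(x, fmt$sample_rate)
}

#' Write an audio track to a WAV file
#'
#' @param audio an [audio_track()].
#' @param path output path.
#' @param format `"float32"` (default; no quantization of synthetic
#'   transients) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, format = c("float32", "pcm16")) {
  stopifnot(inherits(audio, "audio_track"))
  format <- match.arg(format)
  x <- audio$samples
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x)
  if (format == "float32") {
    fmt_tag <- 3L; bits <- 32L; data_size <- 4L * n
  } else {
    fmt_tag <- 1L; bits <- 16L; data_size <- 2L * n
  }
  sr <- as.integer(round(audio$sample_rate))
  block <- as.integer(bits / 8)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_tag, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")
  writeBin(sr, con, 4, endian = "little")
  writeBin(sr * block, con, 4, endian = "little")
  writeBin(block, con, 2, endian = "little")
  writeBin(bits, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (format == "float32") {
    writeBin(as.numeric(x), con, 4, endian = "little")
  } else {
    q <- as.integer(pmax(-32768, pmin(32767, round(x * 32767))))
    writeBin(q, con, 2, endian = "little")
  }
  invisible(path)
}
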