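#' Audio container
#'
#' Mono waveform plus sample rate. Samples are real-valued in `[-1, 1]`;
#' duration is derived.
#'
#' @param samples Numeric vector.
#' @param sample_rate Sampling rate in Hz (positive).
#' @return Object of class `adspeech_audio` with fields `samples`,
#'   `sample_rate`, `duration`.
#' @export
audio_signal <- function(samples, sample_rate) {
  stopifnot(length(samples) >= 1L, sample_rate > 0)
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.integer(sample_rate),
                 duration = length(samples) / sample_rate),
            class = "adspeech_audio")
}

#' @export
print.adspeech_audio <- function(x, ...) {
  cat(sprintf("<adspeech_audio> %.3f s @ %d Hz\n", x$duration,
              x$sample_rate))
  invisible(x)
}

#' Read a WAV file
#'
#' Minimal RIFF/WAV reader covering PCM (8/16/24/32-bit integer) and IEEE
#' float (32/64-bit) encodings. Channels are averaged to mono, the signal is
#' resampled to `target_rate`, and the waveform is scaled down if its peak
#' magnitude exceeds 1.
#'
#' @param path Path to a `.wav` file.
#' @param target_rate Working sample rate in Hz (default 16000).
#' @return An `adspeech_audio` at `target_rate`.
#' @export
read_audio <- function(path, target_rate = 16000L) {
  w <- read_wav(path)
  x <- if (is.matrix(w$samples)) rowMeans(w$samples) else w$samples
  if (w$sample_rate != target_rate)
    x <- resample_audio(x, w$sample_rate, target_rate)
  peak <- max(abs(x))
  if (peak > 1) x <- x / peak
  audio_signal(x, target_rate)
}

# Rational-factor polyphase resampling via signal::resample.
resample_audio <- function(x, from, to) {
  fr <- as.integer(from); t0 <- as.integer(to)
  g <- gcd_int(fr, t0)
  p <- t0 %/% g; q <- fr %/% g
  y <- signal::resample(x, p, q)
  n_target <- round(length(x) * t0 / fr)
  if (length(y) >= n_target) y[seq_len(n_target)]
  else c(y, rep(0, n_target - length(y)))
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

# Raw RIFF/WAV chunk walker.
read_wav <- function(path) {
  if (!file.exists(path)) stop("cannot read WAV file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE container: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || !nzchar(id)) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        code = readBin(fmt_raw[1:2], "integer", 1, 2, signed = FALSE,
                       endian = "little"),
        channels = readBin(fmt_raw[3:4], "integer", 1, 2, signed = FALSE,
                           endian = "little"),
        rate = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1, 2, signed = FALSE,
                       endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2 == 1) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("WAV file missing fmt/data chunk: ", path)

  x <- decode_wav_samples(data_raw, fmt)
  if (length(x) == 0L) stop("zero-length audio: ", path)
  n_frames <- length(x) %/% fmt$channels
  samples <- if (fmt$channels > 1)
    matrix(x[seq_len(n_frames * fmt$channels)], ncol = fmt$channels,
           byrow = TRUE)
  else x
  list(samples = samples, sample_rate = fmt$rate, bits = fmt$bits)
}

decode_wav_samples <- function(raw, fmt) {
  n <- length(raw)
  if (fmt$code == 1L || fmt$code == 65534L) {            # PCM
    if (fmt$bits == 16L) {
      readBin(raw, "integer", n %/% 2, 2, signed = TRUE,
              endian = "little") / 32768
    } else if (fmt$bits == 8L) {
      (readBin(raw, "integer", n, 1, signed = FALSE) - 128) / 128
    } else if (fmt$bits == 24L) {
      m <- matrix(as.integer(raw[seq_len((n %/% 3) * 3)]), nrow = 3)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    } else if (fmt$bits == 32L) {
      readBin(raw, "integer", n %/% 4, 4, signed = TRUE,
              endian = "little") / 2147483648
    } else stop("unsupported PCM bit depth: ", fmt$bits)
  } else if (fmt$code == 3L) {                           # IEEE float
    readBin(raw, "double", n %/% (fmt$bits %/% 8), fmt$bits %/% 8,
            endian = "little")
  } else stop("unsupported WAV format code: ", fmt$code)
}

#' Write a mono waveform as 16-bit PCM WAV
#'
#' @param a An `adspeech_audio`.
#' @param path Output path.
#' @export
write_wav <- function(a, path) {
  x <- pmax(pmin(a$samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")                 # PCM
  writeBin(1L, con, 2, endian = "little")                 # mono
  writeBin(as.integer(a$sample_rate), con, 4, endian = "little")
  writeBin(as.integer(a$sample_rate * 2L), con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")                 # block align
  writeBin(16L, con, 2, endian = "little")                # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
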