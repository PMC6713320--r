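# Minimal RIFF/WAVE codec: linear PCM 16/24-bit and IEEE float32, mono or
# stereo. Samples are held as doubles; integer formats use the symmetric
# scale 2^(bits-1), so int -> double -> int round-trips exactly and an
# identity-processed file is rewritten bit-identically.

#' Read a WAV file
#'
#' @param path file path.
#' @return list of class `wav` with `samples` (an `n x channels` double
#'   matrix, nominal range \[-1, 1\]), `sample_rate` (Hz), and `bit_depth`
#'   (16, 24, or 32; 32 = IEEE float).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 44) stop("input error: not a WAV file", call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (riff != "RIFF" || wave != "WAVE")
    stop("input error: not a RIFF/WAVE file", call. = FALSE)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    len <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", len)
      fmt <- list(
        audio_format = raw_u16(raw, 1L),
        channels     = raw_u16(raw, 3L),
        sample_rate  = raw_u32(raw, 5L),
        bits         = raw_u16(raw, 15L)
      )
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", len)
    } else {
      readBin(con, "raw", len)
    }
    if (len %% 2L == 1L) readBin(con, "raw", 1L)   # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("input error: missing fmt or data chunk", call. = FALSE)
  ch <- fmt$channels
  if (!ch %in% 1:2) stop("only mono/stereo supported", call. = FALSE)
  x <- if (fmt$audio_format == 1L && fmt$bits == 16L) {
    readBin(data_raw, "integer", length(data_raw) / 2L, 2L,
            signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
    n <- length(data_raw) / 3L
    b <- matrix(as.integer(data_raw), 3L, n)
    v <- b[1L, ] + 256L * b[2L, ] + 65536L * b[3L, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    readBin(data_raw, "double", length(data_raw) / 4L, 4L, endian = "little")
  } else {
    stop("unsupported WAV encoding: format ", fmt$audio_format, ", ",
         fmt$bits, " bit", call. = FALSE)
  }
  if (length(x) == 0L) stop("input error: zero-length audio", call. = FALSE)
  structure(list(samples = matrix(x, ncol = ch, byrow = TRUE),
                 sample_rate = fmt$sample_rate, bit_depth = fmt$bits),
            class = "wav")
}

raw_u16 <- function(r, i) as.integer(r[i]) + 256L * as.integer(r[i + 1L])
raw_u32 <- function(r, i) raw_u16(r, i) + 65536 * raw_u16(r, i + 2L)

#' Construct an in-memory WAV object
#' @param samples numeric vector (mono) or `n x channels` matrix in
#'   \[-1, 1\].
#' @param sample_rate sampling rate, Hz.
#' @param bit_depth 16, 24 (PCM) or 32 (IEEE float).
#' @return a `wav` object.
#' @export
wav <- function(samples, sample_rate = 44100, bit_depth = 16) {
  if (!is.matrix(samples)) samples <- matrix(samples, ncol = 1L)
  stopifnot(ncol(samples) %in% 1:2, nrow(samples) >= 1L,
            all(is.finite(samples)), bit_depth %in% c(16, 24, 32))
  structure(list(samples = samples, sample_rate = sample_rate,
                 bit_depth = as.integer(bit_depth)),
            class = "wav")
}

#' @export
print.wav <- function(x, ...) {
  cat(sprintf("<wav> %d samples x %d ch @ %d Hz, %d-bit%s (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$sample_rate, x$bit_depth,
              if (x$bit_depth == 32L) " float" else " PCM",
              nrow(x$samples) / x$sample_rate))
  invisible(x)
}

#' Write a WAV file
#' @param w a `wav` object.
#' @param path output path.
#' @return invisibly `path`.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "wav"))
  interleaved <- as.numeric(t(w$samples))
  ch <- ncol(w$samples)
  bits <- w$bit_depth
  bytes <- bits %/% 8L
  fmt_code <- if (bits == 32L) 3L else 1L
  data_len <- length(interleaved) * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(fmt_code, con, 2L, endian = "little")
  writeBin(ch, con, 2L, endian = "little")
  writeBin(as.integer(w$sample_rate), con, 4L, endian = "little")
  writeBin(as.integer(w$sample_rate * ch * bytes), con, 4L, endian = "little")
  writeBin(as.integer(ch * bytes), con, 2L, endian = "little")
  writeBin(as.integer(bits), con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, 4L, endian = "little")
  if (bits == 16L) {
    v <- pmin(pmax(round(interleaved * 32768), -32768), 32767)
    writeBin(as.integer(v), con, 2L, endian = "little")
  } else if (bits == 24L) {
    v <- pmin(pmax(round(interleaved * 8388608), -8388608), 8388607)
    v <- ifelse(v < 0, v + 16777216, v)
    b <- rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256)
    writeBin(as.raw(b), con)
  } else {
    writeBin(interleaved, con, 4L, endian = "little")
  }
  invisible(path)
}
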