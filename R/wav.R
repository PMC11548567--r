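#' Read a PCM WAV file
#'
#' Reads a RIFF/WAVE file containing integer PCM samples (8, 16, 24 or
#' 32 bit). Multi-channel audio is averaged down to mono and samples are
#' rescaled to `[-1, 1]`.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric vector in `[-1, 1]`) and
#'   `rate` (sampling rate in Hz).
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) abort(paste0("WAV file not found: ", path))
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort(paste0("not a RIFF/WAVE file: ", path))
  readBin(con, "integer", 1, 4, endian = "little")      # overall size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort(paste0("not a RIFF/WAVE file: ", path))

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, signed = FALSE, endian = "little"),
        channels     = readBin(con, "integer", 1, 2, signed = FALSE, endian = "little"),
        rate         = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, 2, signed = FALSE, endian = "little"),
        bits         = readBin(con, "integer", 1, 2, signed = FALSE, endian = "little")
      )
      extra <- size - 16
      if (extra > 0) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2 == 1) readBin(con, "raw", 1)        # chunk padding
    } else {
      readBin(con, "raw", size + size %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) abort(paste0("missing fmt/data chunk in ", path))
  if (fmt$audio_format != 1L) {
    abort(paste0("unsupported WAV encoding (only integer PCM): format tag ", fmt$audio_format))
  }

  bytes <- fmt$bits / 8
  n <- length(data_raw) %/% (bytes * fmt$channels) * fmt$channels
  x <- switch(
    as.character(fmt$bits),
    "8"  = as.numeric(readBin(data_raw, "integer", n, 1, signed = FALSE)) - 128,
    "16" = as.numeric(readBin(data_raw, "integer", n, 2, signed = TRUE, endian = "little")),
    "24" = read_int24(data_raw, n),
    "32" = as.numeric(readBin(data_raw, "integer", n, 4, signed = TRUE, endian = "little")),
    abort(paste0("unsupported PCM bit depth: ", fmt$bits))
  )
  scale <- switch(as.character(fmt$bits),
                  "8" = 128, "16" = 32768, "24" = 8388608, "32" = 2147483648)
  x <- x / scale
  if (fmt$channels > 1) {
    x <- rowMeans(matrix(x, ncol = fmt$channels, byrow = TRUE))
  }
  list(samples = x, rate = fmt$rate)
}

read_int24 <- function(raw, n) {
  b <- as.integer(raw[seq_len(n * 3)])
  b1 <- b[seq(1, length(b), 3)]
  b2 <- b[seq(2, length(b), 3)]
  b3 <- b[seq(3, length(b), 3)]
  v <- b1 + b2 * 256 + b3 * 65536
  ifelse(v >= 8388608, v - 16777216, v)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples Numeric vector in `[-1, 1]`; values outside are clipped.
#' @param rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_wav()]
#' @export
write_wav <- function(samples, rate, path) {
  stopifnot(is.numeric(samples), rate > 0)
  x <- pmin(pmax(samples, -1), 1)
  pcm <- pmin(as.integer(round(x * 32768)), 32767L)   # symmetric with the /32768 read scale
  data_size <- length(pcm) * 2L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")        # PCM
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")        # block align
  writeBin(16L, con, size = 2, endian = "little")       # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
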