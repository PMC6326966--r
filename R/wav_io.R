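#' Read a mono RIFF PCM WAV file
#'
#' Minimal reader for the uncompressed PCM WAV files this package writes
#' (and that field recorders typically produce). Only mono files are
#' accepted: stereo recordings must be mixed down before analysis so that
#' every sample unambiguously belongs to one call.
#'
#' @param path Path to a `.wav` file (RIFF, PCM, 8/16/24/32-bit integer).
#' @return A list with `samples` (numeric vector scaled to `[-1, 1]`),
#'   `rate` (sampling rate in Hz) and `bit` (bit depth).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        format   = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        rate     = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bit      = readBin(raw[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing fmt/data chunk): ", path)
  if (fmt$format != 1L) stop("only PCM WAV is supported: ", path)
  if (fmt$channels != 1L) stop("stereo WAV not supported; mix down to mono first: ", path)

  bytes <- fmt$bit %/% 8L
  n <- length(data_raw) %/% bytes
  if (fmt$bit == 8L) {
    x <- (as.integer(data_raw[seq_len(n)]) - 128) / 128
  } else if (fmt$bit %in% c(16L, 32L)) {
    x <- readBin(data_raw, "integer", n, bytes, signed = TRUE, endian = "little")
    x <- x / 2^(fmt$bit - 1)
  } else if (fmt$bit == 24L) {
    m <- matrix(as.integer(data_raw[seq_len(3L * n)]), nrow = 3L)
    v <- m[1, ] + m[2, ] * 256 + m[3, ] * 65536
    v <- ifelse(v >= 2^23, v - 2^24, v)
    x <- v / 2^23
  } else stop("unsupported bit depth: ", fmt$bit)
  list(samples = x, rate = fmt$rate, bit = fmt$bit)
}

#' Write a mono RIFF PCM WAV file
#'
#' @param samples Numeric vector in `[-1, 1]`; values outside are clipped.
#' @param rate Sampling rate in Hz.
#' @param path Output path.
#' @param bit Bit depth (8, 16 or 32). Default 16.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path, bit = 16L) {
  bit <- as.integer(bit)
  if (!bit %in% c(8L, 16L, 32L)) stop("bit depth must be 8, 16 or 32")
  samples <- pmin(1, pmax(-1, samples))
  bytes <- bit %/% 8L
  n <- length(samples)
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- n * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")              # PCM
  writeBin(1L, con, 2, endian = "little")              # mono
  writeBin(as.integer(rate), con, 4, endian = "little")
  writeBin(as.integer(rate * bytes), con, 4, endian = "little")
  writeBin(as.integer(bytes), con, 2, endian = "little")
  writeBin(bit, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bit == 8L) {
    writeBin(as.raw(pmin(255, pmax(0, round(samples * 128 + 128)))), con)
  } else {
    q <- as.integer(pmin(2^(bit - 1) - 1, pmax(-2^(bit - 1), round(samples * 2^(bit - 1)))))
    writeBin(q, con, bytes, endian = "little")
  }
  invisible(path)
}
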