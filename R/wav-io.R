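#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for single-channel linear PCM at 16 or 24 bits,
#' the two bit depths produced by the recorders this package emulates
#' (SoundTrap HF300: 16-bit; icListen HF: 24-bit). Samples are returned
#' normalised to `[-1, 1)` (division by 2^(bits-1)).
#'
#' @param path WAV file path.
#' @return list with `samples` (numeric in \[-1,1\]), `fs` (Hz), `bit_depth`.
#' @seealso [write_wav()], [wav_to_pressure()]
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  .check(identical(riff, "RIFF"), "not a RIFF file: %s", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  .check(identical(wave, "WAVE"), "not a WAVE file: %s", path)
  fs <- NA_integer_; bits <- NA_integer_; n_channels <- NA_integer_
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      .check(fmt[1] == 1L, "only linear PCM supported (format tag %d)", fmt[1])
      n_channels <- fmt[2]
      fs <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "integer", 1, 4, endian = "little")) # byte rate
      invisible(readBin(con, "integer", 1, 2, endian = "little")) # block align
      bits <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(id, "data")) {
      .check(!is.na(bits), "data chunk before fmt chunk")
      .check(n_channels == 1L, "only mono WAV supported (found %d channels)", n_channels)
      if (bits == 16L) {
        samples <- readBin(con, "integer", size / 2, 2, endian = "little") / 2^15
      } else if (bits == 24L) {
        raw <- as.integer(readBin(con, "raw", size))
        b0 <- raw[seq(1, length(raw), 3)]
        b1 <- raw[seq(2, length(raw), 3)]
        b2 <- raw[seq(3, length(raw), 3)]
        v <- b0 + 256 * b1 + 65536 * b2
        v <- ifelse(v >= 2^23, v - 2^24, v)
        samples <- v / 2^23
      } else {
        stop(sprintf("unsupported bit depth: %d", bits), call. = FALSE)
      }
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(samples)) break
  }
  .check(!is.null(samples), "no data chunk found in %s", path)
  list(samples = samples, fs = fs, bit_depth = as.integer(bits))
}

#' Write a mono PCM WAV file
#'
#' Samples outside `[-1, 1)` are clipped (with a warning); quantisation is
#' round-to-nearest at the requested bit depth.
#'
#' @param samples numeric vector in \[-1, 1\].
#' @param fs sampling rate, Hz.
#' @param path output path.
#' @param bit_depth 16 or 24.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs, path, bit_depth = 16L) {
  .check(bit_depth %in% c(16L, 24L), "bit_depth must be 16 or 24")
  full <- 2^(bit_depth - 1)
  q <- round(samples * full)
  n_clip <- sum(q >= full | q < -full)
  if (n_clip > 0) {
    warning(sprintf("%d samples clipped on write", n_clip))
    q <- pmin(pmax(q, -full), full - 1)
  }
  bytes_per <- bit_depth / 8
  data_size <- length(q) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")                  # PCM
  writeBin(1L, con, 2, endian = "little")                  # mono
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bit_depth), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bit_depth == 16L) {
    writeBin(as.integer(q), con, 2, endian = "little")
  } else {
    v <- as.integer(q)
    v <- ifelse(v < 0, v + 2^24, v)
    raw <- as.raw(rbind(v %% 256, (v %/% 256) %% 256, v %/% 65536))
    writeBin(raw, con)
  }
  invisible(path)
}
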