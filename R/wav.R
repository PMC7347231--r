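#' Read and write single-channel PCM WAV files
#'
#' Minimal RIFF/WAVE I/O for the mono 16-bit PCM recordings this package
#' works with (typically sampled at 300 kHz). Samples are exchanged as
#' numeric vectors scaled to `[-1, 1]`.
#'
#' @param path File path.
#' @param waveform Numeric vector in `[-1, 1]`; values outside are clipped.
#' @param sample_rate Samples per second.
#' @return `read_wav()` returns a list with `waveform` and `sample_rate`;
#'   `write_wav()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".wav")
#' write_wav(sin(2 * pi * 60000 * seq(0, 0.01, by = 1 / 3e5)), f)
#' rec <- read_wav(f)
#' @export
write_wav <- function(waveform, path, sample_rate = 300000) {
  x <- as.integer(round(clamp(waveform, -1, 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(x) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV is supported")
      if (fmt[2] != 1L) stop("only mono WAV is supported")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      bits <- readBin(con, integer(), n = 2, size = 2, endian = "little")[2]
      if (bits != 16L) stop("only 16-bit PCM is supported")
      if (sz > 16) readBin(con, raw(), n = sz - 16L)
    } else if (identical(id, "data")) {
      x <- readBin(con, integer(), n = sz / 2L, size = 2, signed = TRUE,
                   endian = "little")
      return(list(waveform = x / 32767, sample_rate = sample_rate))
    } else {
      readBin(con, raw(), n = sz)
    }
  }
}
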