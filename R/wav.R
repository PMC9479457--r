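# Minimal mono 24-bit RIFF/PCM WAV input and output.

#' Write a waveform to a 24-bit mono WAV file
#'
#' @param w a [waveform()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  peak <- if (length(w$samples)) max(abs(w$samples)) else 0
  if (peak > 1) stop(sprintf("refusing to write clipped audio (peak %.4f > 1)", peak))
  scale <- 2^23 - 1
  v <- as.integer(round(w$samples * scale))
  v[v < 0] <- v[v < 0] + as.integer(2^24)
  bytes <- as.raw(rbind(v %% 256L, (v %/% 256L) %% 256L, v %/% 65536L))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(bytes)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(w$fs), con, size = 4, endian = "little")
  writeBin(as.integer(w$fs * 3), con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")            # block align
  writeBin(24L, con, size = 2, endian = "little")           # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  writeBin(bytes, con)
  invisible(path)
}

#' Read a 24-bit mono WAV file
#'
#' @param path input file path.
#' @param expect_fs if non-`NULL`, error unless the file's sampling rate
#'   matches.
#' @return a [waveform()].
#' @export
read_wav <- function(path, expect_fs = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fs <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      channels <- fmt[2]
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16) readBin(con, raw(), n = size - 16)
    } else if (id == "data") {
      samples <- readBin(con, raw(), n = size)
      break
    } else {
      readBin(con, raw(), n = size)
    }
  }
  if (is.null(fs) || is.null(samples)) stop("malformed WAV file: ", path)
  if (channels != 1) stop("only mono WAV supported (file has ", channels, " channels)")
  if (bits != 24) stop("only 24-bit PCM supported (file has ", bits, " bits)")
  if (!is.null(expect_fs) && fs != expect_fs) {
    stop(sprintf("sample rate mismatch: file %g Hz, expected %g Hz", fs, expect_fs))
  }
  m <- matrix(as.integer(samples), nrow = 3)
  v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
  v[v >= 2^23] <- v[v >= 2^23] - 2^24
  waveform(v / (2^23 - 1), fs)
}
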