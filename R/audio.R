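# Minimal RIFF/WAVE reader and writer (PCM16 and IEEE float32, mono or
# stereo). Kept dependency-free; stereo input is averaged to mono with a
# warning since all stimulus transforms operate on mono waveforms.

#' Read a WAV file
#'
#' @param path WAV file path.
#' @param to_mono average stereo channels to mono (with a warning).
#' @return List with `samples` (numeric vector in \[-1, 1\]) and `sr` (Hz).
#' @export
read_wav <- function(path, to_mono = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_invalid("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  if (!identical(readChar(con, 4L, useBytes = TRUE), "WAVE"))
    stop_invalid("not a WAVE file: ", path)
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "raw", sz)
    } else if (id == "data") {
      dat <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(fmt) || is.null(dat)) stop_invalid("malformed WAV: ", path)
  u16 <- function(r, i) sum(as.integer(r[i + 0:1]) * c(1, 256))
  u32 <- function(r, i) sum(as.integer(r[i + 0:3]) * c(1, 256, 65536, 16777216))
  audio_format <- u16(fmt, 1L)
  n_ch <- u16(fmt, 3L)
  sr <- u32(fmt, 5L)
  bits <- u16(fmt, 15L)
  if (audio_format == 1L && bits == 16L) {
    x <- readBin(dat, "integer", length(dat) / 2L, 2L, signed = TRUE,
                 endian = "little") / 32768
  } else if (audio_format == 3L && bits == 32L) {
    x <- readBin(dat, "numeric", length(dat) / 4L, 4L, endian = "little")
  } else {
    stop_invalid("unsupported WAV encoding (format ", audio_format,
                 ", ", bits, " bit)")
  }
  if (n_ch > 1L) {
    x <- matrix(x, nrow = n_ch)
    if (to_mono) {
      warning("averaging ", n_ch, " channels to mono")
      x <- colMeans(x)
    } else x <- t(x)
  }
  list(samples = x, sr = sr)
}

#' Write a mono WAV file (PCM16)
#'
#' @param samples numeric vector in \[-1, 1\] (clipped otherwise).
#' @param sr sampling rate in Hz.
#' @param path output path.
#' @export
write_wav <- function(samples, sr, path) {
  x <- as.integer(round(pmin(1, pmax(-1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_sz <- length(x) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_sz, con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  for (v in list(c(1L, 2L), c(1L, 2L))) NULL
  writeBin(1L, con, size = 2L, endian = "little")            # PCM
  writeBin(1L, con, size = 2L, endian = "little")            # mono
  writeBin(as.integer(sr), con, size = 4L, endian = "little")
  writeBin(as.integer(sr) * 2L, con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_sz, con, size = 4L, endian = "little")
  writeBin(x, con, size = 2L, endian = "little")
  invisible(path)
}
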