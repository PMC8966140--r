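#' Read a RIFF/WAVE file
#'
#' Minimal WAV reader supporting uncompressed PCM16 and IEEE float32,
#' mono or multichannel.
#'
#' @param path file path.
#' @return list with `samples` (numeric matrix, samples x channels, in
#'   [-1, 1] for PCM16) and `fs` (sampling rate in Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(fmt_raw[3:4], "integer", 1, 2, endian = "little"),
        fs = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (id == "data") {
      dat <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(fmt) || is.null(dat)) stop("missing fmt/data chunk in ", path)
  if (fmt$audio_format == 1 && fmt$bits == 16) {
    x <- readBin(dat, "integer", length(dat) / 2, 2, signed = TRUE,
                 endian = "little") / 32768
  } else if (fmt$audio_format == 3 && fmt$bits == 32) {
    x <- readBin(dat, "numeric", length(dat) / 4, 4, endian = "little")
  } else {
    stop("unsupported WAV encoding (format ", fmt$audio_format, ", ",
         fmt$bits, " bit)")
  }
  list(samples = matrix(x, ncol = fmt$channels, byrow = TRUE), fs = fmt$fs)
}

#' Write a RIFF/WAVE file
#'
#' @param samples numeric vector or matrix (samples x channels).
#' @param fs sampling rate, Hz.
#' @param path output file path.
#' @param bits 32 (IEEE float, default) or 16 (PCM, values clipped to
#'   [-1, 1)).
#' @return invisibly, `path`.
#' @export
write_wav <- function(samples, fs, path, bits = 32) {
  if (!is.matrix(samples)) samples <- matrix(samples, ncol = 1)
  nch <- ncol(samples)
  x <- as.numeric(t(samples))  # interleave
  con <- file(path, "wb")
  on.exit(close(con))
  bytes_per <- bits / 8
  data_size <- length(x) * bytes_per
  fmt_code <- if (bits == 32) 3L else 1L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(as.integer(nch), con, 2, endian = "little")
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * nch * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(nch * bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 32) {
    writeBin(x, con, 4, endian = "little")
  } else {
    xi <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
    writeBin(xi, con, 2, endian = "little")
  }
  invisible(path)
}
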