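# Minimal mono 16-bit PCM WAV I/O. Only the canonical RIFF/fmt/data layout
# is supported — enough to exchange ultrasonic recordings with the parser
# and the audio fixture generator.

#' Read a mono 16-bit PCM WAV file
#'
#' @param path file path.
#' @return list with `wave` (numeric vector scaled to roughly unit range,
#'   samples / 32768) and `fs` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) {
    stop("not a WAVE file: ", path)
  }
  fs <- NULL; bits <- NULL; channels <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", size %/% 2, 2, signed = FALSE,
                     endian = "little")
      if (fmt[1] != 1) stop("only PCM WAV supported")
      channels <- fmt[2]
      fs <- fmt[3] + fmt[4] * 65536
      bits <- fmt[8]
    } else if (identical(id, "data")) {
      if (is.null(fs)) stop("data chunk before fmt chunk")
      if (channels != 1) stop("only mono WAV supported")
      if (bits != 16) stop("only 16-bit WAV supported")
      samples <- readBin(con, "integer", size %/% 2, 2, signed = TRUE,
                         endian = "little")
      return(list(wave = samples / 32768, fs = fs))
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
}

#' Write a mono 16-bit PCM WAV file
#'
#' The waveform is scaled by `scale` and clamped to the 16-bit range; the
#' default scales the maximum absolute sample to 90% of full scale.
#'
#' @param wave numeric vector.
#' @param fs sampling rate (Hz).
#' @param path output file path.
#' @param scale multiplier applied before quantization, or `NULL` for the
#'   default peak normalization.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, fs, path, scale = NULL) {
  if (is.null(scale)) scale <- 0.9 * 32767 / max(abs(wave), 1e-12)
  s <- as.integer(pmax(pmin(round(wave * scale), 32767), -32768))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(s)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")        # PCM, mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little")  # byte rate
  writeBin(c(2L, 16L), con, size = 2, endian = "little")       # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(s, con, size = 2, endian = "little")
  invisible(path)
}
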