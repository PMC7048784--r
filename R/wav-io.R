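#' Read a mono PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the audio this pipeline consumes: linear PCM
#' (16- or 32-bit integer) or IEEE float, single channel (multichannel input
#' is averaged to mono). Samples are returned as numeric in [-1, 1].
#'
#' @param path Path to a `.wav` file.
#' @return A list with `wave` (numeric vector) and `rate` (sampling rate, Hz).
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  assert_that(file.exists(path), paste0("WAV file not found: ", path))
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  assert_that(identical(riff, "RIFF"), "not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  assert_that(identical(wave, "WAVE"), "not a WAVE file")
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        format = readBin(fmt_raw[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        channels = readBin(fmt_raw[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        rate = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  assert_that(!is.null(fmt) && !is.null(data_raw), "malformed WAV: missing fmt/data chunk")
  x <- if (fmt$format == 3L) {
    readBin(data_raw, "numeric", length(data_raw) / 4, 4, endian = "little")
  } else if (fmt$bits == 16L) {
    readBin(data_raw, "integer", length(data_raw) / 2, 2, signed = TRUE,
            endian = "little") / 32768
  } else if (fmt$bits == 32L) {
    readBin(data_raw, "integer", length(data_raw) / 4, 4, endian = "little") / 2147483648
  } else {
    stop("unsupported WAV encoding (", fmt$bits, "-bit, format ", fmt$format, ")",
         call. = FALSE)
  }
  if (fmt$channels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  list(wave = as.numeric(x), rate = fmt$rate)
}

#' Write a mono PCM16 WAV file
#'
#' @param wave Numeric vector; values outside [-1, 1] are clipped.
#' @param rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, rate, path) {
  x <- pmin(pmax(as.numeric(wave), -1), 1)
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")   # PCM
  writeBin(1L, con, 2, endian = "little")   # mono
  writeBin(as.integer(rate), con, 4, endian = "little")
  writeBin(as.integer(rate) * 2L, con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
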