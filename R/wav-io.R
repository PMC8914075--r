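# Minimal mono RIFF/WAVE IO. Supports PCM 16-bit (format tag 1) and IEEE
# float32 (format tag 3), the two encodings used for stimulus files.

#' Read a mono WAV file
#'
#' @param path Path to a RIFF/WAVE file, PCM 16-bit or IEEE float32, mono.
#' @return A [waveform()] with samples in `[-1, 1]` (PCM scaled by 2^15).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1L, 4L, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt_tag <- NA_integer_; n_chan <- NA_integer_; rate <- NA_integer_
  bits <- NA_integer_; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_tag <- readBin(con, "integer", 1L, 2L, endian = "little", signed = FALSE)
      n_chan  <- readBin(con, "integer", 1L, 2L, endian = "little", signed = FALSE)
      rate    <- readBin(con, "integer", 1L, 4L, endian = "little")
      readBin(con, "integer", 1L, 4L, endian = "little")  # byte rate
      readBin(con, "integer", 1L, 2L, endian = "little")  # block align
      bits <- readBin(con, "integer", 1L, 2L, endian = "little", signed = FALSE)
      extra <- size - 16L
      if (extra > 0) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      if (is.na(fmt_tag)) stop("malformed WAV: data chunk before fmt chunk")
      if (fmt_tag == 1L && bits == 16L) {
        raw16 <- readBin(con, "integer", size %/% 2L, 2L, endian = "little", signed = TRUE)
        samples <- raw16 / 32768
      } else if (fmt_tag == 3L && bits == 32L) {
        samples <- readBin(con, "double", size %/% 4L, 4L, endian = "little")
      } else {
        stop("unsupported WAV encoding (format tag ", fmt_tag, ", ", bits, " bits)")
      }
      if (size %% 2L == 1L) readBin(con, "raw", 1L)
    } else {
      readBin(con, "raw", size + size %% 2L)  # skip unknown chunk (word aligned)
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (n_chan != 1L) stop("only mono WAV files are supported (found ", n_chan, " channels)")
  waveform(samples, rate)
}

#' Write a mono WAV file
#'
#' @param wave A [waveform()].
#' @param path Output path.
#' @param format `"float32"` (default; lossless for analysis round-trips) or
#'   `"pcm16"` (samples clipped to `[-1, 1)` and quantised to 16 bits).
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, format = c("float32", "pcm16")) {
  stopifnot(inherits(wave, "waveform"))
  format <- match.arg(format)
  n <- length(wave$samples)
  rate <- as.integer(round(wave$rate))
  if (format == "pcm16") {
    bytes_per <- 2L; fmt_tag <- 1L; bits <- 16L
  } else {
    bytes_per <- 4L; fmt_tag <- 3L; bits <- 32L
  }
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(fmt_tag, con, 2L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")  # mono
  writeBin(rate, con, 4L, endian = "little")
  writeBin(as.integer(rate * bytes_per), con, 4L, endian = "little")
  writeBin(as.integer(bytes_per), con, 2L, endian = "little")
  writeBin(as.integer(bits), con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4L, endian = "little")
  if (format == "pcm16") {
    q <- as.integer(round(pmax(pmin(wave$samples, 32767 / 32768), -1) * 32768))
    writeBin(q, con, 2L, endian = "little")
  } else {
    writeBin(as.numeric(wave$samples), con, 4L, endian = "little")
  }
  invisible(path)
}
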