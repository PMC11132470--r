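#' Write a WAV audio file
#'
#' Minimal RIFF/WAVE writer: mono or stereo, 16-bit integer PCM (default) or
#' 32-bit IEEE float. Samples are expected in `[-1, 1]`; PCM output clips
#' anything outside and quantizes without dither.
#'
#' @param samples Numeric vector (mono) or 2-column matrix (stereo: left,
#'   right), values in `[-1, 1]`.
#' @param path Output file path.
#' @param rate Sampling rate in Hz (default 44100).
#' @param bit_depth 16 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, rate = 44100, bit_depth = 16) {
  if (inherits(samples, "am_stimulus")) {
    rate <- samples$rate
    samples <- samples$waveform
  }
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  n_ch <- ncol(samples)
  if (!n_ch %in% c(1L, 2L)) abort("`samples` must be mono or stereo.")
  if (!bit_depth %in% c(16L, 32L)) abort("`bit_depth` must be 16 or 32.")
  inter <- as.numeric(t(samples)) # interleave channels
  bytes_per <- bit_depth / 8L
  data_size <- length(inter) * bytes_per
  fmt_code <- if (bit_depth == 16) 1L else 3L # PCM vs IEEE float
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  w32(36 + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w32(16)
  w16(fmt_code)
  w16(n_ch)
  w32(rate)
  w32(rate * n_ch * bytes_per) # byte rate
  w16(n_ch * bytes_per)        # block align
  w16(bit_depth)
  writeChar("data", con, eos = NULL)
  w32(data_size)
  if (bit_depth == 16) {
    x <- pmin(1, pmax(-1, inter))
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(inter, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV audio file
#'
#' Counterpart of [write_wav()]; reads 16-bit PCM or 32-bit float RIFF/WAVE.
#'
#' @param path WAV file path.
#' @return A list with `samples` (matrix, one column per channel, values in
#'   `[-1, 1]` for PCM) and `rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r32 <- function() readBin(con, "integer", size = 4, endian = "little")
  r16 <- function() readBin(con, "integer", size = 2, endian = "little")
  if (readChar(con, 4) != "RIFF") abort("Not a RIFF file.")
  r32()
  if (readChar(con, 4) != "WAVE") abort("Not a WAVE file.")
  fmt_code <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || !nzchar(id)) abort("No data chunk found.")
    sz <- r32()
    if (id == "fmt ") {
      fmt_code <- r16(); n_ch <- r16(); rate <- r32(); r32(); r16()
      bit_depth <- r16()
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (id == "data") {
      n_samp <- sz / (bit_depth / 8)
      x <- if (fmt_code == 1 && bit_depth == 16) {
        readBin(con, "integer", n_samp, size = 2, endian = "little") / 32767
      } else if (fmt_code == 3 && bit_depth == 32) {
        readBin(con, "numeric", n_samp, size = 4, endian = "little")
      } else {
        abort(sprintf("Unsupported WAV format (code %d, %d-bit).", fmt_code, bit_depth))
      }
      return(list(samples = matrix(x, ncol = n_ch, byrow = TRUE), rate = rate))
    } else {
      readBin(con, "raw", sz)
    }
  }
}
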