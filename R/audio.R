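#' Parameters of the binaural lateral-position encoder
#'
#' The encoder maps the vehicle's signed lateral deviation to per-ear white
#' noise levels. In the lane centre both ears sit at `base_level`
#' (-50 dB relative to the maximum tolerable level); a leftward deviation
#' raises the left-ear level and lowers the right-ear level by
#' `gain` dB per metre (default 25 dB/m), and symmetrically for rightward
#' deviations. Levels are clamped to `[clamp_floor, clamp_ceiling]`; dB are
#' amplitude-referenced (amplitude factor `10^(dB/20)`).
#'
#' @param base_level Centre-lane per-ear level in dB (default -50).
#' @param gain Encoding gain in dB per metre of deviation (default 25).
#' @param clamp_floor,clamp_ceiling Per-ear level clamps in dB
#'   (defaults -100 and 0).
#' @param sample_rate Audio sampling rate in Hz for rendering
#'   (default 44100).
#' @return An `encoder_params` list.
#' @export
encoder_params <- function(base_level = -50, gain = 25,
                           clamp_floor = -100, clamp_ceiling = 0,
                           sample_rate = 44100) {
  stopifnot_scalar_number(gain, "gain", positive = TRUE)
  stopifnot_scalar_number(sample_rate, "sample_rate", positive = TRUE)
  if (!(clamp_floor <= base_level && base_level <= clamp_ceiling)) {
    stop("`base_level` must lie within [clamp_floor, clamp_ceiling]",
         call. = FALSE)
  }
  structure(list(base_level = base_level, gain = gain,
                 clamp_floor = clamp_floor, clamp_ceiling = clamp_ceiling,
                 sample_rate = sample_rate),
            class = "encoder_params")
}

#' Encode lateral deviation as binaural levels
#'
#' `left = clamp(base + gain * d)`, `right = clamp(base - gain * d)`, with
#' deviation `d` positive leftward: drifting left makes the left ear louder
#' and the right ear quieter. Mirror-symmetric: `encode(-d)` swaps ears.
#'
#' @param deviation Numeric vector of signed lateral deviations in metres
#'   (positive = leftward).
#' @param params An [encoder_params()] list.
#' @return A tibble with columns `left` and `right` (dB).
#' @examples
#' encode_deviation(c(0, 1, -1))
#' @export
encode_deviation <- function(deviation, params = encoder_params()) {
  if (any(!is.finite(deviation))) {
    stop("`deviation` must be finite", call. = FALSE)
  }
  tibble::tibble(
    left = clamp(params$base_level + params$gain * deviation,
                 params$clamp_floor, params$clamp_ceiling),
    right = clamp(params$base_level - params$gain * deviation,
                  params$clamp_floor, params$clamp_ceiling)
  )
}

#' Decode binaural levels back to lateral deviation
#'
#' Inverse of [encode_deviation()]: `d = (left - right) / (2 * gain)`, exact
#' in the unclamped range. When either ear is clamped the estimate saturates
#' and is flagged.
#'
#' @param levels A data frame with columns `left` and `right` (dB), as
#'   returned by [encode_deviation()].
#' @param params An [encoder_params()] list.
#' @return A tibble with columns `deviation` (m) and `saturated` (logical).
#' @examples
#' decode_levels(encode_deviation(0.5))
#' @export
decode_levels <- function(levels, params = encoder_params()) {
  stopifnot(is.data.frame(levels), all(c("left", "right") %in% names(levels)))
  d <- (levels$left - levels$right) / (2 * params$gain)
  lim <- (params$clamp_ceiling - params$base_level) / params$gain
  saturated <- levels$left >= params$clamp_ceiling |
    levels$right >= params$clamp_ceiling |
    levels$left <= params$clamp_floor |
    levels$right <= params$clamp_floor
  tibble::tibble(deviation = ifelse(saturated, sign(d) * lim, d),
                 saturated = saturated)
}

#' Render a binaural level series as stereo white noise
#'
#' Generates a Gaussian white-noise carrier at `sample_rate` and applies the
#' per-ear amplitude factor `10^(level/20)` with a zero-order hold over each
#' simulation frame of length `dt`.
#'
#' @param levels A data frame with columns `left` and `right` (dB), one row
#'   per simulation frame.
#' @param dt Frame duration in seconds (default 1/60).
#' @param params An [encoder_params()] list (supplies `sample_rate`).
#' @param seed Integer seed for the noise carrier.
#' @param ref_amplitude Linear amplitude of a 0 dB carrier sample SD
#'   (default 0.25, leaving headroom for 16-bit export).
#' @return A numeric matrix with one row per audio sample and columns
#'   `left`, `right`.
#' @examples
#' buf <- render_binaural(encode_deviation(rep(0, 60)), seed = 1)
#' nrow(buf)  # one second of audio
#' @export
render_binaural <- function(levels, dt = 1 / 60, params = encoder_params(),
                            seed = NULL, ref_amplitude = 0.25) {
  stopifnot(is.data.frame(levels), all(c("left", "right") %in% names(levels)))
  n_frames <- nrow(levels)
  if (n_frames == 0) stop("`levels` is empty", call. = FALSE)
  sr <- params$sample_rate
  # cumulative rounding keeps total sample count = duration * sample_rate
  edges <- round(seq_len(n_frames) * dt * sr)
  n_per_frame <- diff(c(0, edges))
  n_samples <- edges[n_frames]
  amp_l <- rep(10^(levels$left / 20), n_per_frame) * ref_amplitude
  amp_r <- rep(10^(levels$right / 20), n_per_frame) * ref_amplitude
  with_seed(seed, {
    buf <- cbind(left = rnorm(n_samples) * amp_l,
                 right = rnorm(n_samples) * amp_r)
    buf
  })
}

#' Write a stereo buffer as a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer (2-channel, 16-bit little-endian PCM). Samples
#' outside `[-1, 1]` are hard-clipped.
#'
#' @param buffer Numeric matrix with columns `left`, `right`, values in
#'   `[-1, 1]`.
#' @param path Output file path.
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @return `path`, invisibly.
#' @export
write_wav <- function(buffer, path, sample_rate = 44100) {
  stopifnot(is.matrix(buffer), ncol(buffer) == 2)
  pcm <- as.integer(round(clamp(t(buffer), -1, 1) * 32767))
  data_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(2L, con, size = 2, endian = "little")            # stereo
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 4L), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM stereo WAV file
#'
#' Companion reader for [write_wav()], used mainly for round-trip checks.
#'
#' @param path WAV file path.
#' @return A list with `sample_rate` and `buffer` (numeric matrix, columns
#'   `left`, `right`).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (riff != "RIFF" || wave != "WAVE") stop("not a RIFF/WAVE file")
  repeat {
    id <- readChar(con, 4)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(id) == 0) stop("no data chunk found")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "raw", size - 8)
      n_channels <- fmt[2]
    } else if (id == "data") {
      pcm <- readBin(con, "integer", size / 2, size = 2, endian = "little")
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  m <- matrix(pcm / 32767, ncol = n_channels, byrow = TRUE)
  colnames(m) <- c("left", "right")[seq_len(n_channels)]
  list(sample_rate = sample_rate, buffer = m)
}
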