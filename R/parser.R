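# Simplified spectrogram-based syllable parser: detects stretches of
# ultrasonic power above the per-bin noise floor, merges nearby events,
# drops too-short ones, and extracts per-syllable pitch features (mean peak
# frequency, pitch-jump count and directions).

#' Parser configuration
#'
#' @param fs sampling rate in Hz (default 250 kHz).
#' @param fft_size FFT length in samples (default 256).
#' @param hop hop between frames in samples (default `fft_size / 2`).
#' @param band frequency band searched for vocal power (Hz).
#' @param threshold_db detection threshold above the noise floor (dB).
#' @param min_duration shortest retained event (seconds).
#' @param merge_gap events closer than this are merged (seconds).
#' @param jump_threshold peak-frequency step counted as a pitch jump (Hz).
#' @return object of class `parser_config`.
#' @export
parser_config <- function(fs = 250000, fft_size = 256, hop = fft_size / 2,
                          band = c(25e3, 110e3), threshold_db = 10,
                          min_duration = 0.005, merge_gap = 0.010,
                          jump_threshold = 20e3) {
  stopifnot(band[1] >= 0, band[2] <= fs / 2, band[2] > band[1],
            min_duration > hop / fs, threshold_db > 0, jump_threshold > 0)
  structure(list(fs = fs, fft_size = fft_size, hop = hop, band = band,
                 threshold_db = threshold_db, min_duration = min_duration,
                 merge_gap = merge_gap, jump_threshold = jump_threshold),
            class = "parser_config")
}

# power spectrogram: list(P = freq x frames, freqs, hop_s)
power_spectrogram <- function(wave, config) {
  sp <- signal::specgram(wave, n = config$fft_size, Fs = config$fs,
                         window = signal::hanning(config$fft_size),
                         overlap = config$fft_size - config$hop)
  list(P = abs(sp$S)^2, freqs = sp$f, hop_s = config$hop / config$fs)
}

#' Parse a waveform into syllables
#'
#' Frames whose total in-band power exceeds the noise floor by
#' `threshold_db` are marked active; runs of active frames become candidate
#' events, events separated by less than `merge_gap` are merged, and events
#' shorter than `min_duration` are dropped. The noise floor is the per-bin
#' median frame power over the whole file (robust when vocal activity is
#' sparse). Boundaries are reported at hop resolution; each retained
#' syllable also carries its mean peak frequency and pitch-jump features
#' (see [extract_pitch_features()]).
#'
#' @param wave numeric waveform (mono), or a path to a 16-bit PCM WAV file.
#' @param config a [parser_config()]; `config$fs` must match the file's
#'   sampling rate when reading from disk.
#' @return data.frame with columns `start_s`, `end_s`, `duration_s`,
#'   `mean_freq_hz`, `jump_count`, `jump_dirs`.
#' @export
parse_wav <- function(wave, config = parser_config()) {
  if (is.character(wave)) {
    w <- read_wav(wave)
    if (w$fs != config$fs) {
      stop("file sampling rate ", w$fs, " Hz does not match config (",
           config$fs, " Hz)")
    }
    wave <- w$wave
  }
  if (length(wave) < 2 * config$fft_size) stop("waveform empty or too short")
  if (any(!is.finite(wave))) stop("waveform contains non-finite samples")
  peak <- max(abs(wave))
  if (peak > 0 && mean(abs(wave) >= peak * 0.999) > 0.01) {
    stop("waveform appears clipped (>1% of samples at full scale)")
  }
  # zero-pad so an event ending at end-of-file still fills its last frames
  sg <- power_spectrogram(c(wave, numeric(config$fft_size)), config)
  inband <- sg$freqs >= config$band[1] & sg$freqs <= config$band[2]
  floor_power <- sum(apply(sg$P[inband, , drop = FALSE], 1, stats::median))
  frame_power <- colSums(sg$P[inband, , drop = FALSE])
  active <- frame_power > floor_power * 10^(config$threshold_db / 10)
  if (!any(active)) {
    return(empty_syllable_table())
  }
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ev <- data.frame(first = starts[r$values], last = ends[r$values])
  # merge events separated by < merge_gap
  if (nrow(ev) > 1) {
    gap_frames <- (ev$first[-1] - ev$last[-nrow(ev)] - 1) * sg$hop_s
    keep_break <- gap_frames >= config$merge_gap
    grp <- cumsum(c(1, as.integer(keep_break)))
    ev <- data.frame(
      first = tapply(ev$first, grp, min),
      last = tapply(ev$last, grp, max)
    )
  }
  # boundary convention: true onsets/offsets sit about one hop inside the
  # first/last triggered frame (windows trigger on partial overlap)
  ev$start_s <- ev$first * sg$hop_s
  ev$end_s <- ev$last * sg$hop_s
  ev <- ev[ev$end_s - ev$start_s >= config$min_duration, , drop = FALSE]
  if (nrow(ev) == 0) {
    return(empty_syllable_table())
  }
  feats <- lapply(seq_len(nrow(ev)), function(i) {
    frames <- ev$first[i]:ev$last[i]
    pitch_features_from_track(
      peak_track(sg$P[, frames, drop = FALSE], sg$freqs, config$band),
      config$jump_threshold)
  })
  data.frame(
    start_s = ev$start_s,
    end_s = ev$end_s,
    duration_s = ev$end_s - ev$start_s,
    mean_freq_hz = vapply(feats, function(f) f$mean_freq_hz, numeric(1)),
    jump_count = vapply(feats, function(f) f$jump_count, integer(1)),
    jump_dirs = vapply(feats, function(f) f$jump_dirs, character(1)),
    row.names = NULL
  )
}

empty_syllable_table <- function() {
  data.frame(start_s = numeric(0), end_s = numeric(0), duration_s = numeric(0),
             mean_freq_hz = numeric(0), jump_count = integer(0),
             jump_dirs = character(0))
}

# strongest in-band frequency per frame
peak_track <- function(P, freqs, band) {
  inband <- which(freqs >= band[1] & freqs <= band[2])
  freqs[inband][apply(P[inband, , drop = FALSE], 2, which.max)]
}

pitch_features_from_track <- function(track, jump_threshold) {
  d <- diff(track)
  jumps <- which(abs(d) > jump_threshold)
  list(mean_freq_hz = mean(track),
       jump_count = length(jumps),
       jump_dirs = paste(ifelse(d[jumps] > 0, "up", "down"), collapse = ","))
}

#' Pitch features of one detected syllable segment
#'
#' Tracks the strongest in-band frequency in every frame of the segment's
#' spectrogram; the syllable's mean frequency is the mean of this track, and
#' a pitch jump is counted wherever the track steps by more than
#' `jump_threshold` between consecutive frames (direction = sign of the
#' step).
#'
#' @param segment numeric waveform of a single detected syllable.
#' @param config a [parser_config()].
#' @return list with `mean_freq_hz`, `jump_count`, `jump_dirs`
#'   (comma-separated `"up"`/`"down"`).
#' @export
extract_pitch_features <- function(segment, config = parser_config()) {
  if (length(segment) < config$fft_size + config$hop) {
    stop("segment shorter than 2 frames")
  }
  sg <- power_spectrogram(segment, config)
  pitch_features_from_track(peak_track(sg$P, sg$freqs, config$band),
                            config$jump_threshold)
}
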