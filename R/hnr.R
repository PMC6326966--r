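#' Harmonicity analysis settings
#'
#' @param time_step Frame step (s).
#' @param minimum_pitch Lowest expected f0 (Hz); sets the analysis window to
#'   `periods_per_window / minimum_pitch` seconds.
#' @param silence_threshold Frames whose local peak amplitude is below this
#'   fraction of the call's global peak are skipped.
#' @param periods_per_window Window length in pitch-floor periods.
#' @return An `hnr_config` list.
#' @export
hnr_config <- function(time_step = 0.01, minimum_pitch = 75,
                       silence_threshold = 0.1, periods_per_window = 1) {
  if (minimum_pitch <= 0) stop("minimum_pitch must be > 0")
  structure(list(time_step = time_step, minimum_pitch = minimum_pitch,
                 silence_threshold = silence_threshold,
                 periods_per_window = periods_per_window),
            class = "hnr_config")
}

# dB harmonicity implied by a normalized autocorrelation peak r:
# r is the fraction of frame power that is periodic, so HNR =
# 10 log10(r / (1 - r)).
harmonicity_db <- function(r) {
  r <- pmin(1 - 1e-12, pmax(1e-12, r))
  10 * log10(r / (1 - r))
}

#' Mean harmonics-to-noise ratio of a call
#'
#' Per frame, the maximum normalized cross-correlation `r` over candidate
#' periods estimates the periodic fraction of the frame's power; the frame
#' HNR is `10 log10(r / (1 - r))` dB. Frames whose local peak amplitude
#' falls below `silence_threshold` times the global peak are skipped, and
#' the mean over the retained frames is returned.
#'
#' @param recording A `call_recording` or list with `samples` and `rate`.
#' @param cfg An [hnr_config()].
#' @param max_candidate_f0 Upper bound of the period search (Hz); keeps the
#'   trivial small-lag correlation of any smooth waveform out of the search.
#' @return Mean HNR in dB.
#' @export
compute_hnr <- function(recording, cfg = hnr_config(), max_candidate_f0 = 1200) {
  x <- recording$samples
  rate <- recording$rate
  maxlag <- ceiling(rate * cfg$periods_per_window / cfg$minimum_pitch)
  minlag <- max(2L, floor(rate / max_candidate_f0))
  if (length(x) < 2 * maxlag)
    stop("recording shorter than the harmonicity analysis window")
  W <- maxlag
  step <- round(cfg$time_step * rate)
  starts <- seq(1L, length(x) - 2L * W + 1L, by = step)
  peak_all <- max(abs(x))
  vals <- numeric(0)
  for (s in starts) {
    seg <- x[s:(s + 2L * W - 1L)]
    if (max(abs(seg)) < cfg$silence_threshold * peak_all) next
    r <- frame_nccf(seg, W)
    vals <- c(vals, harmonicity_db(max(r[(minlag:maxlag) + 1])))
  }
  if (length(vals) == 0) stop("all frames below the silence threshold")
  mean(vals)
}
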