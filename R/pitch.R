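#' Pitch analysis settings
#'
#' Defaults match the analysis window used for coo calls: 10-ms frames and a
#' 75-1200 Hz pitch search range. `voicing_threshold` is the minimum
#' normalized cross-correlation peak for a frame to count as voiced.
#'
#' @param time_step Frame step (s).
#' @param pitch_floor,pitch_ceiling Pitch search range (Hz).
#' @param voicing_threshold Correlation threshold in (0, 1).
#' @param octave_cost Per-octave penalty on longer candidate periods; breaks
#'   the exact subharmonic ties of periodic signals and suppresses isolated
#'   octave-down errors in noisy frames.
#' @return A `pitch_config` list.
#' @export
pitch_config <- function(time_step = 0.01, pitch_floor = 75, pitch_ceiling = 1200,
                         voicing_threshold = 0.45, octave_cost = 0.03) {
  if (time_step <= 0) stop("time_step must be > 0")
  if (pitch_floor <= 0 || pitch_floor >= pitch_ceiling)
    stop("need 0 < pitch_floor < pitch_ceiling")
  structure(list(time_step = time_step, pitch_floor = pitch_floor,
                 pitch_ceiling = pitch_ceiling,
                 voicing_threshold = voicing_threshold,
                 octave_cost = octave_cost),
            class = "pitch_config")
}

# Normalized cross-correlation of the first `W` samples of `seg` against
# itself at lags 0..W (seg has length 2W). Returns the correlation vector;
# r[lag + 1] corresponds to integer lag `lag`.
frame_nccf <- function(seg, W) {
  seg <- seg - mean(seg)
  num <- convolve(seg, seg[1:W], conj = TRUE, type = "open")[W + 0:W]
  cs <- cumsum(c(0, seg^2))
  e0 <- cs[W + 1] - cs[1]
  elag <- cs[(0:W) + W + 1] - cs[(0:W) + 1]
  den <- sqrt(e0 * elag)
  ifelse(den > 0, num / den, 0)
}

# Peak of r over integer lags [lo, hi] with parabolic interpolation.
# Returns c(lag, height); lag is fractional.
interp_peak <- function(r, lo, hi) {
  idx <- lo:hi
  k <- idx[which.max(r[idx + 1])]
  y0 <- r[k]; y1 <- r[k + 1]; y2 <- r[k + 2]
  if (k > lo && k < hi && is.finite(y0 + y1 + y2)) {
    d <- y0 - 2 * y1 + y2
    off <- if (abs(d) > 1e-12) 0.5 * (y0 - y2) / d else 0
    off <- max(-0.5, min(0.5, off))
    c(k + off, y1 - 0.25 * (y0 - y2) * off)
  } else c(k, r[k + 1])
}

#' Extract a pitch contour by normalized cross-correlation
#'
#' Frame-local cross-correlation pitch tracking: each 10-ms frame is scored
#' by the normalized cross-correlation of a one-pitch-floor-period window
#' against its lagged copy over lags spanning `[1/ceiling, 1/floor]` s; the
#' best peak is refined by parabolic interpolation, and a small per-octave
#' lag penalty resolves the exact-subharmonic ties of perfectly periodic
#' signals. Frames whose peak correlation falls below the
#' voicing threshold, or that are essentially silent, are marked unvoiced.
#'
#' @param recording A `call_recording` or any list with `samples` and `rate`.
#' @param cfg A [pitch_config()].
#' @return A `pitch_contour`: list with `frame_times` (s), `f0` (Hz, `NA`
#'   when unvoiced) and `voiced` (logical).
#' @export
extract_pitch <- function(recording, cfg = pitch_config()) {
  x <- recording$samples
  rate <- recording$rate
  maxlag <- ceiling(rate / cfg$pitch_floor)
  minlag <- max(2L, floor(rate / cfg$pitch_ceiling))
  if (length(x) < 3 * maxlag)
    stop("recording shorter than 3 pitch-floor periods; cannot track pitch")
  W <- maxlag
  step <- round(cfg$time_step * rate)
  starts <- seq(1L, length(x) - 2L * W + 1L, by = step)
  peak_all <- max(abs(x))
  n <- length(starts)
  f0 <- rep(NA_real_, n)
  voiced <- rep(FALSE, n)
  for (i in seq_len(n)) {
    seg <- x[starts[i]:(starts[i] + 2L * W - 1L)]
    if (max(abs(seg)) < 1e-3 * peak_all) next
    r <- frame_nccf(seg, W)
    score <- r[(minlag:maxlag) + 1] - cfg$octave_cost * log2((minlag:maxlag) / minlag)
    pk <- interp_peak(c(rep(-Inf, minlag), score), minlag, maxlag)
    # recover the unpenalized correlation height at the chosen lag
    height <- pk[2] + cfg$octave_cost * log2(pk[1] / minlag)
    if (height >= cfg$voicing_threshold) {
      cand <- rate / pk[1]
      if (cand >= cfg$pitch_floor && cand <= cfg$pitch_ceiling) {
        f0[i] <- cand
        voiced[i] <- TRUE
      }
    }
  }
  structure(list(frame_times = (starts - 1 + W) / rate, f0 = f0, voiced = voiced,
                 time_step = cfg$time_step),
            class = "pitch_contour")
}

#' Summary statistics of the fundamental-frequency contour
#'
#' Computes the seven f0 parameters over voiced frames only: mean, sample
#' (n-1) standard deviation, minimum, maximum, range (max minus min), and
#' the start and end values (first and last voiced frames).
#'
#' @param contour A `pitch_contour`.
#' @return Named numeric vector `mean_f0, sd_f0, min_f0, max_f0, range_f0,
#'   start_f0, end_f0` (Hz).
#' @export
summarize_f0 <- function(contour) {
  v <- contour$f0[contour$voiced]
  if (length(v) < 2) stop("need at least 2 voiced frames to summarize f0")
  c(mean_f0 = mean(v), sd_f0 = stats::sd(v), min_f0 = min(v), max_f0 = max(v),
    range_f0 = max(v) - min(v), start_f0 = v[1], end_f0 = v[length(v)])
}

#' Call duration from the voiced span
#'
#' Duration is defined as the time between the first and last voiced pitch
#' frames plus one frame step — a reproducible onset/offset convention that
#' is invariant to silence padding around the call.
#'
#' @param contour A `pitch_contour`.
#' @return Duration in seconds.
#' @export
measure_duration <- function(contour) {
  tv <- contour$frame_times[contour$voiced]
  if (length(tv) < 1) stop("no voiced frames; cannot measure duration")
  (tv[length(tv)] - tv[1]) + contour$time_step
}
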