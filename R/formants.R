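#' Formant analysis settings
#'
#' Defaults follow standard LPC practice for calls with energy below 8 kHz:
#' the signal is resampled to twice `max_formant`, pre-emphasized above
#' 50 Hz, and a Burg autoregressive model of order `2 * max_n_formants` is
#' fitted per 50-ms Gaussian-tapered frame.
#'
#' @param time_step Frame step (s).
#' @param max_n_formants Number of formants sought (model order is twice this).
#' @param max_formant Upper frequency limit (Hz); analysis rate is
#'   `2 * max_formant`.
#' @param window_length Frame length (s).
#' @param pre_emphasis_from First-order pre-emphasis corner frequency (Hz).
#' @param pre_emphasis_passes Number of pre-emphasis passes; each pass adds
#'   +6 dB/octave. The default of 2 (+12 dB/octave) whitens the steep
#'   spectral tilt typical of glottal sources, which otherwise biases
#'   low-order Burg fits of high-pitched calls.
#' @param max_bandwidth Reject formant candidates broader than this (Hz);
#'   above 5 kHz the cutoff grows as 12% of the candidate frequency, since
#'   resonance bandwidths scale roughly with center frequency.
#' @return A `formant_config` list.
#' @export
formant_config <- function(time_step = 0.01, max_n_formants = 5, max_formant = 8000,
                           window_length = 0.05, pre_emphasis_from = 50,
                           pre_emphasis_passes = 2L, max_bandwidth = 400) {
  if (max_n_formants < 4) stop("need max_n_formants >= 4 to report F1-F4")
  structure(list(time_step = time_step, max_n_formants = as.integer(max_n_formants),
                 max_formant = max_formant, window_length = window_length,
                 pre_emphasis_from = pre_emphasis_from,
                 pre_emphasis_passes = as.integer(pre_emphasis_passes),
                 max_bandwidth = max_bandwidth),
            class = "formant_config")
}

# LPC formant candidates of one windowed frame: frequencies/bandwidths (Hz)
# of the complex AR polynomial roots in the upper half unit disc.
frame_formant_candidates <- function(seg, fs, order, max_formant, max_bandwidth) {
  fit <- try(stats::ar(seg, aic = FALSE, order.max = order, method = "burg",
                       demean = TRUE), silent = TRUE)
  if (inherits(fit, "try-error") || length(fit$ar) < order) return(numeric(0))
  roots <- polyroot(c(rev(-fit$ar), 1))
  ang <- Arg(roots)
  keep <- ang > 0 & Mod(roots) < 1
  freq <- ang[keep] * fs / (2 * pi)
  bwid <- -log(Mod(roots[keep])) * fs / pi
  # bandwidth gate is relative above 5 kHz: resonance bandwidths scale
  # roughly with center frequency, and a flat cutoff discards accurate
  # high-frequency formants of short vocal tracts
  ok <- freq > 50 & freq < max_formant - 50 &
    bwid < pmax(max_bandwidth, 0.12 * freq)
  sort(freq[ok])
}

#' Extract mean formant frequencies F1-F4
#'
#' Per-frame Burg linear-predictive analysis: the call is resampled to
#' `2 * max_formant` Hz, pre-emphasized, cut into Gaussian-tapered frames,
#' and each frame's AR polynomial roots give formant candidates; candidates
#' with plausible bandwidth are assigned to F1..F4 lowest-first, and each
#' formant's mean is taken over the frames where it is defined. Frames whose
#' peak amplitude is below 10% of the call's peak are skipped.
#'
#' @param recording A `call_recording` or list with `samples` and `rate`.
#' @param cfg A [formant_config()].
#' @return List with `formants` (named F1..F4 means, Hz) and `tracks`
#'   (frames x 4 matrix of per-frame values, `NA` where undefined).
#' @export
extract_formants <- function(recording, cfg = formant_config()) {
  fs <- 2 * cfg$max_formant
  x <- recording$samples
  if (recording$rate != fs) {
    g <- gcd_int(round(recording$rate), fs)
    x <- signal::resample(x, fs %/% g, round(recording$rate) %/% g)
  }
  a <- exp(-2 * pi * cfg$pre_emphasis_from / fs)
  for (pass in seq_len(cfg$pre_emphasis_passes))
    x <- c(x[1], x[-1] - a * x[-length(x)])
  N <- round(cfg$window_length * fs)
  step <- round(cfg$time_step * fs)
  if (length(x) < N) stop("recording shorter than one formant analysis window")
  w <- exp(-0.5 * ((seq_len(N) - (N + 1) / 2) / (N / 6))^2)
  starts <- seq(1L, length(x) - N + 1L, by = step)
  peak_all <- max(abs(x))
  order <- 2L * cfg$max_n_formants
  tracks <- matrix(NA_real_, nrow = length(starts), ncol = 4)
  used <- 0L
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + N - 1L)]
    if (max(abs(seg)) < 0.1 * peak_all) next
    used <- used + 1L
    cand <- frame_formant_candidates(seg * w, fs, order, cfg$max_formant,
                                     cfg$max_bandwidth)
    if (length(cand) >= 1)
      tracks[i, seq_len(min(4, length(cand)))] <- cand[seq_len(min(4, length(cand)))]
  }
  complete <- sum(stats::complete.cases(tracks))
  if (used == 0 || complete < used / 2)
    stop("fewer than four formants recoverable in more than half the frames",
         if (!is.null(recording$call_id)) paste0(" (", recording$call_id, ")"))
  means <- colMeans(tracks, na.rm = TRUE)
  names(means) <- paste0("F", 1:4)
  list(formants = means, tracks = tracks)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Formant dispersion by zero-intercept regression
#'
#' Under the uniform-tube (closed at the glottis, open at the lips) model,
#' formants sit at `F_k = (2k - 1) * dF / 2`. The dispersion `dF` is the
#' zero-intercept least-squares slope of the measured formants on
#' `x_k = (2k - 1) / 2`: `dF = sum(F_k x_k) / sum(x_k^2)`. `dF` relates to
#' vocal tract length L by `dF = c / (2 L)`.
#'
#' @param F Numeric length-4 vector of formant frequencies (Hz), strictly
#'   increasing.
#' @return Formant dispersion in Hz.
#' @export
estimate_delta_f <- function(F) {
  if (length(F) != 4) stop("need exactly four formant frequencies")
  if (any(diff(F) <= 0)) stop("formant frequencies must be strictly increasing")
  x <- (2 * (1:4) - 1) / 2
  sum(F * x) / sum(x^2)
}
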