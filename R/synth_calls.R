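#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  })
  set.seed(seed)
  code
}

# speed of sound in the warm, humid vocal tract (cm/s)
SPEED_OF_SOUND <- 35000

#' Create an individual caller profile
#'
#' An `individual_profile` collects the production parameters that define one
#' caller under the source-filter model: the glottal source sets the
#' fundamental frequency (f0) and its call-to-call variability, the vocal
#' tract length places the formants on the uniform-tube (closed-open) pattern
#' `F_k = (2k - 1) * dF / 2` with `dF = c / (2 * L)`, and `noise_gain`
#' controls the ratio of aspiration noise to harmonic energy (hence the
#' harmonics-to-noise ratio of the call).
#'
#' @param individual_id Character label, unique within a population.
#' @param mean_f0 Individual mean fundamental frequency (Hz); must lie inside
#'   the analysis pitch window `[75, 1200]` Hz.
#' @param f0_within_sd Call-to-call standard deviation of per-call mean f0 (Hz).
#' @param contour_shape One of `"flat"`, `"fall"`, `"rise"`, `"arc"`.
#' @param contour_depth Modulation depth of the contour as a fraction of
#'   `mean_f0` (coo calls are weakly modulated, so values around 0.03-0.10
#'   are typical).
#' @param vocal_tract_length Vocal tract length in cm (> 0).
#' @param formant_shape_offsets Numeric length-4 additive offsets (Hz) applied
#'   to F1..F4 after uniform-tube placement, representing tract-shape
#'   deviations from the uniform tube.
#' @param formant_within_sd Relative call-to-call jitter SD on each formant.
#' @param mean_duration Mean call duration (s).
#' @param duration_within_cv Call-to-call coefficient of variation of duration.
#' @param noise_gain Linear amplitude ratio of aspiration noise to the
#'   harmonic source (>= 0); 0 gives a noiseless call.
#' @param noise_within_sdlog Log-scale SD of per-call noise-gain jitter.
#' @param n_calls Number of calls to generate for this individual (>= 2).
#' @return An object of class `individual_profile`.
#' @export
individual_profile <- function(individual_id, mean_f0, f0_within_sd = 0.06 * mean_f0,
                               contour_shape = c("arc", "flat", "fall", "rise"),
                               contour_depth = 0.06,
                               vocal_tract_length = 9,
                               formant_shape_offsets = c(0, 0, 0, 0),
                               formant_within_sd = 0.025,
                               mean_duration = 0.45, duration_within_cv = 0.15,
                               noise_gain = 0.08, noise_within_sdlog = 0.2,
                               n_calls = 20L) {
  contour_shape <- match.arg(contour_shape)
  if (mean_f0 < 75 || mean_f0 > 1200)
    stop("mean_f0 must lie in the analysis pitch window [75, 1200] Hz")
  if (vocal_tract_length <= 0) stop("vocal_tract_length must be > 0")
  if (n_calls < 2) stop("n_calls must be >= 2 (a CV needs a standard deviation)")
  if (duration_within_cv < 0) stop("duration_within_cv must be >= 0")
  if (noise_gain < 0) stop("noise_gain must be >= 0")
  if (length(formant_shape_offsets) != 4) stop("formant_shape_offsets must have length 4")
  structure(list(
    individual_id = as.character(individual_id),
    mean_f0 = mean_f0, f0_within_sd = f0_within_sd,
    contour_shape = contour_shape, contour_depth = contour_depth,
    vocal_tract_length = vocal_tract_length,
    formant_shape_offsets = formant_shape_offsets,
    formant_within_sd = formant_within_sd,
    mean_duration = mean_duration, duration_within_cv = duration_within_cv,
    noise_gain = noise_gain, noise_within_sdlog = noise_within_sdlog,
    n_calls = as.integer(n_calls)
  ), class = "individual_profile")
}

#' Uniform-tube formant frequencies for a profile
#'
#' Closed-open tube resonances `F_k = (2k - 1) * dF / 2` with
#' `dF = c / (2 * L)`, `c = 35000` cm/s, plus the profile's shape offsets.
#'
#' @param profile An `individual_profile`.
#' @return Numeric length-4 vector of formant frequencies (Hz).
#' @export
profile_formants <- function(profile) {
  df <- SPEED_OF_SOUND / (2 * profile$vocal_tract_length)
  (2 * (1:4) - 1) * df / 2 + profile$formant_shape_offsets
}

# Baseline caller used by make_population(); separation scales the
# between-individual draws away from this profile.
base_profile <- function(individual_id = "base", within_scale = 1, n_calls = 20L) {
  individual_profile(
    individual_id = individual_id,
    mean_f0 = 350, f0_within_sd = within_scale * 0.06 * 350,
    contour_shape = "arc", contour_depth = 0.06,
    vocal_tract_length = 9,
    formant_within_sd = within_scale * 0.025,
    mean_duration = 0.45, duration_within_cv = within_scale * 0.15,
    noise_gain = 0.08, noise_within_sdlog = within_scale * 0.2,
    n_calls = n_calls
  )
}

#' Build a synthetic caller population
#'
#' Draws `k` caller profiles around a common baseline. Between-individual
#' differences (in mean f0, vocal tract length, formant-shape offsets,
#' duration and noisiness) scale linearly with `separation`; `separation = 0`
#' yields `k` identical profiles (a null population in which no parameter
#' carries identity information). Within-individual call-to-call variation
#' scales with `within_scale`. At `separation = 1` the between-individual
#' relative SDs are roughly those reported for wild adult-male coo calls
#' (about 8% for mean f0, 4% for vocal tract length, 12% for duration).
#'
#' @param k Number of individuals (>= 2).
#' @param separation Non-negative scale of between-individual variation.
#' @param within_scale Positive scale of within-individual variation.
#' @param seed Integer seed; the same seed reproduces the same population.
#' @param n_calls Optional integer vector of per-individual call counts
#'   (recycled to length `k`). By default counts are drawn uniformly from
#'   12..40, mimicking an unbalanced field sample.
#' @param sample_rate Sampling rate for synthesis (Hz). Default 44100.
#' @param bit_depth WAV bit depth. Default 16.
#' @return An object of class `coo_population`: a list with `profiles`,
#'   `sample_rate`, `bit_depth`, `master_seed`.
#' @export
make_population <- function(k, separation = 1, within_scale = 1, seed = 1L,
                            n_calls = NULL, sample_rate = 44100, bit_depth = 16L) {
  if (k < 2) stop("a population needs at least k = 2 individuals")
  if (separation < 0) stop("separation must be >= 0")
  if (within_scale <= 0) stop("within_scale must be > 0")
  profiles <- with_seed(as.integer(seed), {
    counts <- if (is.null(n_calls)) sample(12:40, k, replace = TRUE)
              else rep_len(as.integer(n_calls), k)
    base_F <- profile_formants(base_profile())
    lapply(seq_len(k), function(i) {
      p <- base_profile(sprintf("ID%02d", i), within_scale, counts[i])
      if (separation > 0) {
        p$mean_f0 <- min(1000, max(100, p$mean_f0 * exp(separation * rnorm(1, 0, 0.08))))
        p$f0_within_sd <- within_scale * 0.06 * p$mean_f0
        # keep F4 comfortably below the 8 kHz formant-analysis ceiling, as
        # a field protocol's choice of ceiling implicitly guarantees
        p$vocal_tract_length <- min(12, max(8.7,
          p$vocal_tract_length * exp(separation * rnorm(1, 0, 0.04))))
        p$formant_shape_offsets <- rnorm(4, 0, separation * 0.02 * base_F)
        p$mean_duration <- p$mean_duration * exp(separation * rnorm(1, 0, 0.12))
        p$noise_gain <- p$noise_gain * exp(separation * rnorm(1, 0, 0.4))
        p$contour_shape <- sample(c("flat", "fall", "rise", "arc"), 1)
        p$contour_depth <- runif(1, 0.03, 0.10)
      }
      p
    })
  })
  structure(list(profiles = profiles, sample_rate = sample_rate,
                 bit_depth = as.integer(bit_depth), master_seed = as.integer(seed)),
            class = "coo_population")
}

# Contour basis functions, each with zero mean on [0, 1] so that the
# realized contour averages to the drawn per-call mean f0.
contour_basis <- function(shape, u) {
  switch(shape,
    flat = rep(0, length(u)),
    fall = 0.5 - u,
    rise = u - 0.5,
    arc  = sin(pi * u) - 2 / pi,
    stop("unknown contour shape: ", shape))
}

#' Draw the realized production parameters of one call
#'
#' Samples the call-level parameters (duration, per-call mean f0, f0 contour
#' at 10-ms frames, formants, noise gain) from an individual profile. The
#' contour includes a small smooth random drift (about 0.4% of f0) standing
#' in for vocal jitter, so even "flat" calls have a nonzero f0 SD, as real
#' tracked contours do. This function is the single source of ground truth
#' shared by the audio synthesizer and the feature-level simulator.
#'
#' @param profile An `individual_profile`.
#' @param call_seed Integer seed for this call.
#' @param time_step Frame step (s) at which the true contour is realized.
#' @return A list of realized parameters, including the frame-wise `f0`
#'   contour, `formants`, `delta_f`, `duration` and `noise_gain`.
#' @export
draw_call_params <- function(profile, call_seed, time_step = 0.01) {
  with_seed(as.integer(call_seed), {
    dur_sdlog <- sqrt(log(1 + profile$duration_within_cv^2))
    duration <- profile$mean_duration * exp(rnorm(1, -dur_sdlog^2 / 2, dur_sdlog))
    duration <- max(duration, 0.12)
    m <- profile$mean_f0 * exp(rnorm(1, 0, profile$f0_within_sd / profile$mean_f0))
    depth <- profile$contour_depth * runif(1, 0.8, 1.2)
    drift_amp <- 0.004
    drift_phase <- runif(1, 0, 2 * pi)
    ft <- seq(0, duration, by = time_step)
    u <- ft / duration
    f0 <- m * (1 + depth * contour_basis(profile$contour_shape, u)) *
      (1 + drift_amp * sin(2 * pi * u + drift_phase))
    clipped <- f0 < 75 | f0 > 1200
    if (any(clipped)) {
      warning("f0 contour left [75, 1200] Hz for ", profile$individual_id,
              "; clipping to the analysis pitch window")
      f0 <- pmin(1200, pmax(75, f0))
    }
    formants <- profile_formants(profile) *
      exp(rnorm(4, 0, profile$formant_within_sd))
    formants <- sort(formants)
    g <- profile$noise_gain * exp(rnorm(1, 0, profile$noise_within_sdlog))
    list(
      individual_id = profile$individual_id,
      duration = duration, frame_times = ft, f0 = f0,
      mean_f0 = mean(f0), sd_f0 = stats::sd(f0),
      min_f0 = min(f0), max_f0 = max(f0),
      start_f0 = f0[1], end_f0 = f0[length(f0)],
      formants = formants, delta_f = estimate_delta_f(formants),
      noise_gain = g
    )
  })
}

# One second-order resonator (two-pole) section.
resonate <- function(x, freq, bw, rate) {
  r <- exp(-pi * bw / rate)
  theta <- 2 * pi * freq / rate
  as.numeric(stats::filter(x, c(2 * r * cos(theta), -r^2), method = "recursive"))
}

#' Synthesize one coo-like call
#'
#' Renders a call by the source-filter model: an additive, band-limited
#' harmonic source following the call's f0 contour with a -12 dB/octave
#' spectral tilt (harmonic amplitudes 1/h^2), plus broadband aspiration
#' noise at the profile's noise gain; both pass through a cascade of
#' second-order resonators at the call's formant frequencies F1-F4, plus
#' the fifth and sixth resonances of the uniform tube (a real tract's
#' resonance series does not stop at F4, and truncating it there leaves an
#' unphysical spectral hole above F4 that biases formant measurement). A
#' raised-cosine onset/offset ramp is applied and the waveform is
#' peak-normalized to 0.9.
#'
#' @param profile An `individual_profile`.
#' @param call_seed Integer seed; the same seed reproduces the same samples.
#' @param rate Sampling rate (Hz); must be at least twice the highest formant.
#' @param call_id Optional call label stored in the result.
#' @return A `call_recording`: list with `samples`, `rate`, `individual_id`,
#'   `call_id`, `seed`, and `true_params` (the realized generating
#'   parameters, for recovery tests).
#' @export
synthesize_call <- function(profile, call_seed, rate = 44100, call_id = NULL) {
  params <- draw_call_params(profile, call_seed)
  if (rate < 2 * (11 / 2) * SPEED_OF_SOUND / (2 * profile$vocal_tract_length) ||
      rate < 2 * max(params$formants))
    stop("sampling rate must be at least twice the highest synthesized resonance")
  n <- round(params$duration * rate)
  tt <- (0:(n - 1)) / rate
  # per-sample f0 by linear interpolation of the frame-wise true contour
  f0s <- stats::approx(params$frame_times, params$f0, xout = tt, rule = 2)$y
  phase <- 2 * pi * cumsum(f0s) / rate
  nh <- max(1L, floor(0.45 * rate / max(f0s)))
  nh <- min(nh, floor(12000 / max(f0s)))  # coo energy is concentrated below ~12 kHz
  src <- rep(0, n)
  for (h in seq_len(nh)) src <- src + sin(h * phase) / h^2
  sig <- src
  if (params$noise_gain > 0) {
    noise <- with_seed(as.integer(call_seed) + 1000003L, rnorm(n))
    noise <- noise * params$noise_gain * sqrt(mean(src^2)) / sqrt(mean(noise^2))
    sig <- sig + noise
  }
  df <- SPEED_OF_SOUND / (2 * profile$vocal_tract_length)
  res_freqs <- c(params$formants, (2 * (5:6) - 1) * df / 2)
  bw <- pmax(80, 0.02 * res_freqs)
  for (k in seq_along(res_freqs)) sig <- resonate(sig, res_freqs[k], bw[k], rate)
  ramp_n <- round(min(0.03, params$duration / 4) * rate)
  env <- rep(1, n)
  ramp <- 0.5 - 0.5 * cos(pi * seq_len(ramp_n) / ramp_n)
  env[seq_len(ramp_n)] <- ramp
  env[n + 1 - seq_len(ramp_n)] <- ramp
  sig <- sig * env
  sig <- 0.9 * sig / max(abs(sig))
  structure(list(samples = sig, rate = rate,
                 individual_id = profile$individual_id,
                 call_id = call_id, seed = as.integer(call_seed),
                 true_params = params),
            class = "call_recording")
}

# Deterministic per-call seeds derived from a master seed (kept < 2^31).
derive_call_seeds <- function(master_seed, n) {
  with_seed(as.integer(master_seed), sample.int(.Machine$integer.max - 1L, n))
}

#' Generate a labelled synthetic call dataset on disk
#'
#' Writes one mono WAV per call plus a `manifest.csv` mapping files to caller
#' identities, call seeds and the true generating parameters.
#'
#' @param config A `coo_population` from [make_population()].
#' @param output_dir Directory to write into (created if needed).
#' @param overwrite Overwrite an existing manifest? Default `FALSE`.
#' @return The manifest as a data.frame, invisibly; columns
#'   `file,individual_id,call_id,seed,true_mean_f0,true_F1..true_F4,
#'   true_deltaF,true_duration,noise_gain`.
#' @export
generate_dataset <- function(config, output_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "coo_population"))
  if (length(config$profiles) == 0) stop("population has no profiles")
  manifest_path <- file.path(output_dir, "manifest.csv")
  if (file.exists(manifest_path) && !overwrite)
    stop("manifest already exists (use overwrite = TRUE): ", manifest_path)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  total <- sum(vapply(config$profiles, `[[`, integer(1), "n_calls"))
  seeds <- derive_call_seeds(config$master_seed, total)
  rows <- vector("list", total)
  idx <- 0L
  for (p in config$profiles) {
    for (j in seq_len(p$n_calls)) {
      idx <- idx + 1L
      call_id <- sprintf("%s_%03d", p$individual_id, j)
      rec <- synthesize_call(p, seeds[idx], rate = config$sample_rate, call_id = call_id)
      fname <- paste0(call_id, ".wav")
      write_wav(rec$samples, rec$rate, file.path(output_dir, fname),
                bit = config$bit_depth)
      tp <- rec$true_params
      rows[[idx]] <- data.frame(
        file = fname, individual_id = p$individual_id, call_id = call_id,
        seed = seeds[idx], true_mean_f0 = tp$mean_f0,
        true_F1 = tp$formants[1], true_F2 = tp$formants[2],
        true_F3 = tp$formants[3], true_F4 = tp$formants[4],
        true_deltaF = tp$delta_f, true_duration = tp$duration,
        noise_gain = tp$noise_gain
      )
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest)
}

#' Simulate a feature table directly from a population model
#'
#' Draws the same per-call true parameters as the audio path (via
#' [draw_call_params()]) and maps them straight to the 14-parameter feature
#' space, bypassing waveform rendering and acoustic measurement. This is the
#' fast path for statistical calibration experiments (null-distribution and
#' PIC behavior over many replicate populations) where measurement error is
#' not the quantity under study. The HNR column is the noise-budget value
#' implied by the realized noise gain, `-20 log10(noise_gain)` dB (capped at
#' 40 dB for near-noiseless calls).
#'
#' @param config A `coo_population`.
#' @return A `feature_table` data.frame (see [read_feature_table()] for the
#'   column layout).
#' @export
simulate_feature_table <- function(config) {
  stopifnot(inherits(config, "coo_population"))
  total <- sum(vapply(config$profiles, `[[`, integer(1), "n_calls"))
  seeds <- derive_call_seeds(config$master_seed, total)
  rows <- vector("list", total)
  idx <- 0L
  for (p in config$profiles) {
    for (j in seq_len(p$n_calls)) {
      idx <- idx + 1L
      tp <- draw_call_params(p, seeds[idx])
      hnr <- min(40, -20 * log10(max(tp$noise_gain, 1e-4)))
      rows[[idx]] <- data.frame(
        call_id = sprintf("%s_%03d", p$individual_id, j),
        individual_id = p$individual_id,
        duration = tp$duration, mean_f0 = tp$mean_f0, sd_f0 = tp$sd_f0,
        max_f0 = tp$max_f0, min_f0 = tp$min_f0,
        range_f0 = tp$max_f0 - tp$min_f0,
        start_f0 = tp$start_f0, end_f0 = tp$end_f0, hnr = hnr,
        F1 = tp$formants[1], F2 = tp$formants[2],
        F3 = tp$formants[3], F4 = tp$formants[4],
        delta_f = tp$delta_f
      )
    }
  }
  tab <- do.call(rbind, rows)
  class(tab) <- c("feature_table", "data.frame")
  tab
}
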