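FEATURE_NAMES <- c("duration", "mean_f0", "sd_f0", "max_f0", "min_f0",
                   "range_f0", "start_f0", "end_f0", "hnr",
                   "F1", "F2", "F3", "F4", "delta_f")

#' Extract the 14 acoustic parameters of one call
#'
#' Runs pitch tracking, f0 summarization, duration measurement, formant
#' estimation, formant-dispersion regression and harmonicity analysis on one
#' recording and returns the standard 14-parameter record: duration; mean,
#' SD, max, min, range, start and end f0; HNR; F1-F4; and formant dispersion.
#'
#' @param recording A `call_recording` (or list with `samples`, `rate`, and
#'   optionally `individual_id`/`call_id`).
#' @param pitch_cfg,formant_cfg,hnr_cfg Analysis settings; see
#'   [pitch_config()], [formant_config()], [hnr_config()].
#' @return A one-row data.frame with `call_id`, `individual_id` and the 14
#'   parameters.
#' @export
extract_features <- function(recording, pitch_cfg = pitch_config(),
                             formant_cfg = formant_config(),
                             hnr_cfg = hnr_config()) {
  label <- if (!is.null(recording$call_id)) recording$call_id else "call"
  res <- tryCatch({
    contour <- extract_pitch(recording, pitch_cfg)
    if (!any(contour$voiced)) stop("no voiced frames found")
    f0s <- summarize_f0(contour)
    dur <- measure_duration(contour)
    fmt <- extract_formants(recording, formant_cfg)$formants
    df <- estimate_delta_f(fmt)
    hnr <- compute_hnr(recording, hnr_cfg)
    data.frame(
      call_id = label,
      individual_id = if (!is.null(recording$individual_id))
        recording$individual_id else NA_character_,
      duration = dur,
      mean_f0 = f0s[["mean_f0"]], sd_f0 = f0s[["sd_f0"]],
      max_f0 = f0s[["max_f0"]], min_f0 = f0s[["min_f0"]],
      range_f0 = f0s[["range_f0"]],
      start_f0 = f0s[["start_f0"]], end_f0 = f0s[["end_f0"]],
      hnr = hnr,
      F1 = fmt[["F1"]], F2 = fmt[["F2"]], F3 = fmt[["F3"]], F4 = fmt[["F4"]],
      delta_f = df
    )
  }, error = function(e) stop("feature extraction failed for '", label, "': ",
                              conditionMessage(e), call. = FALSE))
  res
}

#' Extract a feature table from a dataset manifest
#'
#' Reads each WAV listed in a manifest (as written by [generate_dataset()]),
#' extracts its 14 parameters, and stacks them into a `feature_table`.
#' Calls on which extraction fails are excluded and reported, mirroring the
#' quality screening step of field studies; the exclusions are attached as
#' the `"excluded"` attribute.
#'
#' @param manifest Data.frame with columns `file` and `individual_id` (and
#'   optionally `call_id`), or the path of such a CSV.
#' @param audio_dir Directory holding the WAV files; defaults to the
#'   manifest's directory when `manifest` is a path.
#' @param pitch_cfg,formant_cfg,hnr_cfg Analysis settings.
#' @return A `feature_table` data.frame, one row per successfully analysed
#'   call.
#' @export
extract_feature_table <- function(manifest, audio_dir = NULL,
                                  pitch_cfg = pitch_config(),
                                  formant_cfg = formant_config(),
                                  hnr_cfg = hnr_config()) {
  if (is.character(manifest)) {
    if (is.null(audio_dir)) audio_dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (is.null(audio_dir)) stop("audio_dir is required when manifest is a data.frame")
  rows <- list()
  excluded <- character(0)
  for (i in seq_len(nrow(manifest))) {
    wav <- read_wav(file.path(audio_dir, manifest$file[i]))
    rec <- list(samples = wav$samples, rate = wav$rate,
                individual_id = manifest$individual_id[i],
                call_id = if ("call_id" %in% names(manifest)) manifest$call_id[i]
                          else manifest$file[i])
    row <- tryCatch(
      extract_features(rec, pitch_cfg, formant_cfg, hnr_cfg),
      error = function(e) {
        warning(conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(row)) excluded <- c(excluded, rec$call_id)
    else rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0) stop("no call could be analysed")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  class(tab) <- c("feature_table", "data.frame")
  attr(tab, "excluded") <- excluded
  tab
}

#' Read or validate a feature table
#'
#' A feature table has one row per call with columns `call_id`,
#' `individual_id` and the 14 acoustic parameters
#' `duration, mean_f0, sd_f0, max_f0, min_f0, range_f0, start_f0, end_f0,
#' hnr, F1, F2, F3, F4, delta_f`.
#'
#' @param x Path of a feature CSV, or a data.frame with those columns.
#' @return A validated `feature_table` data.frame.
#' @export
read_feature_table <- function(x) {
  if (is.character(x)) x <- utils::read.csv(x, stringsAsFactors = FALSE)
  need <- c("individual_id", FEATURE_NAMES)
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("feature table is missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyNA(x[, FEATURE_NAMES])) stop("feature table contains missing values")
  counts <- table(x$individual_id)
  if (length(counts) < 2) stop("feature table needs at least 2 individuals")
  if (any(counts < 2)) stop("every individual needs at least 2 calls")
  class(x) <- c("feature_table", "data.frame")
  x
}

#' Write a feature table to CSV
#'
#' @param table A `feature_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
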