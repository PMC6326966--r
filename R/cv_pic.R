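#' Small-sample corrected coefficient of variation
#'
#' `CV = 100 * (1 + 1/(4n)) * SD / mean`, where SD is the sample (n-1)
#' standard deviation. The `(1 + 1/(4n))` factor corrects the downward bias
#' of the CV in small samples.
#'
#' @param values Numeric vector, length >= 2, with nonzero mean.
#' @return The corrected CV in percent.
#' @export
corrected_cv <- function(values) {
  n <- length(values)
  if (n < 2) stop("CV needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean")
  100 * (1 + 1 / (4 * n)) * stats::sd(values) / m
}

#' Within/between CVs and the potential for individual identity coding
#'
#' For each acoustic parameter, computes the within-individual CV for every
#' individual, their unweighted mean (`mean_cv_w`), a between-individual CV
#' (`cv_b`), and `PIC = cv_b / mean_cv_w`. A PIC above 1 marks a parameter
#' that varies more between than within individuals, i.e. one with potential
#' to encode caller identity. `cv_b` is computed either over all calls
#' pooled (default) or over the per-individual means.
#'
#' @param table A `feature_table`.
#' @param between_mode `"pooled_calls"` (default) or `"individual_means"`.
#' @return A `pic_report` data.frame with columns `parameter, mean_cv_w,
#'   cv_b, pic`; PIC is `NA` (with a warning) for a parameter whose
#'   within-individual SD is zero for some individual.
#' @export
pic_table <- function(table, between_mode = c("pooled_calls", "individual_means")) {
  between_mode <- match.arg(between_mode)
  table <- read_feature_table(table)
  ids <- unique(table$individual_id)
  out <- lapply(FEATURE_NAMES, function(p) {
    vals <- table[[p]]
    cvw <- vapply(ids, function(id) {
      v <- vals[table$individual_id == id]
      if (stats::sd(v) == 0) NA_real_ else corrected_cv(v)
    }, numeric(1))
    cvb <- switch(between_mode,
      pooled_calls = corrected_cv(vals),
      individual_means = corrected_cv(vapply(ids, function(id)
        mean(vals[table$individual_id == id]), numeric(1))))
    mcw <- if (anyNA(cvw)) NA_real_ else mean(cvw)
    if (is.na(mcw))
      warning("PIC undefined for '", p, "': zero within-individual SD")
    data.frame(parameter = p, mean_cv_w = mcw, cv_b = cvb,
               pic = cvb / mcw)
  })
  out <- do.call(rbind, out)
  class(out) <- c("pic_report", "data.frame")
  attr(out, "between_mode") <- between_mode
  out
}

#' Kruskal-Wallis screen for one parameter
#'
#' Rank-based test of whether a parameter differs among individuals
#' (chi-square approximation with k-1 degrees of freedom, tie-corrected).
#'
#' @param table A `feature_table`.
#' @param parameter One of the 14 parameter names.
#' @return List with `chi2`, `df`, `p_value`.
#' @export
kw_screen <- function(table, parameter) {
  table <- read_feature_table(table)
  if (!parameter %in% FEATURE_NAMES) stop("unknown parameter: ", parameter)
  vals <- table[[parameter]]
  if (length(unique(vals)) == 1) stop("all values identical; ranks degenerate")
  kt <- stats::kruskal.test(vals, factor(table$individual_id))
  list(chi2 = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Pairwise Mann-Whitney comparisons for one parameter
#'
#' Tests all `k(k-1)/2` unordered pairs of individuals two-tailed with the
#' Mann-Whitney (Wilcoxon rank-sum) U test; a pair is flagged as detected
#' when its p-value falls below the Bonferroni-adjusted level
#' `family_alpha / n_pairs`. P-values are exact for small tie-free groups
#' (both sizes <= 8) and use the normal approximation with continuity and
#' tie correction otherwise.
#'
#' @param table A `feature_table`.
#' @param parameter One of the 14 parameter names.
#' @param family_alpha Family-wise significance level (default 0.05).
#' @return List with `pairs` (data.frame: `a, b, U, p_value, detected`),
#'   `n_pairs`, `adjusted_alpha`, and `detected` (character vector
#'   `"A-B"` of flagged pairs).
#' @export
pairwise_mwu <- function(table, parameter, family_alpha = 0.05) {
  table <- read_feature_table(table)
  if (!parameter %in% FEATURE_NAMES) stop("unknown parameter: ", parameter)
  ids <- sort(unique(table$individual_id))
  k <- length(ids)
  n_pairs <- k * (k - 1) / 2
  adj <- family_alpha / n_pairs
  combs <- utils::combn(ids, 2)
  rows <- lapply(seq_len(ncol(combs)), function(j) {
    a <- combs[1, j]; b <- combs[2, j]
    va <- table[[parameter]][table$individual_id == a]
    vb <- table[[parameter]][table$individual_id == b]
    exact <- length(va) <= 8 && length(vb) <= 8 &&
      !any(duplicated(c(va, vb)))
    wt <- suppressWarnings(stats::wilcox.test(va, vb, exact = exact,
                                              correct = TRUE))
    data.frame(a = a, b = b, U = unname(wt$statistic), p_value = wt$p.value,
               detected = wt$p.value < adj)
  })
  pairs <- do.call(rbind, rows)
  list(pairs = pairs, n_pairs = n_pairs, adjusted_alpha = adj,
       detected = paste(pairs$a[pairs$detected], pairs$b[pairs$detected],
                        sep = "-"))
}

#' Full nonparametric screening across all 14 parameters
#'
#' Runs the Kruskal-Wallis test on every parameter and, for parameters
#' significant at `alpha`, the pairwise Mann-Whitney comparisons at the
#' Bonferroni-adjusted level.
#'
#' @param table A `feature_table`.
#' @param alpha Significance level for the Kruskal-Wallis gate (default 0.05).
#' @param family_alpha Family-wise level for the pairwise tests.
#' @return Data.frame with `parameter, chi2, p_value, detected_pairs`
#'   (pairs serialized `"A-B;C-D"`; empty when the gate is not passed).
#' @export
screen_parameters <- function(table, alpha = 0.05, family_alpha = 0.05) {
  table <- read_feature_table(table)
  rows <- lapply(FEATURE_NAMES, function(p) {
    kw <- kw_screen(table, p)
    det <- ""
    if (kw$p_value < alpha) {
      mwu <- pairwise_mwu(table, p, family_alpha)
      det <- paste(mwu$detected, collapse = ";")
    }
    data.frame(parameter = p, chi2 = kw$chi2, p_value = kw$p_value,
               detected_pairs = det)
  })
  do.call(rbind, rows)
}
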