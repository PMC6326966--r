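#' Standardized principal component analysis with eigenvalue retention
#'
#' Z-score standardizes every parameter, eigendecomposes the correlation
#' matrix, retains the components whose eigenvalue exceeds
#' `eigen_threshold` (a relaxed Kaiser criterion; 0.6 by default), and
#' varimax-rotates the retained loadings. Mixed-unit acoustic parameters
#' make the correlation (not covariance) matrix the appropriate basis.
#'
#' @param table A `feature_table`.
#' @param eigen_threshold Retain components with eigenvalue above this.
#' @return A `pca_model`: standardization `means`/`sds`, all `eigenvalues`,
#'   `n_retained`, rotated `loadings` (14 x retained), the score-coefficient
#'   matrix `score_coef` (regression method), `scores` for the input calls,
#'   `labels`, and `cum_variance_pct` of the retained set.
#' @export
fit_pca <- function(table, eigen_threshold = 0.6) {
  table <- read_feature_table(table)
  X <- as.matrix(table[, FEATURE_NAMES])
  if (nrow(X) <= ncol(X)) stop("need more calls than parameters for PCA")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("degenerate correlation matrix: constant parameter ",
                          paste(FEATURE_NAMES[sds == 0], collapse = ", "))
  means <- colMeans(X)
  Z <- scale(X, center = means, scale = sds)
  R <- stats::cor(X)
  ei <- eigen(R, symmetric = TRUE)
  retained <- sum(ei$values > eigen_threshold)
  if (retained < 1) stop("no eigenvalue exceeds the retention threshold")
  L <- ei$vectors[, seq_len(retained), drop = FALSE] %*%
    diag(sqrt(ei$values[seq_len(retained)]), retained)
  L <- rotate_varimax(L)
  rownames(L) <- FEATURE_NAMES
  colnames(L) <- paste0("PC", seq_len(retained))
  # regression-method component scores from the rotated loadings; the
  # correlation matrix is rank-deficient by construction (range f0 is an
  # exact linear combination of max and min f0), so use its pseudo-inverse
  pos <- ei$values > 1e-8 * ei$values[1]
  Rpinv <- ei$vectors[, pos, drop = FALSE] %*%
    (t(ei$vectors[, pos, drop = FALSE]) / ei$values[pos])
  W <- Rpinv %*% L
  scores <- Z %*% W
  structure(list(means = means, sds = sds, eigenvalues = ei$values,
                 n_retained = retained, loadings = L, score_coef = W,
                 scores = scores, labels = table$individual_id,
                 cum_variance_pct = 100 * sum(ei$values[seq_len(retained)]) /
                   length(ei$values)),
            class = "pca_model")
}

#' Varimax rotation of a loading matrix
#'
#' Orthogonal rotation maximizing the varimax simplicity criterion (with
#' Kaiser row normalization), as used to aid component interpretation after
#' retention. A single-column matrix is returned unchanged: there is
#' nothing to rotate. Row communalities are preserved exactly, since the
#' rotation is orthogonal.
#'
#' @param L Numeric loading matrix (variables x components).
#' @return The rotated loading matrix.
#' @export
rotate_varimax <- function(L) {
  if (ncol(L) < 2) return(L)
  vm <- stats::varimax(L, normalize = TRUE, eps = 1e-8)
  L %*% vm$rotmat
}

#' Kolmogorov-Smirnov normality check of component scores
#'
#' One-sample KS test of each score column against a normal distribution
#' with that column's sample mean and SD. Reported for transparency only;
#' nothing downstream is gated on it.
#'
#' @param scores Numeric matrix of component scores (>= 5 rows).
#' @return Named numeric vector of per-component p-values.
#' @export
ks_normality <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 5) stop("need at least 5 scores per component")
  apply(scores, 2, function(v)
    suppressWarnings(stats::ks.test(v, "pnorm", mean(v), stats::sd(v)))$p.value)
}

#' Fit a linear discriminant model on component scores
#'
#' Classical DFA with a pooled within-class covariance: canonical functions
#' come from the eigenproblem of within^-1 x between, and classification
#' uses the linear Gaussian discriminant score with class priors taken from
#' the observed group sizes (default, appropriate for unbalanced call
#' counts) or uniform. A small ridge (`1e-8 x mean diagonal`) is added to
#' the pooled covariance before inversion so that near-singular folds at
#' toy sample sizes remain solvable.
#'
#' @param scores Numeric matrix (calls x components).
#' @param labels Class (individual) label per row.
#' @param priors `"observed"` or `"uniform"`.
#' @return A `dfa_model`: class `levels`, `priors`, class `means`, pooled
#'   covariance `cov_pooled`, canonical `eigenvalues` and
#'   `variance_pct` per function, and `n_functions = min(k - 1, p)`.
#' @export
fit_dfa <- function(scores, labels, priors = c("observed", "uniform")) {
  priors <- match.arg(priors)
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  k <- length(lev)
  n <- nrow(scores)
  p <- ncol(scores)
  if (k < 2) stop("need at least two classes")
  counts <- vapply(lev, function(l) sum(labels == l), numeric(1))
  if (any(counts < 2)) stop("every class needs at least 2 cases")
  M <- do.call(rbind, lapply(lev, function(l)
    colMeans(scores[labels == l, , drop = FALSE])))
  Sw <- matrix(0, p, p)
  for (i in seq_len(k)) {
    d <- sweep(scores[labels == lev[i], , drop = FALSE], 2, M[i, ])
    Sw <- Sw + crossprod(d)
  }
  Sw <- Sw / (n - k)
  Sw <- Sw + diag(1e-8 * sum(diag(Sw)) / p, p)
  mu <- colMeans(scores)
  Sb <- matrix(0, p, p)
  for (i in seq_len(k)) Sb <- Sb + counts[i] * tcrossprod(M[i, ] - mu)
  Sb <- Sb / (n - k)
  ev <- eigen(solve(Sw, Sb))
  nf <- min(k - 1, p)
  eigvals <- Re(ev$values)[seq_len(nf)]
  pri <- if (priors == "observed") counts / n else rep(1 / k, k)
  structure(list(levels = lev, priors = pri, counts = counts, means = M,
                 cov_pooled = Sw, eigenvalues = eigvals,
                 variance_pct = 100 * eigvals / sum(eigvals),
                 n_functions = nf, prior_mode = priors),
            class = "dfa_model")
}

# Class predictions of a fitted dfa_model for a score matrix. Maximum
# posterior under the shared-covariance Gaussian model; ties go to the
# first class in level order.
predict_dfa <- function(model, scores) {
  scores <- as.matrix(scores)
  Sinv <- solve(model$cov_pooled)
  A <- Sinv %*% t(model$means)                             # p x k
  const <- -0.5 * colSums(t(model$means) * A) + log(model$priors)
  delta <- scores %*% A + matrix(const, nrow(scores), length(const), byrow = TRUE)
  model$levels[apply(delta, 1, which.max)]
}

#' Confusion matrix of true versus predicted labels
#'
#' @param true,predicted Character vectors of equal length.
#' @param levels Optional ordered class labels.
#' @return A k x k integer matrix (rows = true, columns = predicted) of
#'   class `confusion_matrix`.
#' @export
confusion_matrix <- function(true, predicted, levels = sort(unique(true))) {
  cm <- table(factor(true, levels = levels), factor(predicted, levels = levels))
  m <- matrix(as.integer(cm), nrow = length(levels),
              dimnames = list(true = levels, predicted = levels))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Resubstitution classification of the training data
#'
#' @param model A `dfa_model`.
#' @param scores,labels The data to classify (typically the training set).
#' @return A `confusion_matrix`.
#' @export
classify <- function(model, scores, labels) {
  confusion_matrix(as.character(labels), predict_dfa(model, scores),
                   levels = model$levels)
}

#' Leave-one-out cross-validated classification
#'
#' Each call is classified by a discriminant model refitted on all other
#' calls (class means, pooled covariance and observed priors are all
#' recomputed per fold; the upstream standardization and PCA are fixed,
#' matching the usual practice of running PCA once and cross-validating
#' inside the DFA only). A fold that would empty a class is skipped with a
#' warning.
#'
#' @param scores Numeric matrix (calls x components).
#' @param labels Class label per row.
#' @param priors `"observed"` or `"uniform"`.
#' @return A `confusion_matrix` over the classified calls.
#' @export
loocv <- function(scores, labels, priors = c("observed", "uniform")) {
  priors <- match.arg(priors)
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  n <- nrow(scores)
  pred <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (sum(labels[-i] == labels[i]) < 2) {
      warning("fold ", i, " would leave class '", labels[i],
              "' with fewer than 2 cases; skipped")
      next
    }
    m <- fit_dfa(scores[-i, , drop = FALSE], labels[-i], priors = priors)
    pred[i] <- predict_dfa(m, scores[i, , drop = FALSE])
  }
  keep <- !is.na(pred)
  confusion_matrix(labels[keep], pred[keep], levels = lev)
}

#' Correct-classification rate of a confusion matrix
#'
#' @param cm A square count matrix (rows = true, columns = predicted).
#' @return Percent of cases on the diagonal, `100 * trace / total`.
#' @export
accuracy <- function(cm) {
  cm <- unclass(cm)
  if (sum(cm) == 0) stop("empty confusion matrix")
  100 * sum(diag(cm)) / sum(cm)
}

#' Chance classification level for k classes
#'
#' @param k Number of classes (>= 2).
#' @return `100 / k` percent.
#' @export
chance_level <- function(k) {
  if (k < 2) stop("need at least 2 classes")
  100 / k
}

#' One-sided exact binomial test against chance
#'
#' Upper-tail probability `P[X >= correct]` for
#' `X ~ Binomial(total, p0)` — the evidence that a classifier beats the
#' chance rate `p0`.
#'
#' @param correct Number of correctly classified cases.
#' @param total Total cases.
#' @param p0 Chance success probability.
#' @return The one-sided p-value.
#' @export
binomial_vs_chance <- function(correct, total, p0) {
  if (correct < 0 || correct > total) stop("need 0 <= correct <= total")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  stats::binom.test(correct, total, p = p0, alternative = "greater")$p.value
}

#' PCA-DFA individual distinctiveness analysis
#'
#' The full discrimination stage: standardized PCA with eigenvalue
#' retention and varimax rotation, KS normality check of the component
#' scores, prior-adjusted DFA on the scores, resubstitution and
#' leave-one-out confusion matrices, accuracies, and the one-sided binomial
#' test of the cross-validated accuracy against chance.
#'
#' @param table A `feature_table`.
#' @param eigen_threshold Component retention threshold (default 0.6).
#' @param priors `"observed"` or `"uniform"`.
#' @return A `dfa_result` list: `pca`, `ks_p`, `dfa`, `confusion_resub`,
#'   `confusion_loocv`, `accuracy_resub`, `accuracy_loocv`, `chance_pct`,
#'   `binomial_p`.
#' @export
discriminate <- function(table, eigen_threshold = 0.6,
                         priors = c("observed", "uniform")) {
  priors <- match.arg(priors)
  pca <- fit_pca(table, eigen_threshold)
  ks_p <- ks_normality(pca$scores)
  dfa <- fit_dfa(pca$scores, pca$labels, priors = priors)
  cm_r <- classify(dfa, pca$scores, pca$labels)
  cm_cv <- loocv(pca$scores, pca$labels, priors = priors)
  k <- length(dfa$levels)
  structure(list(
    pca = pca, ks_p = ks_p, dfa = dfa,
    confusion_resub = cm_r, confusion_loocv = cm_cv,
    accuracy_resub = accuracy(cm_r), accuracy_loocv = accuracy(cm_cv),
    chance_pct = chance_level(k),
    binomial_p = binomial_vs_chance(sum(diag(unclass(cm_cv))), sum(cm_cv), 1 / k)
  ), class = "dfa_result")
}
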