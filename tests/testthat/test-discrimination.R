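test_that("PCA on independent unit-variance parameters retains most components", {
  tab <- random_table(500, c("A", "B"), seed = 40)
  m <- fit_pca(tab)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  expect_gte(m$n_retained, 12)
  expect_true(all(abs(m$eigenvalues - 1) < 0.3))
})

test_that("a duplicated parameter concentrates shared variance in one component", {
  tab <- random_table(300, c("A", "B"), seed = 41)
  tab$end_f0 <- tab$start_f0
  m <- fit_pca(tab)
  expect_gte(m$eigenvalues[1], 1.8)
})

test_that("degenerate inputs to PCA raise clear errors", {
  tab <- random_table(100, c("A", "B"), seed = 42)
  tab$hnr <- 5
  expect_error(fit_pca(tab), "constant parameter hnr")
  tab2 <- random_table(100, c("A", "B"), seed = 43)
  expect_error(fit_pca(tab2, eigen_threshold = 100), "no eigenvalue exceeds")
  expect_error(fit_pca(random_table(10, c("A", "B"), seed = 44)),
               "more calls than parameters")
})

test_that("varimax rotation preserves communalities and improves the criterion", {
  set.seed(50)
  L <- matrix(rnorm(18), 6, 3)
  R <- rotate_varimax(L)
  expect_equal(rowSums(R^2), rowSums(L^2), tolerance = 1e-10)
  # varimax criterion under Kaiser row normalization, as the rotation uses
  vcrit <- function(M) {
    M <- M / sqrt(rowSums(M^2))
    sum(apply(M^2, 2, function(c2) mean(c2^2) - mean(c2)^2))
  }
  expect_gte(vcrit(R), vcrit(L) - 1e-10)
  # 2-component case against a brute-force grid over rotation angles
  L2 <- matrix(rnorm(12), 6, 2)
  R2 <- rotate_varimax(L2)
  grid <- sapply(seq(0, pi / 2, length.out = 2000), function(a) {
    G <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
    vcrit(L2 %*% G)
  })
  expect_gte(vcrit(R2), max(grid) - 1e-4)
  # simple structure is already a fixed point (up to sign/permutation)
  S <- rbind(diag(3), diag(3)) * 0.9
  RS <- rotate_varimax(S)
  expect_equal(sort(round(abs(RS), 6)), sort(round(abs(S), 6)), tolerance = 1e-4)
  expect_identical(rotate_varimax(L[, 1, drop = FALSE]), L[, 1, drop = FALSE])
})

test_that("KS normality check flags non-normal component scores", {
  set.seed(51)
  flags <- replicate(100, ks_normality(matrix(rnorm(200), ncol = 1)) > 0.05)
  expect_gte(mean(flags), 0.9)
  set.seed(52)
  two_point <- matrix(sample(c(0, 1), 200, replace = TRUE), ncol = 1)
  expect_lt(ks_normality(two_point)[1], 0.01)
  expect_error(ks_normality(matrix(1:4, ncol = 1)), "at least 5")
})

test_that("DFA matches the classical LDA solution on well-posed data", {
  set.seed(60)
  n <- 60
  scores <- rbind(matrix(rnorm(n * 3, 0), ncol = 3),
                  matrix(rnorm(n * 3, 1.2), ncol = 3),
                  matrix(rnorm(n * 3, -1.2), ncol = 3))
  labels <- rep(c("A", "B", "C"), each = n)
  m <- fit_dfa(scores, labels)
  expect_equal(m$n_functions, 2)
  ours <- cooid:::predict_dfa(m, scores)
  ref <- as.character(predict(MASS::lda(scores, grouping = labels))$class)
  expect_gt(mean(ours == ref), 0.99)
  # canonical eigenvalue ratio agrees with lda's singular values
  sv <- MASS::lda(scores, grouping = labels)$svd
  expect_equal(m$eigenvalues / sum(m$eigenvalues), sv^2 / sum(sv^2),
               tolerance = 0.05)
})

test_that("two separated classes give one function carrying all between-variance", {
  set.seed(61)
  scores <- rbind(matrix(rnorm(40, 0, 0.1), ncol = 2),
                  matrix(rnorm(40, 5, 0.1), ncol = 2))
  labels <- rep(c("A", "B"), each = 20)
  m <- fit_dfa(scores, labels)
  expect_equal(m$n_functions, 1)
  expect_equal(m$variance_pct, 100)
  cm <- classify(m, scores, labels)
  expect_equal(accuracy(cm), 100)
  expect_equal(unclass(cm), diag(c(20L, 20L)), ignore_attr = TRUE)
})

test_that("seven classes on seven components give six canonical functions", {
  set.seed(13)
  scores <- matrix(rnorm(140 * 7), ncol = 7) +
    matrix(rnorm(7 * 7), 7, 7)[rep(1:7, each = 20), ]
  m <- fit_dfa(scores, rep(sprintf("M%d", 1:7), each = 20))
  expect_equal(m$n_functions, 6)
  expect_equal(sum(m$variance_pct), 100)
})

test_that("relabeling classes permutes the confusion matrix but not accuracy", {
  pop <- make_population(4, separation = 1.5, seed = 14, n_calls = rep(15, 4))
  tab <- simulate_feature_table(pop)
  pca <- fit_pca(tab)
  cm1 <- loocv(pca$scores, pca$labels)
  swap <- c(ID01 = "Z", ID02 = "Y", ID03 = "X", ID04 = "W")
  cm2 <- loocv(pca$scores, unname(swap[pca$labels]))
  expect_equal(accuracy(cm1), accuracy(cm2))
  perm <- match(sort(swap), swap)
  expect_equal(unclass(cm2), unclass(cm1)[perm, perm], ignore_attr = TRUE)
  # conservation: row sums equal per-class call counts in both matrices
  expect_equal(unname(rowSums(cm1)), rep(15, 4))
  expect_equal(unname(rowSums(classify(fit_dfa(pca$scores, pca$labels),
                                       pca$scores, pca$labels))), rep(15, 4))
})

test_that("shuffled labels put LOOCV accuracy at chance, and structure above it", {
  pop <- make_population(5, separation = 2, seed = 15, n_calls = rep(20, 5))
  tab <- simulate_feature_table(pop)
  pca <- fit_pca(tab)
  cm <- loocv(pca$scores, pca$labels)
  resub <- classify(fit_dfa(pca$scores, pca$labels), pca$scores, pca$labels)
  expect_gte(accuracy(resub), accuracy(cm))
  expect_gt(accuracy(cm), 60)
  set.seed(70)
  shuffled <- sample(pca$labels)
  corr <- sum(diag(unclass(loocv(pca$scores, shuffled))))
  band <- qbinom(c(0.025, 0.975), 100, 1 / 5)
  expect_gte(corr, band[1])
  expect_lte(corr, band[2])
})

test_that("accuracy, chance level and the binomial test follow their definitions", {
  expect_equal(accuracy(diag(c(5L, 7L))), 100)
  cm <- matrix(c(8, 2, 3, 7), 2, 2, byrow = TRUE)
  expect_equal(accuracy(cm), 75)
  expect_error(accuracy(matrix(0, 2, 2)), "empty")
  expect_equal(chance_level(2), 50)
  expect_equal(chance_level(4), 25)
  expect_error(chance_level(1), "at least 2")
  expect_equal(binomial_vs_chance(3, 3, 0.5), 0.125)
  expect_equal(binomial_vs_chance(0, 10, 0.3), 1)
  # enumeration oracle: P[X >= 7], X ~ Bin(10, 0.4)
  expect_equal(binomial_vs_chance(7, 10, 0.4),
               sum(dbinom(7:10, 10, 0.4)))
})

test_that("discriminate() composes the stages coherently", {
  pop <- make_population(4, separation = 1.5, seed = 16, n_calls = rep(12, 4))
  res <- discriminate(simulate_feature_table(pop))
  expect_s3_class(res, "dfa_result")
  expect_equal(sum(res$confusion_loocv), 48)
  expect_equal(res$chance_pct, 25)
  expect_equal(length(res$ks_p), res$pca$n_retained)
  expect_equal(res$binomial_p,
               binomial_vs_chance(sum(diag(unclass(res$confusion_loocv))), 48, 0.25))
})
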