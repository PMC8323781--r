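test_that("ANOVA F-scores match an independent brute-force oracle", {
  set.seed(101)
  for (rep in 1:20) {
    n1 <- sample(3:25, 1); n0 <- sample(3:25, 1)
    p <- sample(2:20, 1)
    x <- matrix(stats::rnorm(p * (n1 + n0)), n1 + n0, p)
    y <- rep(c(1L, 0L), c(n1, n0))
    data <- toy_features(x, y)
    ranking <- anova_f_scores(data)
    scores <- setNames(ranking$score, ranking$feature)
    for (j in seq_len(p)) {
      expect_equal(unname(scores[paste0("f", j)]),
                   brute_force_f(x[, j], y),
                   tolerance = 1e-10)
    }
  }
})

test_that("ANOVA F agrees with stats::aov on a spot check", {
  set.seed(5)
  x <- stats::rnorm(30)
  y <- rep(c(1L, 0L), 15)
  data <- toy_features(cbind(x), y)
  f_pkg <- anova_f_scores(data)$score
  f_aov <- summary(stats::aov(x ~ factor(y)))[[1]]$`F value`[1]
  expect_equal(f_pkg, f_aov, tolerance = 1e-10)
})

test_that("degenerate features score as documented", {
  set.seed(8)
  jitter <- stats::rnorm(8, sd = 1e-3)
  x <- cbind(
    const = rep(1, 8),                       # constant everywhere -> 0
    sep = rep(c(1, 0), each = 4),            # zero within-variance -> capped
    noisy = rep(c(1, 0), each = 4) + jitter  # ordinary finite score
  )
  y <- rep(c(1L, 0L), each = 4)
  ranking <- anova_f_scores(toy_features(x, y))
  scores <- setNames(ranking$score, ranking$feature)
  expect_equal(unname(scores["f1"]), 0)
  expect_true(is.finite(scores["f2"]))
  expect_equal(ranking$feature[1], "f2")   # capped score ranks first
  expect_gt(scores["f2"], scores["f3"])
  expect_equal(attr(ranking, "capped"), "f2")
})

test_that("F-scores are invariant to affine feature rescaling and sample order", {
  set.seed(13)
  x <- matrix(stats::rnorm(120), 20, 6)
  y <- rep(c(1L, 0L), 10)
  base <- anova_f_scores(toy_features(x, y))

  rescaled <- anova_f_scores(toy_features(3.7 * x + 2, y))
  expect_equal(rescaled$score, base$score, tolerance = 1e-10)
  expect_equal(rescaled$feature, base$feature)

  perm <- sample(nrow(x))
  shuffled <- anova_f_scores(toy_features(x[perm, ], y[perm]))
  expect_equal(shuffled$score, base$score, tolerance = 1e-12)
  expect_equal(shuffled$feature, base$feature)
})

test_that("single-class or tiny inputs are rejected", {
  x <- matrix(stats::rnorm(20), 10, 2)
  expect_error(anova_f_scores(toy_features(x, rep(1L, 10))),
               class = "raacpred_error_single_class")
  expect_error(anova_f_scores(toy_features(x, c(1L, rep(0L, 9)))),
               class = "raacpred_error_tiny_class")
})

test_that("IFS finds the single informative feature and honours max_dim", {
  set.seed(21)
  n <- 40
  x <- cbind(
    rep(c(5, -5), each = n / 2) + stats::rnorm(n, sd = 0.1),  # wide margin
    stats::rnorm(n),
    stats::rnorm(n)
  )
  y <- rep(c(1L, 0L), each = n / 2)
  data <- toy_features(x, y)
  ranking <- anova_f_scores(data)
  cfg <- svm_config(folds = 5, seed = 3)
  ifs <- incremental_feature_selection(data, ranking, cfg, step = 1,
                                       tune = "none", cost = 8, gamma = 0.5)
  expect_equal(ifs$best_dimension, 1L)
  expect_equal(ifs$best_accuracy, 1)
  expect_equal(ifs$features, ranking$feature[1])

  one <- incremental_feature_selection(data, ranking, cfg, step = 1,
                                       max_dim = 1, tune = "none",
                                       cost = 8, gamma = 0.5)
  expect_equal(nrow(one$curve), 1)
})

test_that("IFS curve respects its argmax contract", {
  set.seed(33)
  x <- matrix(stats::rnorm(30 * 8), 30, 8)
  x[, 3] <- x[, 3] + rep(c(2, -2), each = 15)
  y <- rep(c(1L, 0L), each = 15)
  data <- toy_features(x, y)
  ranking <- anova_f_scores(data)
  ifs <- incremental_feature_selection(data, ranking,
                                       svm_config(folds = 5, seed = 9),
                                       step = 2, tune = "none",
                                       cost = 2, gamma = 0.25)
  expect_true(all(ifs$curve$accuracy >= 0 & ifs$curve$accuracy <= 1))
  expect_true(all(diff(ifs$curve$dimension) > 0))
  expect_equal(ifs$best_accuracy, max(ifs$curve$accuracy))
  expect_equal(ifs$best_dimension,
               min(ifs$curve$dimension[ifs$curve$accuracy ==
                                         ifs$best_accuracy]))
  expect_length(ifs$features, ifs$best_dimension)
})

test_that("IFS on label-permuted data hovers at chance", {
  set.seed(55)
  n <- 60
  accs <- vapply(1:5, function(i) {
    x <- matrix(stats::rnorm(n * 6), n, 6)
    y <- sample(rep(c(1L, 0L), each = n / 2))
    data <- toy_features(x, y)
    ranking <- anova_f_scores(data)
    ifs <- incremental_feature_selection(data, ranking,
                                         svm_config(folds = 5, seed = i),
                                         step = 2, tune = "none",
                                         cost = 1, gamma = 1 / 6)
    ifs$best_accuracy
  }, numeric(1))
  # best-of-curve maximizes over 3 dims, so allow the null band around 0.5
  # plus 3 binomial SEs at n per run
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(accs) - 0.5), 3 * se)
})

test_that("rankings and IFS curves persist as TSV", {
  set.seed(3)
  x <- matrix(stats::rnorm(40), 10, 4)
  y <- rep(c(1L, 0L), 5)
  data <- toy_features(x, y)
  ranking <- anova_f_scores(data)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_selection_tsv(ranking, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(back$feature, ranking$feature)
  expect_equal(back$score, ranking$score, tolerance = 1e-6)
})
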