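test_that("svm_config enforces the open grid bounds", {
  cfg <- svm_config()
  expect_true(all(cfg$cost_grid > 2^-5 & cfg$cost_grid < 2^15))
  expect_true(all(cfg$gamma_grid > 2^-15 & cfg$gamma_grid < 2^3))
  expect_error(svm_config(cost_exponents = c(-5, 0)),
               class = "raacpred_error_grid_bounds")
  expect_error(svm_config(gamma_exponents = c(0, 3)),
               class = "raacpred_error_grid_bounds")
  expect_error(svm_config(cost_exponents = integer(0)),
               class = "raacpred_error_empty_grid")
})

test_that("fold assignment is stratified, balanced and seeded", {
  y <- rep(c(1L, 0L), each = 10)
  f <- make_folds(y, folds = 10, seed = 4)
  expect_equal(as.vector(table(f)), rep(2L, 10))    # n=20, 10 folds -> 2 each
  # stratification: every fold holds one of each class
  expect_true(all(table(f, y) == 1))
  expect_identical(f, make_folds(y, 10, seed = 4))
  expect_false(identical(f, make_folds(y, 10, seed = 5)))
  expect_error(make_folds(rep(c(1L, 0L), c(19, 1)), 10, 1),
               class = "raacpred_error_degenerate_fold")
})

test_that("grid search separates well-separated clusters and stays in bounds", {
  set.seed(61)
  data <- separable_clusters(n_per_class = 50, d = 4, gap = 8)
  cfg <- svm_config(cost_exponents = c(-2, 2, 6), gamma_exponents = c(-6, -2),
                    folds = 5, seed = 2)
  model <- grid_search_train(data, cfg)
  acc <- model$cv$eval$metrics$value[model$cv$eval$metrics$metric == "acc"]
  expect_gte(acc, 0.95)
  expect_true(model$cost > 2^-5 && model$cost < 2^15)
  expect_true(model$gamma > 2^-15 && model$gamma < 2^3)
  # grid is sorted: ties break to smaller cost then gamma
  expect_equal(nrow(model$grid), 6)
  expect_equal(model$grid$accuracy[1], max(model$grid$accuracy))
})

test_that("grid search at chance level on permuted labels", {
  set.seed(71)
  data <- separable_clusters(n_per_class = 40, d = 4, gap = 8)
  data$label <- sample(data$label)
  cfg <- svm_config(cost_exponents = c(0, 4), gamma_exponents = c(-4, -1),
                    folds = 5, seed = 3)
  model <- grid_search_train(data, cfg)
  acc <- model$cv$eval$metrics$value[model$cv$eval$metrics$metric == "acc"]
  se <- sqrt(0.25 / nrow(data))
  # the grid maximizes over 4 cells, so allow the winner's-curse margin on
  # top of 3 binomial SEs
  expect_lt(abs(acc - 0.5), 3 * se + 0.1)
})

test_that("training is bit-reproducible under a fixed seed", {
  set.seed(81)
  data <- separable_clusters(n_per_class = 20, d = 3, gap = 6)
  cfg <- svm_config(cost_exponents = c(0, 4), gamma_exponents = c(-4, 0),
                    folds = 5, seed = 11)
  m1 <- grid_search_train(data, cfg)
  m2 <- grid_search_train(data, cfg)
  expect_identical(m1$grid, m2$grid)
  expect_identical(c(m1$cost, m1$gamma), c(m2$cost, m2$gamma))
  expect_identical(m1$cv$predictions, m2$cv$predictions)
})

test_that("cross_validate pools out-of-fold predictions and partitions evenly", {
  set.seed(91)
  data <- separable_clusters(n_per_class = 10, d = 3, gap = 10)
  cfg <- svm_config(folds = 10, seed = 6)
  cv <- cross_validate(data, cfg, cost = 8, gamma = 0.25)
  vals <- setNames(cv$eval$metrics$value, cv$eval$metrics$metric)
  expect_equal(unname(vals["acc"]), 1)
  expect_equal(unname(vals["mcc"]), 1)
  expect_equal(cv$per_fold$n, rep(2L, 10))
  expect_identical(cv$predictions,
                   cross_validate(data, cfg, cost = 8, gamma = 0.25)$predictions)
  expect_s3_class(tidy(cv), "tbl_df")
  expect_equal(glance(cv)$folds, 10L)
})

test_that("predict encodes sequences, keeps label/score consistent and reports short ones", {
  set.seed(103)
  sch <- raac_type33()[["15"]]
  sim <- simulate_dataset(sim_config(n_pos = 30, n_neg = 30,
                                     length_range = c(60L, 100L),
                                     positive_bias = 0.5, seed = 12))
  data <- encode_dataset(sim$pos_fasta, sim$neg_fasta, sch, k = 1)
  cfg <- svm_config(cost_exponents = c(0, 4, 8), gamma_exponents = c(-4, 0),
                    folds = 5, seed = 7)
  model <- grid_search_train(data, cfg)

  # training sequences fed back: labels recovered on separable data
  back <- predict(model, sim$pos_fasta)
  expect_gte(mean(back$pred == 1L), 0.9)
  expect_true(all((back$score > 0) == (back$pred == 1L)))
  expect_true(all(back$probability >= 0 & back$probability <= 1))

  # identical inputs give identical outputs; short sequences are reported
  seqs <- read_fasta(sim$pos_fasta)[1:2]
  dup <- c(a = unname(seqs[1]), b = unname(seqs[1]))
  pd <- predict(model, dup)
  expect_equal(pd$score[1], pd$score[2])
  expect_equal(pd$pred[1], pd$pred[2])

  model2 <- grid_search_train(
    encode_dataset(sim$pos_fasta, sim$neg_fasta, sch, k = 2),
    cfg
  )
  short <- predict(model2, c(tiny = "A"))   # length k-1 after reduction
  expect_true(is.na(short$pred))
  expect_match(short$note, "shorter")
})

test_that("models persist and restore with identical predictions", {
  set.seed(113)
  sch <- raac_type33()[["5"]]
  pos <- random_proteins(10, prefix = "p")
  neg <- random_proteins(10, prefix = "n")
  data <- encode_dataset(pos, neg, sch, k = 1)
  cfg <- svm_config(cost_exponents = 0, gamma_exponents = -2,
                    folds = 5, seed = 9)
  model <- grid_search_train(data, cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  write_model(model, path)
  restored <- read_model(path)
  probe <- random_proteins(5, prefix = "q")
  expect_identical(predict(model, probe), predict(restored, probe))
  # a path with no model behind it is rejected
  suppressWarnings(
    expect_error(read_model(withr::local_tempfile(fileext = ".rds")))
  )
})

test_that("enlarging the grid never decreases the selected CV accuracy", {
  set.seed(123)
  data <- separable_clusters(n_per_class = 20, d = 3, gap = 3, sd = 2)
  small <- svm_config(cost_exponents = c(0, 2), gamma_exponents = c(-4, -2),
                      folds = 5, seed = 13)
  large <- svm_config(cost_exponents = c(-2, 0, 2, 6),
                      gamma_exponents = c(-6, -4, -2, 0),
                      folds = 5, seed = 13)
  acc_small <- grid_search_train(data, small)$grid$accuracy[1]
  acc_large <- grid_search_train(data, large)$grid$accuracy[1]
  expect_gte(acc_large, acc_small)
})
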