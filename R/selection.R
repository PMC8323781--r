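#' Rank features by one-way ANOVA F-score
#'
#' For each feature the F statistic is the between-class mean square over
#' the pooled within-class mean square of a one-way, two-group ANOVA: a
#' large F means the feature's class means are far apart relative to its
#' within-class spread. Features are ranked by descending F; ties break by
#' ascending feature index so the ranking is deterministic.
#'
#' Degenerate features are handled explicitly: a feature constant within
#' each class but different between classes has zero within-class variance
#' and formally infinite F — it is capped just above the largest finite
#' score and ranks first; a feature constant across all samples scores 0.
#'
#' @param data Feature tibble from [encode_dataset()] (needs `label` plus
#'   numeric feature columns), with at least 2 samples per class.
#' @return A tibble of class `raac_ranking` with columns `feature`,
#'   `score`, `rank` (1 = most discriminative), ordered by rank. Attribute
#'   `capped` lists features whose infinite score was capped.
#' @examples
#' sch <- raac_type33()[["2"]]
#' d <- encode_dataset(c(a = "CCCS", b = "CCSS"), c(c = "SSSS", d = "SSSC"),
#'                     sch, k = 1)
#' anova_f_scores(d)
#' @export
anova_f_scores <- function(data) {
  fm <- features_matrix(data)
  check_two_classes(fm$y)
  if (length(fm$y) < 4) {
    abort("Need at least 4 samples (2 per class) to rank features",
          class = "raacpred_error_tiny_class")
  }
  x <- fm$x; y <- fm$y
  n <- nrow(x)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  m <- colMeans(x)
  m1 <- colMeans(x[y == 1L, , drop = FALSE])
  m0 <- colMeans(x[y == 0L, , drop = FALSE])
  ssb <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  ssw <- colSums((x[y == 1L, , drop = FALSE] -
                    matrix(m1, n1, ncol(x), byrow = TRUE))^2) +
    colSums((x[y == 0L, , drop = FALSE] -
               matrix(m0, n0, ncol(x), byrow = TRUE))^2)
  msb <- ssb / 1           # 2 groups: 1 df between
  msw <- ssw / (n - 2)
  f <- msb / msw
  f[msw == 0 & msb == 0] <- 0          # constant everywhere
  capped <- which(msw == 0 & msb > 0)  # perfect separation of means
  if (length(capped) > 0) {
    others <- setdiff(seq_along(f), capped)
    finite_max <- if (length(others) > 0) max(f[others], 0) else 0
    f[capped] <- finite_max + 1
  }
  ord <- order(-f, seq_along(f))
  out <- tibble::tibble(
    feature = colnames(x)[ord],
    score = unname(f[ord]),
    rank = seq_along(ord)
  )
  structure(out,
            capped = colnames(x)[capped],
            class = c("raac_ranking", class(out)))
}

#' Incremental feature selection over an ANOVA ranking
#'
#' Walks nested prefixes of the ranked feature list (dimensions `step`,
#' `2*step`, ... up to `max_dim`, always including `max_dim` itself) and
#' scores each prefix by stratified k-fold CV accuracy of the RBF-SVM. The
#' selected dimension is the smallest one attaining the maximum accuracy.
#'
#' Hyperparameters at each prefix are controlled by `tune`:
#' `"once"` (default) grid-searches at the full candidate dimension and
#' fixes the chosen (cost, gamma) for every prefix; `"per_dim"` re-runs the
#' grid search at every prefix (slow, exhaustive); `"none"` uses the
#' supplied `cost`/`gamma`.
#'
#' @param data Feature tibble from [encode_dataset()].
#' @param ranking An `raac_ranking` from [anova_f_scores()].
#' @param config An [svm_config()].
#' @param step Dimension increment (default 1).
#' @param max_dim Largest dimension to consider (default all features).
#' @param tune `"once"`, `"per_dim"` or `"none"`.
#' @param cost,gamma Hyperparameters when `tune = "none"`.
#' @return An object of class `raac_ifs`: list with `curve` (tibble
#'   `dimension`, `accuracy`), `best_dimension`, `best_accuracy`,
#'   `features` (names of the selected prefix), `cost`, `gamma` (as used at
#'   the best dimension), `tune`, `config`.
#' @export
incremental_feature_selection <- function(data, ranking,
                                          config = svm_config(),
                                          step = 1L, max_dim = NULL,
                                          tune = c("once", "per_dim", "none"),
                                          cost = 1, gamma = NULL) {
  tune <- match.arg(tune)
  stopifnot(inherits(ranking, "raac_ranking"), step >= 1)
  fm <- features_matrix(data)
  check_two_classes(fm$y)
  n_feat <- length(ranking$feature)
  max_dim <- min(max_dim %||% n_feat, n_feat)
  dims <- if (step >= max_dim) max_dim else
    unique(c(seq(step, max_dim, by = step), max_dim))
  fold_of <- make_folds(fm$y, config$folds, config$seed)
  ord_cols <- match(ranking$feature, colnames(fm$x))

  grid_fold_of <- make_folds(fm$y, config$grid_folds, config$seed)
  pick <- function(xsub) {
    grid <- grid_cv_accuracy(xsub, fm$y, grid_fold_of, config)
    list(cost = grid$cost[1], gamma = grid$gamma[1])
  }
  fixed <- switch(tune,
    none = list(cost = cost, gamma = gamma %||% (1 / max_dim)),
    once = pick(fm$x[, ord_cols[seq_len(max_dim)], drop = FALSE]),
    per_dim = NULL
  )
  acc <- vapply(dims, function(d) {
    xsub <- fm$x[, ord_cols[seq_len(d)], drop = FALSE]
    hp <- fixed %||% pick(xsub)
    mean(oof_predict(xsub, fm$y, fold_of, hp$cost, hp$gamma)$pred == fm$y)
  }, numeric(1))
  best_i <- which(acc == max(acc))[1]
  best_hp <- fixed %||%
    pick(fm$x[, ord_cols[seq_len(dims[best_i])], drop = FALSE])
  structure(
    list(
      curve = tibble::tibble(dimension = as.integer(dims), accuracy = acc),
      best_dimension = as.integer(dims[best_i]),
      best_accuracy = acc[best_i],
      features = ranking$feature[seq_len(dims[best_i])],
      cost = best_hp$cost, gamma = best_hp$gamma,
      tune = tune, config = config
    ),
    class = "raac_ifs"
  )
}

#' @export
print.raac_ifs <- function(x, ...) {
  cat(sprintf(
    "<raac_ifs> %d dimensions scanned; best: %d features, CV accuracy %.4f\n",
    nrow(x$curve), x$best_dimension, x$best_accuracy))
  invisible(x)
}

#' @rdname incremental_feature_selection
#' @param x,object An `raac_ifs` object.
#' @param ... Unused.
#' @export
tidy.raac_ifs <- function(x, ...) x$curve

#' @rdname incremental_feature_selection
#' @export
glance.raac_ifs <- function(x, ...) {
  tibble::tibble(
    best_dimension = x$best_dimension,
    best_accuracy = x$best_accuracy,
    cost = x$cost, gamma = x$gamma,
    dimensions_scanned = nrow(x$curve)
  )
}

#' @rdname incremental_feature_selection
#' @export
autoplot.raac_ifs <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(.data$dimension, .data$accuracy)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_point(
      data = object$curve[object$curve$dimension == object$best_dimension, ],
      colour = "red", size = 2.5
    ) +
    ggplot2::labs(
      x = "Number of top-ranked features",
      y = "Cross-validated accuracy",
      title = sprintf("IFS curve (best: %d features, %.2f%%)",
                      object$best_dimension, 100 * object$best_accuracy)
    ) +
    ggplot2::theme_minimal()
}

#' Write a feature ranking or IFS curve as TSV
#'
#' @param x An `raac_ranking` or `raac_ifs`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_tsv <- function(x, path) {
  df <- if (inherits(x, "raac_ifs")) as.data.frame(x$curve)
        else as.data.frame(x)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
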