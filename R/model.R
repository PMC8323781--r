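#' RBF-SVM configuration
#'
#' Fixes the grid-search lattice and cross-validation layout. The grids are
#' geometric in base 2 and must stay inside the open intervals
#' `2^-5 < C < 2^15` and `2^-15 < gamma < 2^3`; the defaults step the
#' exponent by 2 across each interval.
#'
#' @param cost_exponents Integer exponents; the cost grid is
#'   `2^cost_exponents`.
#' @param gamma_exponents Integer exponents; the gamma grid is
#'   `2^gamma_exponents`.
#' @param folds Number of stratified cross-validation folds for model
#'   evaluation (default 10).
#' @param grid_folds Folds used when screening the (cost, gamma) lattice
#'   (default 5, the convention of libsvm's grid-search tool; the final
#'   model is still evaluated at `folds`).
#' @param seed Integer seed controlling fold assignment and the probability
#'   calibration.
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(cost_exponents = seq(-4L, 14L, by = 2L),
                       gamma_exponents = seq(-14L, 2L, by = 2L),
                       folds = 10L, grid_folds = 5L, seed = 1L) {
  if (length(cost_exponents) == 0 || length(gamma_exponents) == 0) {
    abort("Hyperparameter grids must be non-empty",
          class = "raacpred_error_empty_grid")
  }
  if (any(cost_exponents <= -5) || any(cost_exponents >= 15)) {
    abort("cost exponents must satisfy -5 < e < 15",
          class = "raacpred_error_grid_bounds")
  }
  if (any(gamma_exponents <= -15) || any(gamma_exponents >= 3)) {
    abort("gamma exponents must satisfy -15 < e < 3",
          class = "raacpred_error_grid_bounds")
  }
  stopifnot(folds >= 2, grid_folds >= 2)
  structure(
    list(
      cost_grid = 2^sort(unique(as.numeric(cost_exponents))),
      gamma_grid = 2^sort(unique(as.numeric(gamma_exponents))),
      folds = as.integer(folds),
      grid_folds = as.integer(grid_folds),
      seed = as.integer(seed)
    ),
    class = "svm_config"
  )
}

#' @export
print.svm_config <- function(x, ...) {
  cat("<svm_config> RBF kernel;",
      length(x$cost_grid), "x", length(x$gamma_grid), "grid;",
      x$folds, "folds; seed", x$seed, "\n")
  invisible(x)
}

#' Deterministic stratified fold assignment
#'
#' Samples of each class are shuffled under the seed and dealt round-robin
#' into folds, so every fold's class balance matches the data as closely as
#' integer arithmetic allows and the assignment is bit-reproducible.
#'
#' @param y Binary label vector.
#' @param folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..folds), same length as `y`.
#' @export
make_folds <- function(y, folds, seed) {
  y <- as.integer(y)
  stopifnot(folds >= 2, length(y) >= folds)
  fold_of <- integer(length(y))
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- sample(which(y == cls))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  counts <- table(factor(fold_of, levels = seq_len(folds)), y)
  bad <- which(apply(counts, 1, function(r) any(r == 0)))
  if (length(bad) > 0) {
    abort(paste0("Fold(s) ", paste(bad, collapse = ", "),
                 " would miss a class; use fewer folds"),
          class = "raacpred_error_degenerate_fold")
  }
  fold_of
}

# Out-of-fold class predictions for a fixed (cost, gamma); the deterministic
# workhorse behind grid search, IFS and cross_validate.
oof_predict <- function(x, y, fold_of, cost, gamma, decision = FALSE) {
  pred <- integer(length(y))
  score <- numeric(length(y))
  for (f in sort(unique(fold_of))) {
    test <- fold_of == f
    fit <- e1071::svm(
      x = x[!test, , drop = FALSE],
      y = factor(y[!test], levels = c(0L, 1L)),
      type = "C-classification", kernel = "radial",
      cost = cost, gamma = gamma, scale = FALSE
    )
    p <- predict(fit, x[test, , drop = FALSE], decision.values = decision)
    pred[test] <- as.integer(as.character(p))
    if (decision) {
      dv <- attr(p, "decision.values")
      # libsvm orients the decision value by its internal label order; flip
      # so larger always means class 1
      sgn <- if (grepl("^0/1", colnames(dv)[1])) -1 else 1
      score[test] <- sgn * dv[, 1]
    }
  }
  list(pred = pred, score = if (decision) score else NULL)
}

#' Cross-validated evaluation at fixed hyperparameters
#'
#' Runs stratified k-fold cross-validation at one (cost, gamma) pair,
#' pools the out-of-fold predictions and scores them with the full metric
#' set; per-fold accuracies are also reported.
#'
#' @param data Feature tibble from [encode_dataset()] (needs `label` plus
#'   numeric feature columns).
#' @param config An [svm_config()]; its `folds` and `seed` control the fold
#'   layout.
#' @param cost,gamma RBF-SVM hyperparameters. Defaults: `cost = 1`,
#'   `gamma = 1/n_features`.
#' @return An object of class `raac_cv`: list with `eval` (an `raac_eval`
#'   on the pooled out-of-fold predictions), `per_fold` (tibble `fold`,
#'   `n`, `accuracy`), `predictions` (tibble `sample_id`, `label`, `fold`,
#'   `pred`, `score`), `cost`, `gamma`, `config`.
#' @export
cross_validate <- function(data, config = svm_config(), cost = 1,
                           gamma = NULL) {
  fm <- features_matrix(data)
  check_two_classes(fm$y)
  gamma <- gamma %||% (1 / ncol(fm$x))
  fold_of <- make_folds(fm$y, config$folds, config$seed)
  oof <- oof_predict(fm$x, fm$y, fold_of, cost, gamma, decision = TRUE)
  per_fold <- tibble::tibble(fold = sort(unique(fold_of))) |>
    dplyr::mutate(
      n = vapply(.data$fold, function(f) sum(fold_of == f), integer(1)),
      accuracy = vapply(.data$fold, function(f) {
        mean(oof$pred[fold_of == f] == fm$y[fold_of == f])
      }, numeric(1))
    )
  structure(
    list(
      eval = evaluate_predictions(fm$y, oof$pred, oof$score),
      per_fold = per_fold,
      predictions = tibble::tibble(
        sample_id = fm$sample_id, label = fm$y, fold = fold_of,
        pred = oof$pred, score = oof$score
      ),
      cost = cost, gamma = gamma, config = config
    ),
    class = "raac_cv"
  )
}

#' @export
print.raac_cv <- function(x, ...) {
  m <- setNames(x$eval$metrics$value, x$eval$metrics$metric)
  cat(sprintf(
    "<raac_cv> %d-fold; cost %.4g gamma %.4g; pooled acc %.4f mcc %.4f\n",
    x$config$folds, x$cost, x$gamma, m["acc"], m["mcc"]))
  invisible(x)
}

#' @rdname cross_validate
#' @param x,object An `raac_cv` object.
#' @param ... Unused.
#' @export
tidy.raac_cv <- function(x, ...) x$per_fold

#' @rdname cross_validate
#' @export
glance.raac_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(cost = x$cost, gamma = x$gamma, folds = x$config$folds),
    glance(x$eval)
  )
}

check_two_classes <- function(y) {
  tab <- table(factor(y, levels = 0:1))
  if (any(tab == 0)) {
    abort("Both classes must be present",
          class = "raacpred_error_single_class")
  }
  if (any(tab < 2)) {
    abort("Each class needs at least 2 samples",
          class = "raacpred_error_tiny_class")
  }
  invisible(NULL)
}

# CV accuracy over the (cost, gamma) lattice on fixed folds. Returns the
# grid tibble; ties on accuracy go to smaller cost, then smaller gamma.
grid_cv_accuracy <- function(x, y, fold_of, config) {
  grid <- tidyr::expand_grid(cost = config$cost_grid,
                             gamma = config$gamma_grid)
  grid$accuracy <- purrr::map2_dbl(grid$cost, grid$gamma, function(co, ga) {
    mean(oof_predict(x, y, fold_of, co, ga)$pred == y)
  })
  dplyr::arrange(grid, dplyr::desc(.data$accuracy), .data$cost, .data$gamma)
}

#' Train an RBF-SVM with exhaustive grid search
#'
#' Evaluates every (cost, gamma) pair of the configured lattice by
#' stratified k-fold cross-validation, picks the pair with the highest CV
#' accuracy (ties: smaller cost, then smaller gamma), refits on all data at
#' that pair, and attaches a pooled cross-validation report at the chosen
#' hyperparameters.
#'
#' Composition features are already bounded in \[0, 1\], so no additional
#' scaling is applied before the kernel.
#'
#' @param data Feature tibble from [encode_dataset()]; if `selected` is
#'   given, only those feature columns are used.
#' @param config An [svm_config()].
#' @param selected Optional character vector of feature names (e.g. the top
#'   of an ANOVA ranking) to train on.
#' @return An object of class `raac_model`: list with `fit` (the e1071
#'   model), `cost`, `gamma`, `grid` (full CV-accuracy lattice),
#'   `cv` (an [cross_validate()] report at the chosen pair), `scheme`, `k`,
#'   `feature_names` (the columns the model consumes), `config`.
#' @export
grid_search_train <- function(data, config = svm_config(), selected = NULL) {
  scheme <- attr(data, "scheme")
  k <- attr(data, "k")
  if (!is.null(selected)) {
    keep <- intersect(names(data), c("sample_id", "label", selected))
    data2 <- data[keep]
    attr(data2, "scheme") <- scheme; attr(data2, "k") <- k
    data <- data2
  }
  fm <- features_matrix(data)
  check_two_classes(fm$y)
  fold_of <- make_folds(fm$y, config$grid_folds, config$seed)
  grid <- grid_cv_accuracy(fm$x, fm$y, fold_of, config)
  best <- grid[1, ]
  fit <- e1071::svm(
    x = fm$x, y = factor(fm$y, levels = c(0L, 1L)),
    type = "C-classification", kernel = "radial",
    cost = best$cost, gamma = best$gamma, scale = FALSE,
    probability = TRUE, seed = config$seed
  )
  structure(
    list(
      fit = fit,
      cost = best$cost, gamma = best$gamma,
      grid = grid,
      cv = cross_validate(data, config, cost = best$cost,
                          gamma = best$gamma),
      scheme = scheme, k = k,
      feature_names = colnames(fm$x),
      config = config
    ),
    class = "raac_model"
  )
}

#' @export
print.raac_model <- function(x, ...) {
  cat("<raac_model> RBF-SVM on", length(x$feature_names), "features")
  if (!is.null(x$scheme)) {
    cat(" (scheme type", x$scheme$type_id, "size", x$scheme$size,
        ", k =", x$k, ")")
  }
  cat(sprintf("\n  cost 2^%g, gamma 2^%g; CV accuracy %.4f\n",
              log2(x$cost), log2(x$gamma),
              x$cv$eval$metrics$value[x$cv$eval$metrics$metric == "acc"]))
  invisible(x)
}

#' @rdname grid_search_train
#' @param x,object An `raac_model`.
#' @param ... Unused.
#' @export
tidy.raac_model <- function(x, ...) x$grid

#' @rdname grid_search_train
#' @export
glance.raac_model <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      n_features = length(x$feature_names),
      cost = x$cost, gamma = x$gamma
    ),
    glance(x$cv$eval)
  )
}

#' Predict class membership for new sequences
#'
#' Encodes new sequences under the model's own reduction scheme and k,
#' restricts to the feature columns the model was trained on, and returns a
#' per-sequence call with the RBF decision score and calibrated
#' probability. Sequences shorter than `k` are reported with `NA` outputs
#' rather than dropped silently.
#'
#' @param object An `raac_model` from [grid_search_train()].
#' @param new_data Sequences: FASTA path, named character vector,
#'   `AAStringSet`, or a pre-encoded feature tibble.
#' @param ... Unused.
#' @return A tibble `sample_id`, `pred` (1/0), `score` (signed decision
#'   value, positive = class 1), `probability` (of class 1), `note`.
#' @export
predict.raac_model <- function(object, new_data, ...) {
  if (is.data.frame(new_data) && all(object$feature_names %in%
                                     names(new_data))) {
    enc <- new_data
    skipped <- tibble::tibble(id = character(0), reason = character(0))
  } else {
    if (is.null(object$scheme)) {
      abort("Model carries no reduction scheme; supply encoded features")
    }
    enc <- encode_sequences(as_fasta_or_seqs(new_data), object$scheme,
                            object$k)
    skipped <- attr(enc, "skipped")
  }
  missing_cols <- setdiff(object$feature_names, names(enc))
  if (length(missing_cols) > 0) {
    abort(paste0("Encoded input lacks model feature(s): ",
                 paste(head(missing_cols, 3), collapse = ", ")))
  }
  x <- as.matrix(enc[object$feature_names])
  out <- if (nrow(x) > 0) {
    p <- predict(object$fit, x, decision.values = TRUE, probability = TRUE)
    dv <- attr(p, "decision.values")
    sgn <- if (grepl("^0/1", colnames(dv)[1])) -1 else 1
    pr <- attr(p, "probabilities")
    score <- unname(sgn * dv[, 1])
    # class call from the decision value itself, so label and score always
    # agree even if the probability calibration is degenerate
    tibble::tibble(
      sample_id = enc$sample_id,
      pred = as.integer(score > 0),
      score = score,
      probability = unname(pr[, "1"]),
      note = NA_character_
    )
  } else {
    tibble::tibble(sample_id = character(0), pred = integer(0),
                   score = numeric(0), probability = numeric(0),
                   note = character(0))
  }
  if (nrow(skipped) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      sample_id = skipped$id, pred = NA_integer_, score = NA_real_,
      probability = NA_real_, note = skipped$reason
    ))
  }
  out
}

#' Persist / restore a trained model
#'
#' The file embeds a format version, the reduction scheme, k, the selected
#' feature names and the fitted SVM, so a restored model predicts
#' identically.
#'
#' @param model An `raac_model`.
#' @param path File path.
#' @return `path` (writer) / an `raac_model` (reader).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "raac_model"))
  saveRDS(list(format = "raacpred-model-v1", model = model), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "raacpred-model-v1")) {
    abort("Not a raacpred model file", class = "raacpred_error_bad_model_file")
  }
  obj$model
}
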