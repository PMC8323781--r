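#' Scan reduction schemes and k-mer orders for classification accuracy
#'
#' Full factorial evaluation over a set of reduction schemes and k values:
#' each cell encodes the data under (scheme, k) and measures stratified
#' k-fold CV accuracy of the RBF-SVM. Failures in a cell (for example all
#' sequences shorter than k) are recorded and the scan continues.
#'
#' By default each cell is evaluated at fixed hyperparameters
#' (`cost = 1`, `gamma = 1/dimension`); set `tune = "grid"` to grid-search
#' within every cell (exhaustive, much slower).
#'
#' @param pos,neg Positive / negative sequences (FASTA paths or sequence
#'   vectors).
#' @param schemes List of [raac_scheme] objects (default [raac_type33()]),
#'   or a registry tibble from [read_scheme_library()].
#' @param k_values Subset of `1:3`.
#' @param config An [svm_config()].
#' @param tune `"none"` (default) or `"grid"`.
#' @param nonstandard Non-canonical residue policy, see
#'   [reduce_sequences()].
#' @return A tibble of class `raac_scan` with one row per (scheme, k):
#'   columns `type_id`, `size`, `k`, `dimension`, `accuracy`, `error`
#'   (`NA` unless the cell failed). Attribute `best` holds the best row
#'   (ties: lexicographically smallest (type_id, size, k)).
#' @export
scan_schemes <- function(pos, neg, schemes = raac_type33(),
                         k_values = 1:3, config = svm_config(),
                         tune = c("none", "grid"),
                         nonstandard = c("drop", "error")) {
  tune <- match.arg(tune)
  nonstandard <- match.arg(nonstandard)
  if (is.data.frame(schemes)) schemes <- schemes$scheme
  stopifnot(length(schemes) >= 1, length(k_values) >= 1)
  k_values <- vapply(k_values, check_k, integer(1))
  pos <- as_fasta_or_seqs(pos); neg <- as_fasta_or_seqs(neg)

  cells <- tidyr::expand_grid(si = seq_along(schemes), k = k_values)
  rows <- purrr::pmap(cells, function(si, k) {
    sch <- schemes[[si]]
    res <- tryCatch({
      data <- encode_dataset(pos, neg, sch, k, nonstandard)
      acc <- if (tune == "grid") {
        fm <- features_matrix(data)
        fold_of <- make_folds(fm$y, config$grid_folds, config$seed)
        grid_cv_accuracy(fm$x, fm$y, fold_of, config)$accuracy[1]
      } else {
        cv <- cross_validate(data, config)
        mean(cv$predictions$pred == cv$predictions$label)
      }
      list(accuracy = acc, error = NA_character_)
    }, error = function(e) list(accuracy = NA_real_,
                                error = conditionMessage(e)))
    tibble::tibble(
      type_id = sch$type_id, size = sch$size, k = k,
      dimension = sch$size^k,
      accuracy = res$accuracy, error = res$error
    )
  })
  out <- dplyr::bind_rows(rows)
  ok <- dplyr::filter(out, !is.na(.data$accuracy))
  best <- if (nrow(ok) > 0) {
    dplyr::arrange(ok, dplyr::desc(.data$accuracy), .data$type_id,
                   .data$size, .data$k)[1, ]
  } else NULL
  structure(out, best = best, class = c("raac_scan", class(out)))
}

#' Best cell of a scheme scan
#'
#' @param scan An `raac_scan` tibble.
#' @return One-row tibble (or `NULL` if every cell failed).
#' @export
scan_best <- function(scan) attr(scan, "best")

#' @rdname scan_schemes
#' @param object An `raac_scan` (for `autoplot`).
#' @param ... Unused.
#' @export
autoplot.raac_scan <- function(object, ...) {
  dat <- dplyr::filter(object, !is.na(.data$accuracy))
  ggplot2::ggplot(dat, ggplot2::aes(factor(.data$size), factor(.data$k),
                                    fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "CV accuracy") +
    ggplot2::labs(
      x = "Reduced alphabet size (s)",
      y = "K-mer order (k)",
      title = "Accuracy over reduction schemes and k"
    ) +
    ggplot2::theme_minimal()
}

#' Run the full classification pipeline on a two-class sequence set
#'
#' The canonical workflow: encode under one (scheme, k), rank features by
#' ANOVA F-score, prune by incremental feature selection, then grid-search
#' the RBF-SVM on the selected prefix. Set `ifs = FALSE` to train on the
#' full feature set.
#'
#' @inheritParams scan_schemes
#' @param scheme An [raac_scheme].
#' @param k K-mer order, 1--3.
#' @param config An [svm_config()].
#' @param ifs Run incremental feature selection (default TRUE).
#' @param ifs_step Dimension increment of the IFS walk.
#' @param ifs_tune Hyperparameter policy inside IFS, see
#'   [incremental_feature_selection()].
#' @return A list of class `raac_pipeline` with `data` (encoded features),
#'   `ranking`, `ifs` (or `NULL`), `model` (an `raac_model`) and the pooled
#'   CV `eval` of the final model.
#' @export
train_pipeline <- function(pos, neg, scheme, k, config = svm_config(),
                           ifs = TRUE, ifs_step = 1L,
                           ifs_tune = "once",
                           nonstandard = c("drop", "error")) {
  nonstandard <- match.arg(nonstandard)
  data <- encode_dataset(pos, neg, scheme, k, nonstandard)
  ranking <- anova_f_scores(data)
  ifs_res <- NULL
  selected <- NULL
  if (ifs) {
    ifs_res <- incremental_feature_selection(
      data, ranking, config, step = ifs_step, tune = ifs_tune
    )
    selected <- ifs_res$features
  }
  model <- grid_search_train(data, config, selected = selected)
  structure(
    list(data = data, ranking = ranking, ifs = ifs_res, model = model,
         eval = model$cv$eval),
    class = "raac_pipeline"
  )
}

#' @export
print.raac_pipeline <- function(x, ...) {
  cat("<raac_pipeline>\n  features:", ncol(x$data) - 2, "encoded;",
      length(x$model$feature_names), "used\n")
  if (!is.null(x$ifs)) {
    cat("  IFS best dimension:", x$ifs$best_dimension, "\n")
  }
  m <- setNames(x$eval$metrics$value, x$eval$metrics$metric)
  cat(sprintf("  pooled CV: acc %.4f, mcc %.4f, auc %.4f\n",
              m["acc"], m["mcc"], x$eval$auc))
  invisible(x)
}
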