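#' Confusion counts from truth and predictions
#'
#' @param truth,pred Binary vectors (1 = positive, 0 = negative), any type
#'   coercible to integer.
#' @return A one-row tibble with columns `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred), length(truth) >= 1,
            all(truth %in% 0:1), all(pred %in% 0:1))
  tibble::tibble(
    tp = sum(truth == 1L & pred == 1L),
    tn = sum(truth == 0L & pred == 0L),
    fp = sum(truth == 0L & pred == 1L),
    fn = sum(truth == 1L & pred == 0L)
  )
}

#' Classification metrics from confusion counts
#'
#' Computes sensitivity `Sn = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`,
#' `F1 = 2TP/(2TP+FP+FN)`, accuracy `Acc = (TP+TN)/total` and the Matthews
#' correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TN+FN)(TP+FN)(TN+FP))`.
#'
#' A metric whose denominator is zero is reported as `NA` with an
#' explanatory `note` (a degenerate classifier is surfaced, never silently
#' coerced to 0).
#'
#' @param counts One-row data frame with `tp`, `tn`, `fp`, `fn`; or give
#'   the four counts directly.
#' @param tp,tn,fp,fn Individual counts when `counts` is not supplied.
#' @return A tibble with columns `metric` (`sn`, `sp`, `f1`, `acc`, `mcc`),
#'   `value` and `note` (`NA` unless the metric is undefined).
#' @examples
#' compute_metrics(tp = 70, tn = 71, fp = 4, fn = 5)
#' @export
compute_metrics <- function(counts = NULL, tp = NULL, tn = NULL, fp = NULL,
                            fn = NULL) {
  if (is.null(counts)) {
    counts <- tibble::tibble(tp = tp, tn = tn, fp = fp, fn = fn)
  }
  stopifnot(all(c("tp", "tn", "fp", "fn") %in% names(counts)),
            nrow(counts) == 1)
  # doubles: the MCC denominator product overflows 32-bit integers easily
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn >= 1)

  ratio <- function(num, den, what) {
    if (den == 0) list(value = NA_real_, note = paste0(what, ": denominator 0"))
    else list(value = num / den, note = NA_character_)
  }
  sn <- ratio(tp, tp + fn, "no positive samples")
  sp <- ratio(tn, tn + fp, "no negative samples")
  f1 <- ratio(2 * tp, 2 * tp + fp + fn, "no positive samples or predictions")
  acc <- ratio(tp + tn, tp + tn + fp + fn, "empty")
  mcc_den2 <- (tp + fp) * (tn + fn) * (tp + fn) * (tn + fp)
  mcc <- if (mcc_den2 == 0) {
    list(value = NA_real_, note = "mcc undefined: a confusion margin is 0")
  } else {
    list(value = (tp * tn - fp * fn) / sqrt(mcc_den2), note = NA_character_)
  }
  tibble::tibble(
    metric = c("sn", "sp", "f1", "acc", "mcc"),
    value = c(sn$value, sp$value, f1$value, acc$value, mcc$value),
    note = c(sn$note, sp$note, f1$note, acc$note, mcc$note)
  )
}

#' ROC curve and AUC from decision scores
#'
#' The AUC is the rank statistic: the probability that a uniformly chosen
#' positive outscores a uniformly chosen negative, with ties counted half
#' (the Mann-Whitney convention). ROC points come from sweeping a threshold
#' over the observed scores; the rank AUC equals the trapezoidal area under
#' that curve.
#'
#' @param scores Numeric decision scores, larger = more positive.
#' @param labels Binary labels (1 = positive, 0 = negative).
#' @return A list of class `raac_roc` with `auc` (scalar) and `points`
#'   (tibble `threshold`, `fpr`, `tpr`, sorted by increasing `fpr`).
#' @examples
#' roc_auc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))$auc  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)),
            all(labels %in% 0:1))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) {
    abort("Both classes must be present to compute a ROC curve",
          class = "raacpred_error_single_class")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- vapply(thresholds, function(th) {
    pred <- as.integer(scores >= th)
    c(fpr = sum(pred == 1L & labels == 0L) / n0,
      tpr = sum(pred == 1L & labels == 1L) / n1)
  }, numeric(2))
  structure(
    list(
      auc = auc,
      points = tibble::tibble(
        threshold = thresholds,
        fpr = pts["fpr", ],
        tpr = pts["tpr", ]
      )
    ),
    class = "raac_roc"
  )
}

#' @export
print.raac_roc <- function(x, ...) {
  cat("<raac_roc> AUC =", format(x$auc, digits = 4), "with",
      nrow(x$points), "threshold points\n")
  invisible(x)
}

#' Full evaluation report from truth, predictions and optional scores
#'
#' Bundles the confusion counts, the five threshold metrics and (when
#' scores are supplied) the ROC/AUC into one object with [tidy()] /
#' [glance()] / [autoplot()] methods.
#'
#' @param truth,pred Binary vectors (1 = positive, 0 = negative).
#' @param scores Optional numeric decision scores for ROC/AUC.
#' @return An object of class `raac_eval`: list with `counts`, `metrics`,
#'   `auc` (or `NA`), `roc` (or `NULL`).
#' @export
evaluate_predictions <- function(truth, pred, scores = NULL) {
  counts <- confusion_counts(truth, pred)
  metrics <- compute_metrics(counts)
  roc <- if (!is.null(scores)) roc_auc(scores, truth) else NULL
  structure(
    list(
      counts = counts,
      metrics = metrics,
      auc = if (is.null(roc)) NA_real_ else roc$auc,
      roc = roc
    ),
    class = "raac_eval"
  )
}

#' @export
print.raac_eval <- function(x, ...) {
  cat("<raac_eval>\n")
  with(x$counts, cat(sprintf("  tp %d  tn %d  fp %d  fn %d\n", tp, tn, fp, fn)))
  m <- setNames(x$metrics$value, x$metrics$metric)
  cat(sprintf("  acc %.4f  sn %.4f  sp %.4f  f1 %.4f  mcc %.4f",
              m["acc"], m["sn"], m["sp"], m["f1"], m["mcc"]))
  if (!is.na(x$auc)) cat(sprintf("  auc %.4f", x$auc))
  cat("\n")
  invisible(x)
}

#' @rdname evaluate_predictions
#' @param x An `raac_eval` object.
#' @param ... Unused.
#' @export
tidy.raac_eval <- function(x, ...) {
  out <- x$metrics
  if (!is.na(x$auc)) {
    out <- dplyr::bind_rows(
      out,
      tibble::tibble(metric = "auc", value = x$auc, note = NA_character_)
    )
  }
  out
}

#' @rdname evaluate_predictions
#' @export
glance.raac_eval <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$metrics[c("metric", "value")],
                             names_from = "metric", values_from = "value")
  dplyr::bind_cols(x$counts, wide, tibble::tibble(auc = x$auc))
}

#' @rdname evaluate_predictions
#' @param object An `raac_eval` object (for `autoplot`).
#' @export
autoplot.raac_eval <- function(object, ...) {
  if (is.null(object$roc)) {
    abort("No scores were supplied, so there is no ROC curve to plot")
  }
  ggplot2::ggplot(object$roc$points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - Sp)",
      y = "True positive rate (Sn)",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Write an evaluation report and its ROC points as TSV
#'
#' @param eval An `raac_eval` object.
#' @param path Base output path; metrics go to `path`, ROC points (if
#'   present) to `paste0(path, ".roc.tsv")`.
#' @return `path`, invisibly.
#' @export
write_eval_tsv <- function(eval, path) {
  write.table(as.data.frame(tidy(eval)), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(eval$roc)) {
    write.table(as.data.frame(eval$roc$points), paste0(path, ".roc.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
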