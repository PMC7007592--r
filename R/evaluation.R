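#' Confusion matrix from labeled predictions
#'
#' @param data A data frame of evaluated patients.
#' @param truth,estimate Column names (strings) holding the true and predicted
#'   class labels. Defaults match [crossval()] output.
#' @param class_names Optional explicit class order; defaults to the sorted
#'   union of the true labels. A predicted label outside the true label set
#'   (and not listed here) is an error rather than a silent extra column.
#' @return A `phenotype_confusion`: square integer matrix, rows = true class,
#'   columns = predicted class.
#' @export
confusion_matrix <- function(data, truth = "label", estimate = "predicted_label",
                             class_names = NULL) {
  tl <- as.character(data[[truth]])
  pl <- as.character(data[[estimate]])
  if (length(tl) != length(pl)) stop("truth/estimate length mismatch", call. = FALSE)
  if (anyNA(tl)) stop("confusion_matrix requires non-missing true labels", call. = FALSE)
  if (is.null(class_names)) class_names <- sort(unique(tl))
  unseen <- setdiff(unique(pl), class_names)
  if (length(unseen) > 0) {
    stop("predicted label(s) outside the class set: ",
         paste(unseen, collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(tl, levels = class_names), factor(pl, levels = class_names))
  m <- matrix(as.integer(counts), nrow = length(class_names),
              dimnames = list(true = class_names, predicted = class_names))
  structure(m, class = c("phenotype_confusion", "matrix"))
}

#' @export
print.phenotype_confusion <- function(x, ...) {
  cat("<confusion matrix> rows = true, columns = predicted\n")
  print(unclass(x))
  invisible(x)
}

#' Area under the ROC curve by the rank statistic
#'
#' For two classes, the probability that a random positive outranks a random
#' negative under the positive-class score, computed from midranks so tied
#' scores earn half credit — identical to all-pairs concordance counting with
#' ties at 1/2. With more than two classes, each class is scored one-vs-rest
#' against its own score column and the class AUROCs are macro-averaged
#' (classes with no positives or no negatives are undefined and excluded).
#'
#' @param data Data frame with a truth column and one numeric score column per
#'   class, named by class (as produced by [predict.phenotype_model()]).
#' @param truth Column name of the true labels.
#' @param class_names Classes to score; defaults to sorted unique truth values.
#' @return A single number in \[0, 1\], or `NA` if undefined.
#' @export
auroc <- function(data, truth = "label", class_names = NULL) {
  tl <- as.character(data[[truth]])
  if (is.null(class_names)) class_names <- sort(unique(tl))
  missing_scores <- setdiff(class_names, names(data))
  if (length(missing_scores) > 0) {
    stop("no score column for class(es): ", paste(missing_scores, collapse = ", "),
         call. = FALSE)
  }
  per_class <- vapply(class_names, function(cls) {
    pos <- tl == cls
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(data[[cls]], ties.method = "average")
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  if (length(class_names) == 2) {
    # symmetric in binary problems; report the second (alphabetically later)
    # class as "positive" by convention, though both give the same macro mean
    mean(per_class)
  } else {
    if (all(is.na(per_class))) NA_real_ else mean(per_class, na.rm = TRUE)
  }
}

#' Diagnostic metrics from a confusion matrix
#'
#' Computes overall accuracy and, per class one-vs-rest: sensitivity
#' (recall), specificity, PPV (precision), NPV, and F1. A ratio with a zero
#' denominator (e.g. NPV when nothing is predicted negative) is reported as
#' `NA`, never as 0 — an undefined rate is not a zero rate. AUROC is included
#' only when per-class scores are supplied; it is never guessed from labels.
#'
#' @param cm A [confusion_matrix()].
#' @param scores Optional data frame with the truth column and per-class score
#'   columns, used for AUROC (one-vs-rest macro-averaged beyond two classes).
#' @param truth Truth column name in `scores`.
#' @param n_abstained Number of patients withheld from evaluation by a
#'   confidence cutoff (bookkeeping only; metrics cover evaluated patients).
#' @return A `metrics_report`: list with `accuracy`, `by_class` tibble,
#'   `auroc`, `confusion`, `n_evaluated`, `n_abstained`.
#' @examples
#' df <- tibble::tibble(label = c("case", "case", "noncase"),
#'                      predicted_label = c("case", "noncase", "noncase"))
#' compute_metrics(confusion_matrix(df))
#' @export
compute_metrics <- function(cm, scores = NULL, truth = "label", n_abstained = 0L) {
  stopifnot(inherits(cm, "phenotype_confusion"))
  m <- unclass(cm)
  total <- sum(m)
  if (total < 1) stop("cannot compute metrics for an empty evaluation", call. = FALSE)
  classes <- rownames(m)

  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  by_class <- purrr::map(seq_along(classes), function(i) {
    tp <- m[i, i]
    fn <- sum(m[i, -i, drop = FALSE])
    fp <- sum(m[-i, i, drop = FALSE])
    tn <- total - tp - fn - fp
    sens <- safe_div(tp, tp + fn)
    spec <- safe_div(tn, tn + fp)
    ppv <- safe_div(tp, tp + fp)
    npv <- safe_div(tn, tn + fn)
    f1 <- if (is.na(ppv) || is.na(sens) || (ppv + sens) == 0) NA_real_
          else 2 * ppv * sens / (ppv + sens)
    tibble::tibble(class = classes[i], n_true = tp + fn,
                   sensitivity = sens, specificity = spec,
                   ppv = ppv, npv = npv, f1 = f1)
  }) |> purrr::list_rbind()

  auc <- if (!is.null(scores)) auroc(scores, truth = truth, class_names = classes)
         else NA_real_

  structure(
    list(accuracy = sum(diag(m)) / total, by_class = by_class, auroc = auc,
         confusion = cm, n_evaluated = as.integer(total),
         n_abstained = as.integer(n_abstained)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> accuracy %.3f on %d patients (%d abstained)",
              x$accuracy, x$n_evaluated, x$n_abstained))
  if (!is.na(x$auroc)) cat(sprintf(", AUROC %.3f", x$auroc))
  cat("\n")
  print(x$by_class)
  invisible(x)
}

#' @export
#' @method tidy metrics_report
tidy.metrics_report <- function(x, ...) {
  x$by_class
}

#' @export
#' @method glance metrics_report
glance.metrics_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, auroc = x$auroc,
                 macro_f1 = mean(x$by_class$f1, na.rm = TRUE),
                 n_evaluated = x$n_evaluated, n_abstained = x$n_abstained)
}

#' Per-class metric bars
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot metrics_report
autoplot.metrics_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$by_class,
                              c("sensitivity", "specificity", "ppv", "npv", "f1"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("accuracy %.3f (n = %d)", object$accuracy,
                                  object$n_evaluated)) +
    ggplot2::theme_minimal()
}

#' Accept predictions at or above a confidence cutoff
#'
#' Splits predictions into those confident enough to act on and those routed
#' to manual review, the selective-classification workflow for production
#' phenotyping runs.
#'
#' @param predictions Prediction tibble with a `confidence` column.
#' @param cutoff Confidence threshold in \[0, 1\]; accepted iff
#'   `confidence >= cutoff`.
#' @return List with tibbles `accepted` and `abstained` (a partition of the
#'   input rows).
#' @export
confidence_filter <- function(predictions, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff >= 0, cutoff <= 1)
  keep <- predictions$confidence >= cutoff
  list(accepted = predictions[keep, , drop = FALSE],
       abstained = predictions[!keep, , drop = FALSE])
}

#' Accuracy as a function of the confidence cutoff
#'
#' One row per distinct observed confidence value (plus cutoff 0): how many
#' predictions would be accepted at that cutoff and how accurate the accepted
#' subset is. `n_accepted` is non-increasing in the cutoff by construction;
#' on a well-calibrated model the accepted-subset accuracy rises with the
#' cutoff, quantifying the review-burden/accuracy trade-off.
#'
#' @param predictions Labeled predictions (columns `confidence`,
#'   `predicted_label`, and the truth column).
#' @param truth Truth column name.
#' @return A `confidence_curve` tibble: `cutoff`, `n_accepted`,
#'   `accuracy_accepted` (`NA` when nothing is accepted).
#' @export
confidence_curve <- function(predictions, truth = "label") {
  stopifnot(truth %in% names(predictions))
  cuts <- sort(unique(c(0, predictions$confidence)))
  correct <- predictions$predicted_label == predictions[[truth]]
  rows <- purrr::map(cuts, function(ct) {
    keep <- predictions$confidence >= ct
    tibble::tibble(
      cutoff = ct,
      n_accepted = sum(keep),
      accuracy_accepted = if (any(keep)) mean(correct[keep]) else NA_real_
    )
  }) |> purrr::list_rbind()
  structure(rows, class = c("confidence_curve", class(tibble::tibble())))
}

#' @export
#' @method autoplot confidence_curve
autoplot.confidence_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$frac_accepted <- df$n_accepted / max(df$n_accepted)
  long <- tidyr::pivot_longer(df, c("accuracy_accepted", "frac_accepted"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cutoff, y = .data$value,
                                     color = .data$series)) +
    ggplot2::geom_step() +
    ggplot2::scale_color_manual(
      values = c(accuracy_accepted = "#2c7fb8", frac_accepted = "#636363"),
      labels = c(accuracy_accepted = "accuracy on accepted",
                 frac_accepted = "fraction accepted")) +
    ggplot2::labs(x = "confidence cutoff", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}
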