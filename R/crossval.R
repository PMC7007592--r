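#' Assign patients to cross-validation folds
#'
#' Folds always partition *patients*; because each patient contributes exactly
#' one vector, no patient's data can leak between a training and a validation
#' fold.
#'
#' @param labels Character vector of class labels, one per patient.
#' @param method `"kfold"`, `"stratified_kfold"`, or `"leave_one_out"`.
#' @param n_folds Number of folds (ignored for leave-one-out).
#' @param seed Integer seed; assignment is deterministic given it.
#' @return Integer fold ids in `1..n_folds`, one per patient.
#' @export
make_folds <- function(labels, method = "stratified_kfold", n_folds = 10L, seed = 1L) {
  method <- match.arg(method, c("kfold", "stratified_kfold", "leave_one_out"))
  n <- length(labels)
  if (method == "leave_one_out") return(seq_len(n))
  n_folds <- as.integer(n_folds)
  if (n_folds < 2) stop("n_folds must be at least 2", call. = FALSE)
  if (n_folds > n) stop("n_folds exceeds the number of patients", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    if (method == "kfold") {
      sample(rep_len(seq_len(n_folds), n))
    } else {
      folds <- integer(n)
      for (cls in unique(labels)) {
        idx <- which(labels == cls)
        if (length(idx) < n_folds) {
          stop("class '", cls, "' has ", length(idx),
               " patients; fewer than n_folds = ", n_folds, call. = FALSE)
        }
        folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
      folds
    }
  })
}

#' Cross-validated out-of-fold predictions
#'
#' Splits labeled patient vectors into folds, trains on each fold's
#' complement, and predicts the held-out fold, so every patient is predicted
#' exactly once by a model that never saw it. The whole procedure is
#' deterministic given the two seeds.
#'
#' @param data Labeled patient vectors (see [train_model()]).
#' @param algorithm One of [phenotype_algorithms].
#' @param hyperparameters Passed to [train_model()].
#' @param cv_method `"kfold"`, `"stratified_kfold"` (default, the usual
#'   setting for class-imbalanced phenotype corpora), or `"leave_one_out"`.
#' @param n_folds Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param model_seed Seed for each fold's model fit.
#' @return A `phenotype_cv` object: `$predictions` (tibble `patient_id`,
#'   `label`, `fold`, `predicted_label`, `confidence`, per-class scores),
#'   `$accuracy` (out-of-fold fraction correct), and the run configuration.
#' @examples
#' \donttest{
#' bench <- make_benchmark_suite(seed = 7)$balanced
#' pv <- vectorize_patients(bench$corpus, bench$features)
#' cv <- crossval(pv, "random_forest", n_folds = 10, seed = 7)
#' glance(cv)
#' }
#' @export
crossval <- function(data, algorithm = "random_forest", hyperparameters = list(),
                     cv_method = "stratified_kfold", n_folds = 10L,
                     seed = 1L, model_seed = seed) {
  data <- tibble::as_tibble(data)
  if (any(is.na(data$label))) stop("cross-validation requires labeled patients", call. = FALSE)
  folds <- make_folds(data$label, method = cv_method, n_folds = n_folds, seed = seed)
  feat <- feature_columns(data)

  preds <- purrr::map(sort(unique(folds)), function(k) {
    train_idx <- which(folds != k)
    test_idx <- which(folds == k)
    model <- train_model(data[train_idx, , drop = FALSE], algorithm = algorithm,
                         hyperparameters = hyperparameters,
                         seed = as.integer(model_seed) + k)
    p <- stats::predict(model, data[test_idx, , drop = FALSE])
    p$label <- data$label[test_idx]
    p$fold <- k
    p
  }) |> purrr::list_rbind()

  # a fold model may have seen fewer classes; normalize score columns
  classes <- sort(unique(data$label))
  for (cls in classes) if (!cls %in% names(preds)) preds[[cls]] <- 0
  preds <- preds[, c("patient_id", "label", "fold", "predicted_label",
                     "confidence", classes)]
  preds[classes][is.na(preds[classes])] <- 0
  preds <- dplyr::arrange(preds, .data$patient_id)

  structure(
    list(
      predictions = preds,
      accuracy = mean(preds$predicted_label == preds$label),
      algorithm = algorithm,
      cv_method = cv_method,
      n_folds = if (cv_method == "leave_one_out") nrow(data) else as.integer(n_folds),
      seed = as.integer(seed),
      model_seed = as.integer(model_seed),
      class_names = classes,
      folds = stats::setNames(folds, data$patient_id),
      hyperparameters = hyperparameters
    ),
    class = "phenotype_cv"
  )
}

#' @export
print.phenotype_cv <- function(x, ...) {
  cat(sprintf("<phenotype_cv> %s, %s (%d folds): out-of-fold accuracy %.3f over %d patients\n",
              x$algorithm, x$cv_method, x$n_folds, x$accuracy, nrow(x$predictions)))
  invisible(x)
}

#' @export
#' @method tidy phenotype_cv
tidy.phenotype_cv <- function(x, ...) {
  x$predictions
}

#' @export
#' @method glance phenotype_cv
glance.phenotype_cv <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    cv_method = x$cv_method,
    n_folds = x$n_folds,
    n_patients = nrow(x$predictions),
    accuracy = x$accuracy,
    mean_confidence = mean(x$predictions$confidence),
    seed = x$seed
  )
}

#' Plot out-of-fold confidence by correctness
#'
#' Histogram of prediction confidence, filled by whether the out-of-fold
#' prediction was correct — the quickest read on whether low-confidence calls
#' are the ones worth routing to manual review.
#'
#' @param object A `phenotype_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot phenotype_cv
autoplot.phenotype_cv <- function(object, ...) {
  df <- object$predictions
  df$correct <- ifelse(df$predicted_label == df$label, "correct", "incorrect")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$confidence, fill = .data$correct)) +
    ggplot2::geom_histogram(bins = 20, boundary = 0, position = "stack") +
    ggplot2::scale_fill_manual(values = c(correct = "#2c7fb8", incorrect = "#d95f02")) +
    ggplot2::labs(x = "prediction confidence", y = "patients", fill = NULL,
                  title = sprintf("%s, %d-fold %s: out-of-fold accuracy %.2f",
                                  object$algorithm, object$n_folds,
                                  object$cv_method, object$accuracy)) +
    ggplot2::theme_minimal()
}
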