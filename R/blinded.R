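#' Seal the labels of a held-out set
#'
#' Produces a blinded evaluation set: the feature vectors with the label
#' column removed and the true labels sealed away. Predictions can be made on
#' a blinded set, but no metric can be computed until [unblind()] is called —
#' the mechanical analogue of keeping the analyst blind to held-out labels
#' until the model has committed to its predictions. Unblinding is logged and
#' idempotent (a second call adds nothing to the log).
#'
#' @param data Labeled patient vectors (e.g. the test side of
#'   [split_corpus()] passed through [vectorize_patients()]).
#' @param label_col Name of the label column to seal.
#' @return A `blinded_set` with `$data` (labels removed).
#' @export
blind_labels <- function(data, label_col = "label") {
  data <- tibble::as_tibble(data)
  if (!label_col %in% names(data)) {
    stop("no '", label_col, "' column to seal", call. = FALSE)
  }
  if (any(is.na(data[[label_col]]))) {
    stop("cannot blind a set with missing labels", call. = FALSE)
  }
  vault <- new.env(parent = emptyenv())
  vault$labels <- stats::setNames(as.character(data[[label_col]]),
                                  as.character(data$patient_id))
  vault$unblinded <- FALSE
  vault$log <- character()
  open <- data[, setdiff(names(data), label_col), drop = FALSE]
  attr(open, "feature_names") <- setdiff(feature_columns(data), label_col)
  structure(list(data = open, vault = vault), class = "blinded_set")
}

#' @export
print.blinded_set <- function(x, ...) {
  cat(sprintf("<blinded_set> %d patients, labels %s\n", nrow(x$data),
              if (x$vault$unblinded) "UNBLINDED" else "sealed"))
  invisible(x)
}

#' Predict on a blinded set
#'
#' Classifies the sealed set's patients without touching the sealed labels.
#' @param model A `phenotype_model`.
#' @param blinded A `blinded_set`.
#' @return Prediction tibble as from [predict.phenotype_model()].
#' @export
evaluate_blinded <- function(model, blinded) {
  stopifnot(inherits(model, "phenotype_model"), inherits(blinded, "blinded_set"))
  stats::predict(model, blinded$data)
}

#' Reveal a blinded set's labels
#'
#' Marks the set unblinded and appends one entry to its audit log; calling it
#' again is a no-op (idempotent, still a single log entry).
#'
#' @param blinded A `blinded_set`.
#' @return The same `blinded_set`, now unblinded.
#' @export
unblind <- function(blinded) {
  stopifnot(inherits(blinded, "blinded_set"))
  if (!blinded$vault$unblinded) {
    blinded$vault$unblinded <- TRUE
    blinded$vault$log <- c(blinded$vault$log,
                           sprintf("unblinded %d labels at %s",
                                   length(blinded$vault$labels),
                                   format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  }
  blinded
}

#' Audit log of a blinded set
#' @param blinded A `blinded_set`.
#' @return Character vector of log entries (empty while still sealed).
#' @export
unblind_log <- function(blinded) {
  stopifnot(inherits(blinded, "blinded_set"))
  blinded$vault$log
}

#' Sealed labels, after unblinding
#' @param blinded A `blinded_set`.
#' @return Tibble `patient_id`, `label`; an error while still sealed.
#' @export
sealed_labels <- function(blinded) {
  stopifnot(inherits(blinded, "blinded_set"))
  if (!blinded$vault$unblinded) {
    stop("the set is still blinded; call unblind() first", call. = FALSE)
  }
  tibble::tibble(patient_id = names(blinded$vault$labels),
                 label = unname(blinded$vault$labels))
}

#' Score blinded predictions after unblinding
#'
#' Joins the predictions to the revealed labels and computes the full
#' diagnostic report. Refuses to run while the set is sealed.
#'
#' @param blinded An [unblind()]ed `blinded_set`.
#' @param predictions Predictions from [evaluate_blinded()].
#' @param n_abstained Passed through to [compute_metrics()].
#' @return A `metrics_report`.
#' @export
score_blinded <- function(blinded, predictions, n_abstained = 0L) {
  labs <- sealed_labels(blinded)  # errors if still sealed
  joined <- dplyr::inner_join(predictions, labs, by = "patient_id")
  if (nrow(joined) != nrow(predictions)) {
    stop("predictions contain patients not in the blinded set", call. = FALSE)
  }
  cm <- confusion_matrix(joined)
  compute_metrics(cm, scores = joined, n_abstained = n_abstained)
}
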