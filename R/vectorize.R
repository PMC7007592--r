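#' Per-sentence match counts for one note
#'
#' The first level of the aggregation hierarchy: each sentence of the note is
#' scanned once per feature and the non-overlapping matches are counted.
#'
#' @param text Note text (a single string; empty gives zero rows).
#' @param features A [feature_set()].
#' @return A tibble with columns `sentence` (index), `text` (the sentence),
#'   and one integer count column per feature, in feature order.
#' @export
sentence_counts <- function(text, features) {
  stopifnot(inherits(features, "feature_set"))
  sents <- segment_sentences(text)
  counts <- purrr::pmap(features, function(name, pattern, case_sensitive) {
    count_matches(sents, pattern, case_sensitive)
  })
  names(counts) <- features$name
  tibble::tibble(sentence = seq_along(sents), text = sents, !!!counts)
}

#' Note-level feature vectors
#'
#' Sums per-sentence match counts over each note's sentences. A note with
#' empty text contributes an all-zero vector: it is a real observation of
#' absence and still counts toward the patient mean.
#'
#' @param corpus A [note_corpus()].
#' @param features A [feature_set()].
#' @return A tibble with one row per note: `note_id`, `patient_id`, then one
#'   integer column per feature.
#' @export
vectorize_notes <- function(corpus, features) {
  stopifnot(inherits(corpus, "note_corpus"), inherits(features, "feature_set"))
  count_rows <- purrr::map(corpus$text, function(txt) {
    sents <- segment_sentences(txt)
    vapply(seq_len(nrow(features)), function(j) {
      if (length(sents) == 0) 0L
      else sum(count_matches(sents, features$pattern[j], features$case_sensitive[j]))
    }, integer(1))
  })
  mat <- if (length(count_rows) == 0) {
    matrix(integer(), nrow = 0, ncol = nrow(features))
  } else {
    do.call(rbind, count_rows)
  }
  colnames(mat) <- features$name
  dplyr::bind_cols(
    tibble::tibble(note_id = corpus$note_id, patient_id = corpus$patient_id),
    tibble::as_tibble(mat)
  )
}

#' Patient-level feature vectors
#'
#' The engine's output and the classifiers' input: for each patient, the
#' arithmetic mean of that patient's note vectors (sentence counts summed
#' within each note, then averaged across notes). The mean is invariant to
#' note order and to duplicating every note, and each coordinate lies within
#' the range of the patient's note-level counts.
#'
#' @param corpus A [note_corpus()].
#' @param features A [feature_set()].
#' @return A tibble with one row per patient, sorted by `patient_id`:
#'   `patient_id`, `label` (`NA` when unlabeled), `n_notes`, then one numeric
#'   column per feature.
#' @examples
#' corp <- note_corpus(tibble::tibble(
#'   note_id = c("n1", "n2"), patient_id = c("p1", "p1"),
#'   text = c("Pelvic pain reported. Pelvic pain worsening.", "No complaints."),
#'   metadata = list(c(label = "case"), c(label = "case"))
#' ))
#' fs <- feature_set(tibble::tibble(name = "pelvic pain", pattern = "pelvic pain",
#'                                  case_sensitive = FALSE))
#' vectorize_patients(corp, fs)
#' @export
vectorize_patients <- function(corpus, features) {
  nv <- vectorize_notes(corpus, features)
  pats <- corpus_patients(corpus)
  means <- nv |>
    dplyr::select(-"note_id") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean), .groups = "drop")
  out <- dplyr::left_join(pats, means, by = "patient_id") |>
    dplyr::arrange(.data$patient_id)
  structure(out, feature_names = features$name,
            class = c("patient_vectors", class(tibble::tibble())))
}

#' Columns of a patient-vector table that are feature coordinates
#' @param vectors A tibble from [vectorize_patients()] (or any table whose
#'   non-feature columns are `patient_id`, `label`, `n_notes`, `fold`).
#' @return Character vector of feature column names, in coordinate order.
#' @export
feature_columns <- function(vectors) {
  fn <- attr(vectors, "feature_names")
  if (!is.null(fn)) return(fn)
  setdiff(names(vectors), c("patient_id", "label", "n_notes", "fold"))
}

#' Audit trail of feature matches
#'
#' Locates every feature match in every note, sentence by sentence, as
#' half-open 0-based offsets into the full note text — a machine-readable
#' stand-in for visually highlighted matches, suitable for review exports.
#'
#' @param corpus A [note_corpus()].
#' @param features A [feature_set()].
#' @return A tibble `note_id`, `feature`, `start`, `end` (offsets into the
#'   note's text), sorted and non-overlapping within a feature and note.
#' @export
audit_spans <- function(corpus, features) {
  stopifnot(inherits(corpus, "note_corpus"), inherits(features, "feature_set"))
  purrr::map2(corpus$note_id, corpus$text, function(id, txt) {
    sents <- segment_sentences(txt)
    if (length(sents) == 0) return(NULL)
    # anchor each sentence at its first occurrence at/after the previous one
    offs <- integer(length(sents))
    cursor <- 1L
    for (i in seq_along(sents)) {
      hit <- regexpr(sents[i], substring(txt, cursor), fixed = TRUE)
      offs[i] <- cursor + as.integer(hit) - 1L
      cursor <- offs[i] + nchar(sents[i])
    }
    purrr::pmap(features, function(name, pattern, case_sensitive) {
      spans <- purrr::map2(sents, offs, function(s, o) {
        sp <- match_spans(s, pattern, case_sensitive)
        sp$start <- sp$start + o - 1L
        sp$end <- sp$end + o - 1L
        sp
      }) |> purrr::list_rbind()
      if (nrow(spans) == 0) return(NULL)
      tibble::tibble(note_id = id, feature = name, start = spans$start, end = spans$end)
    }) |> purrr::list_rbind()
  }) |>
    purrr::list_rbind()
}

#' Write the patient feature matrix as CSV
#'
#' Header is `patient_id,label,<feature names...>` for external analysis.
#' @param vectors Output of [vectorize_patients()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(vectors, path) {
  cols <- c("patient_id", "label", feature_columns(vectors))
  readr::write_csv(tibble::as_tibble(vectors)[, cols], path)
  invisible(path)
}

#' Write the match audit trail as JSON
#' @param spans Output of [audit_spans()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_audit_spans <- function(spans, path) {
  json <- jsonlite::toJSON(spans, dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  write_atomically(json, path)
  invisible(path)
}
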