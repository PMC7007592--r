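#' Construct a clinical-note corpus
#'
#' A corpus is a tibble with one row per note and columns `note_id`,
#' `patient_id`, `text`, `note_date`, `note_type`, and `metadata` (a
#' list-column of named character vectors). One metadata key, named by
#' `label_key`, may carry the gold-standard phenotype class of the patient the
#' note belongs to. Labels attach to the patient: if two notes of the same
#' patient carry different values under `label_key`, construction fails rather
#' than voting, since a silently resolved disagreement would corrupt the gold
#' standard.
#'
#' @param notes A data frame with at least `note_id`, `patient_id`, `text`.
#'   `note_date` (ISO-8601 string or `NA`), `note_type` and `metadata` are
#'   optional and filled with `NA`/empty metadata when absent.
#' @param label_key Name of the metadata field holding the gold-standard class
#'   label, when known. Unlabeled notes (metadata lacking the key) are allowed.
#' @return A `note_corpus`: the validated notes tibble, ordered by patient,
#'   then note date, then note id, with the `label_key` stored as an attribute.
#' @examples
#' notes <- tibble::tibble(
#'   note_id = c("n1", "n2"), patient_id = c("p1", "p1"),
#'   text = c("Reports pelvic pain.", "Denies pelvic pain today."),
#'   metadata = list(c(class = "symptomatic"), c(class = "symptomatic"))
#' )
#' corp <- note_corpus(notes, label_key = "class")
#' corpus_patients(corp)
#' @export
note_corpus <- function(notes, label_key = "label") {
  stopifnot(is.data.frame(notes), is.character(label_key), length(label_key) == 1)
  required <- c("note_id", "patient_id", "text")
  missing_cols <- setdiff(required, names(notes))
  if (length(missing_cols) > 0) {
    stop("corpus is missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  notes <- tibble::as_tibble(notes)
  if (!"note_date" %in% names(notes)) notes$note_date <- NA_character_
  if (!"note_type" %in% names(notes)) notes$note_type <- NA_character_
  if (!"metadata" %in% names(notes)) notes$metadata <- rep(list(character()), nrow(notes))
  notes <- dplyr::select(notes, "note_id", "patient_id", "text", "note_date",
                         "note_type", "metadata")
  notes$note_id <- as.character(notes$note_id)
  notes$patient_id <- as.character(notes$patient_id)
  notes$text <- ifelse(is.na(notes$text), "", as.character(notes$text))
  notes$note_date <- as.character(notes$note_date)
  notes$note_type <- as.character(notes$note_type)
  notes$metadata <- purrr::map(notes$metadata, function(m) {
    if (is.null(m) || length(m) == 0) return(character())
    m <- unlist(m)
    out <- as.character(m)
    names(out) <- names(m)
    out
  })

  if (any(is.na(notes$note_id) | notes$note_id == "")) {
    stop("every note needs a nonempty note_id", call. = FALSE)
  }
  if (anyDuplicated(notes$note_id)) {
    dup <- unique(notes$note_id[duplicated(notes$note_id)])
    stop("duplicate note_id: ", paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(notes$patient_id) | notes$patient_id == "")) {
    stop("every note needs a nonempty patient_id", call. = FALSE)
  }
  bad_meta <- purrr::map_lgl(notes$metadata, function(m) {
    length(m) > 0 && (is.null(names(m)) || any(names(m) == "") || anyDuplicated(names(m)) > 0)
  })
  if (any(bad_meta)) {
    stop("metadata must be uniquely named for note(s): ",
         paste(utils::head(notes$note_id[bad_meta], 5), collapse = ", "), call. = FALSE)
  }

  note_label <- purrr::map_chr(notes$metadata, function(m) {
    if (label_key %in% names(m)) unname(m[[label_key]]) else NA_character_
  })
  conflicts <- tapply(note_label, notes$patient_id, function(x) {
    length(unique(x[!is.na(x)])) > 1
  })
  if (any(conflicts)) {
    stop("conflicting labels within patient(s): ",
         paste(names(conflicts)[conflicts], collapse = ", "), call. = FALSE)
  }

  # reproducible iteration order: patient, then date, then note id
  ord <- order(notes$patient_id, notes$note_date, notes$note_id,
               na.last = TRUE, method = "radix")
  notes <- notes[ord, ]
  structure(notes, label_key = label_key,
            class = c("note_corpus", class(tibble::tibble())))
}

#' @export
print.note_corpus <- function(x, ...) {
  pats <- corpus_patients(x)
  cat(sprintf("<note_corpus> %d notes, %d patients (label key: '%s')\n",
              nrow(x), nrow(pats), label_key(x)))
  if (any(!is.na(pats$label))) {
    tab <- table(pats$label, useNA = "no")
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        sprintf("(unlabeled: %d)\n", sum(is.na(pats$label))))
  } else {
    cat("  unlabeled corpus\n")
  }
  NextMethod()
}

#' Metadata key carrying the gold-standard label
#' @param corpus A `note_corpus`.
#' @return The label key string.
#' @export
label_key <- function(corpus) {
  attr(corpus, "label_key") %||% "label"
}

#' Patient-level view of a corpus
#'
#' Groups notes by patient and resolves the per-patient gold label from the
#' designated metadata key (`NA` for unlabeled patients).
#'
#' @param corpus A `note_corpus`.
#' @return A tibble with one row per patient: `patient_id`, `label`,
#'   `n_notes`, sorted by `patient_id`.
#' @export
corpus_patients <- function(corpus) {
  key <- label_key(corpus)
  lab <- purrr::map_chr(corpus$metadata, function(m) {
    if (key %in% names(m)) unname(m[[key]]) else NA_character_
  })
  tibble::tibble(patient_id = corpus$patient_id, label = lab) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      label = if (all(is.na(.data$label))) NA_character_ else unique(.data$label[!is.na(.data$label)]),
      n_notes = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$patient_id)
}

#' Distinct class labels present in a corpus
#' @param corpus A `note_corpus`.
#' @return Sorted character vector of the labels observed on labeled patients.
#' @export
corpus_classes <- function(corpus) {
  lab <- corpus_patients(corpus)$label
  sort(unique(lab[!is.na(lab)]))
}

#' Read a note corpus from JSON
#'
#' The on-disk dialect is a UTF-8 JSON array of note objects with keys
#' `note_id`, `patient_id`, `text`, optional `note_date` and `note_type`, and
#' a string-keyed `metadata` object; the gold label, when known, lives inside
#' `metadata` under `label_key`.
#'
#' @param path Path to a JSON corpus file.
#' @param label_key Metadata key carrying the gold label.
#' @return A validated [note_corpus()].
#' @export
read_corpus <- function(path, label_key = "label") {
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  recs <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed corpus JSON in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!is.list(recs)) stop("corpus JSON must be an array of note objects", call. = FALSE)
  notes <- purrr::imap(recs, function(r, i) {
    if (!is.list(r)) stop("corpus record ", i, " is not an object", call. = FALSE)
    for (k in c("note_id", "patient_id")) {
      if (is.null(r[[k]])) stop("corpus record ", i, " lacks '", k, "'", call. = FALSE)
    }
    meta <- r$metadata
    tibble::tibble(
      note_id = as.character(r$note_id),
      patient_id = as.character(r$patient_id),
      text = if (is.null(r$text)) "" else as.character(r$text),
      note_date = if (is.null(r$note_date)) NA_character_ else as.character(r$note_date),
      note_type = if (is.null(r$note_type)) NA_character_ else as.character(r$note_type),
      metadata = list(if (is.null(meta)) character() else {
        v <- as.character(unlist(meta))
        names(v) <- names(meta)
        v
      })
    )
  }) |> purrr::list_rbind()
  note_corpus(notes, label_key = label_key)
}

#' Write a corpus to JSON
#'
#' Writes the documented JSON dialect; [read_corpus()] on the result
#' reproduces the corpus field for field (empty texts stay empty strings,
#' clinical unicode survives byte-identically).
#'
#' @param corpus A `note_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "note_corpus"))
  recs <- purrr::pmap(corpus, function(note_id, patient_id, text, note_date,
                                       note_type, metadata) {
    r <- list(note_id = note_id, patient_id = patient_id, text = text)
    if (!is.na(note_date)) r$note_date <- note_date
    if (!is.na(note_type)) r$note_type <- note_type
    r$metadata <- if (length(metadata) == 0) stats::setNames(list(), character()) else as.list(metadata)
    r
  })
  json <- jsonlite::toJSON(recs, auto_unbox = TRUE, pretty = TRUE)
  write_atomically(json, path)
  invisible(path)
}

#' Export patient labels as CSV
#' @param corpus A `note_corpus`.
#' @param path Output path; written as `patient_id,label`.
#' @return `path`, invisibly.
#' @export
write_patient_labels <- function(corpus, path) {
  readr::write_csv(corpus_patients(corpus)[, c("patient_id", "label")], path)
  invisible(path)
}

#' Split a corpus into training and held-out sets
#'
#' Partitions *patients* (never notes) into a training and a testing corpus.
#' With `stratified = TRUE` the per-class allocation follows the requested
#' fraction or counts within each class, so class proportions are preserved up
#' to rounding. The split is deterministic given `seed`.
#'
#' @param corpus A fully labeled `note_corpus`.
#' @param prop Training fraction in (0, 1), or a named integer vector of
#'   per-class training counts.
#' @param stratified Stratify by class (default `TRUE`).
#' @param seed Integer seed controlling the random assignment.
#' @return A list with elements `train` and `test`, both `note_corpus`.
#' @export
split_corpus <- function(corpus, prop = 0.5, stratified = TRUE, seed = 1L) {
  stopifnot(inherits(corpus, "note_corpus"))
  pats <- corpus_patients(corpus)
  if (any(is.na(pats$label))) {
    stop("split_corpus requires every patient to be labeled", call. = FALSE)
  }
  counts <- NULL
  if (is.numeric(prop) && length(prop) == 1 && is.null(names(prop))) {
    if (prop <= 0 || prop >= 1) stop("prop must lie in (0, 1)", call. = FALSE)
  } else {
    counts <- prop
    if (is.null(names(counts)) || any(!names(counts) %in% pats$label)) {
      stop("per-class counts must be named by observed class labels", call. = FALSE)
    }
    if (any(counts < 1)) stop("per-class counts must be positive", call. = FALSE)
  }

  by_class <- split(pats$patient_id, pats$label)
  train_ids <- withr::with_seed(as.integer(seed), {
    if (stratified || !is.null(counts)) {
      unlist(purrr::imap(by_class, function(ids, cls) {
        if (length(ids) < 2) {
          stop("stratified split needs at least 2 patients in class '", cls, "'",
               call. = FALSE)
        }
        n_train <- if (is.null(counts)) round(length(ids) * prop) else counts[[cls]]
        if (n_train > length(ids)) {
          stop("requested ", n_train, " training patients but class '", cls,
               "' has only ", length(ids), call. = FALSE)
        }
        n_train <- max(1L, min(length(ids) - 1L, as.integer(n_train)))
        ids[sample.int(length(ids), n_train)]
      }), use.names = FALSE)
    } else {
      n_train <- max(1L, min(nrow(pats) - 1L, round(nrow(pats) * prop)))
      pats$patient_id[sample.int(nrow(pats), n_train)]
    }
  })
  subset_corpus(corpus, train_ids, setdiff(pats$patient_id, train_ids))
}

subset_corpus <- function(corpus, train_ids, test_ids) {
  key <- label_key(corpus)
  take <- function(ids) {
    note_corpus(corpus[corpus$patient_id %in% ids, , drop = FALSE], label_key = key)
  }
  list(train = take(train_ids), test = take(test_ids))
}

# Atomic text write: to a sibling temp file, then rename over the target.
write_atomically <- function(text, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, open = "wb")
  writeLines(text, con, useBytes = TRUE)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}
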