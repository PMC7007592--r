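#' Neutral filler vocabulary for synthetic notes
#'
#' Routine clinic-visit words verified at generation time to produce zero
#' matches against the configured feature set.
#' @export
default_filler_vocabulary <- c(
  "patient", "seen", "in", "clinic", "today", "stable", "and", "well",
  "appearing", "vitals", "within", "expected", "limits", "reviewed",
  "plan", "continue", "current", "medications", "return", "as", "needed",
  "discussed", "at", "length", "rest", "advised", "hydration", "encouraged",
  "sleep", "adequate", "diet", "balanced", "exercise", "regular", "school",
  "attendance", "good", "mood", "pleasant", "cooperative", "labs", "pending",
  "follow", "scheduled", "family", "present", "questions", "answered"
)

#' Configure a synthetic note-corpus generator
#'
#' Describes a study design to simulate: classes with per-feature planted
#' phrase-emission probabilities, a phrase bank of surface strings, note and
#' sentence count ranges, filler text, and a negation rate. The generator
#' emulates the statistical structure a phenotype classifier consumes —
#' class-dependent planted phrases diluted in neutral filler across multi-note
#' patients — not clinically realistic narrative.
#'
#' Everything is verified up front so tests can never silently decouple from
#' the regex dialect: each `match` phrase must match its feature, each `decoy`
#' must match *no* feature, filler text must match nothing, and each rendered
#' planted sentence must survive sentence segmentation intact. Per sentence, at
#' most one phrase is planted (feature emission probabilities are treated as
#' mutually exclusive and must sum to at most 1 per class); a planted phrase is
#' swapped for one of its feature's `negated` surface forms with probability
#' `negation_rate` (overridable per class via a `negation_rate` column), so
#' class labels can be made to depend on negated rather than affirmative
#' language.
#'
#' @param classes Tibble with columns `class`, `n_patients`, one numeric
#'   emission-probability column per feature name (missing columns default to
#'   0), and optionally `negation_rate`.
#' @param features A [feature_set()]; defines the match semantics phrases are
#'   validated against and the ground-truth count columns.
#' @param phrase_bank Tibble `feature`, `phrase`, `type` with `type` one of
#'   `"match"` (must match its feature), `"negated"` (negated surface form),
#'   `"decoy"` (near-miss that must match nothing).
#' @param notes_per_patient,sentences_per_note Inclusive integer ranges
#'   `c(lo, hi)`.
#' @param filler_vocabulary Words for filler sentences.
#' @param negation_rate Default probability a planted phrase is emitted in a
#'   negated surface form.
#' @param decoy_rate Probability a filler sentence carries a decoy phrase.
#' @param label_key Metadata key to store the gold label under.
#' @param seed Integer seed; generation is deterministic given it.
#' @return A validated `generator_config` (list).
#' @export
generator_config <- function(classes, features, phrase_bank,
                             notes_per_patient = c(3L, 5L),
                             sentences_per_note = c(4L, 8L),
                             filler_vocabulary = default_filler_vocabulary,
                             negation_rate = 0, decoy_rate = 0.1,
                             label_key = "label", seed = 1L) {
  stopifnot(inherits(features, "feature_set"))
  classes <- tibble::as_tibble(classes)
  if (!all(c("class", "n_patients") %in% names(classes))) {
    stop("classes needs 'class' and 'n_patients' columns", call. = FALSE)
  }
  for (f in features$name) {
    if (!f %in% names(classes)) classes[[f]] <- 0
  }
  if (!"negation_rate" %in% names(classes)) classes$negation_rate <- negation_rate
  probs <- as.matrix(classes[, features$name, drop = FALSE])
  if (any(probs < 0 | probs > 1) || any(classes$negation_rate < 0 | classes$negation_rate > 1)) {
    stop("emission and negation probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(rowSums(probs) > 1)) {
    stop("per-class emission probabilities must sum to at most 1 ",
         "(at most one phrase is planted per sentence)", call. = FALSE)
  }
  phrase_bank <- tibble::as_tibble(phrase_bank)
  stopifnot(all(c("feature", "phrase", "type") %in% names(phrase_bank)))
  if (!all(phrase_bank$type %in% c("match", "negated", "decoy"))) {
    stop("phrase type must be one of match/negated/decoy", call. = FALSE)
  }
  if (!all(phrase_bank$feature %in% features$name)) {
    stop("phrase bank references unknown feature(s): ",
         paste(setdiff(phrase_bank$feature, features$name), collapse = ", "),
         call. = FALSE)
  }

  render <- function(phrase) {
    if (grepl("[.?!]$", phrase)) phrase else paste0(phrase, ".")
  }
  count_all_features <- function(text) {
    vapply(seq_len(nrow(features)), function(j) {
      sum(count_matches(segment_sentences(text), features$pattern[j],
                        features$case_sensitive[j]))
    }, integer(1))
  }

  # --- generation-time verification -----------------------------------------
  purrr::pwalk(phrase_bank, function(feature, phrase, type) {
    j <- match(feature, features$name)
    hits <- count_matches(phrase, features$pattern[j], features$case_sensitive[j])
    if (type == "match" && hits == 0) {
      stop("phrase '", phrase, "' does not match its feature '", feature, "'",
           call. = FALSE)
    }
    if (type == "decoy" && any(count_all_features(phrase) > 0)) {
      stop("decoy '", phrase, "' matches a feature; decoys must match nothing",
           call. = FALSE)
    }
    rendered <- render(phrase)
    if (length(segment_sentences(rendered)) != 1) {
      stop("phrase '", phrase, "' does not survive segmentation as one sentence",
           call. = FALSE)
    }
  })
  filler_probe <- c(paste(filler_vocabulary, collapse = " "),
                    paste(rev(filler_vocabulary), collapse = " "))
  for (probe in filler_probe) {
    if (any(count_all_features(probe) > 0)) {
      stop("filler vocabulary matches a feature; filler must be neutral", call. = FALSE)
    }
  }

  # static per-phrase count vector against every feature: the ground truth
  # for any sentence in which this phrase is planted
  bank <- phrase_bank[phrase_bank$type != "decoy", , drop = FALSE]
  bank$rendered <- vapply(bank$phrase, render, character(1))
  bank$counts <- purrr::map(bank$rendered, count_all_features)
  decoys <- phrase_bank$phrase[phrase_bank$type == "decoy"]

  structure(
    list(classes = classes, features = features, bank = bank, decoys = decoys,
         notes_per_patient = as.integer(notes_per_patient),
         sentences_per_note = as.integer(sentences_per_note),
         filler_vocabulary = filler_vocabulary, decoy_rate = decoy_rate,
         label_key = label_key, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Generate a synthetic note corpus with known ground truth
#'
#' Draws a corpus from a [generator_config()]: per patient, a random number
#' of notes; per note, a random number of sentences; per sentence, either one
#' planted phrase (chosen by the class's emission probabilities, possibly in
#' negated surface form) or neutral filler (possibly carrying a decoy).
#' Alongside the corpus it returns the exact per-note planted match counts
#' for every feature — by construction these equal what the vectorization
#' engine counts on the generated text, making every pipeline stage testable
#' end to end without any real clinical data.
#'
#' @param config A `generator_config`.
#' @return List with `corpus` (a [note_corpus()]), `ground_truth` (tibble
#'   `patient_id`, `note_id`, `feature`, `planted_count`), and `config`.
#' @examples
#' bench <- make_benchmark_suite(seed = 42)
#' gen <- bench$balanced
#' vectorize_patients(gen$corpus, gen$features)
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  fs <- config$features
  nf <- nrow(fs)
  withr::with_seed(config$seed, {
    pid <- 0L
    all_notes <- list()
    all_gt <- list()
    for (ci in seq_len(nrow(config$classes))) {
      cls <- config$classes$class[ci]
      p_emit <- as.numeric(config$classes[ci, fs$name])
      neg_rate <- config$classes$negation_rate[ci]
      for (k in seq_len(config$classes$n_patients[ci])) {
        pid <- pid + 1L
        patient_id <- sprintf("p%04d", pid)
        n_notes <- sample_range(config$notes_per_patient)
        for (ni in seq_len(n_notes)) {
          note_id <- sprintf("%s-n%02d", patient_id, ni)
          n_sent <- sample_range(config$sentences_per_note)
          planted <- integer(nf)
          sents <- character(n_sent)
          for (si in seq_len(n_sent)) {
            u <- stats::runif(1)
            j <- planted_feature(u, p_emit)
            if (!is.na(j)) {
              row <- draw_phrase(config$bank, fs$name[j], neg_rate)
              sents[si] <- row$rendered
              planted <- planted + row$counts[[1]]
            } else {
              sents[si] <- filler_sentence(config)
            }
          }
          all_notes[[length(all_notes) + 1L]] <- tibble::tibble(
            note_id = note_id, patient_id = patient_id,
            text = paste(sents, collapse = " "),
            note_date = sprintf("2020-%02d-%02d", 1L + (ni - 1L) %/% 28L,
                                1L + (ni - 1L) %% 28L),
            note_type = "progress note",
            metadata = list(stats::setNames(cls, config$label_key))
          )
          all_gt[[length(all_gt) + 1L]] <- tibble::tibble(
            patient_id = patient_id, note_id = note_id,
            feature = fs$name, planted_count = planted
          )
        }
      }
    }
    corpus <- note_corpus(purrr::list_rbind(all_notes), label_key = config$label_key)
    list(corpus = corpus, ground_truth = purrr::list_rbind(all_gt), config = config)
  })
}

sample_range <- function(range) {
  if (range[1] == range[2]) range[1] else sample(seq(range[1], range[2]), 1L)
}

# index of the feature planted in this sentence, or NA for filler;
# emission probabilities partition [0, sum(p)] of the uniform draw
planted_feature <- function(u, p_emit) {
  cum <- cumsum(p_emit)
  j <- which(u < cum)[1]
  if (is.na(j)) NA_integer_ else j
}

draw_phrase <- function(bank, feature_name, neg_rate) {
  negated <- bank[bank$feature == feature_name & bank$type == "negated", , drop = FALSE]
  positive <- bank[bank$feature == feature_name & bank$type == "match", , drop = FALSE]
  pool <- if (nrow(negated) > 0 && stats::runif(1) < neg_rate) negated else positive
  if (nrow(pool) == 0) {
    stop("no usable phrase for feature '", feature_name, "'", call. = FALSE)
  }
  pool[sample.int(nrow(pool), 1L), c("rendered", "counts")]
}

filler_sentence <- function(config) {
  words <- sample(config$filler_vocabulary, sample(4:9, 1L), replace = TRUE)
  if (length(config$decoys) > 0 && stats::runif(1) < config$decoy_rate) {
    words <- append(words, sample(config$decoys, 1L),
                    after = sample.int(length(words), 1L))
  }
  s <- paste(words, collapse = " ")
  paste0(toupper(substring(s, 1, 1)), substring(s, 2), ".")
}

#' Write generator ground truth as JSON
#' @param ground_truth Tibble from [generate_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  json <- jsonlite::toJSON(ground_truth, dataframe = "rows", auto_unbox = TRUE,
                           pretty = TRUE)
  write_atomically(json, path)
  invisible(path)
}
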