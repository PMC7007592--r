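# Shared fixtures and independent oracles.
#
# Counting oracles use stringr (the ICU regex engine) so the engine under
# test (PCRE) is checked against a genuinely different implementation; the
# fixture patterns are restricted to syntax both dialects share.

tiny_corpus <- function(label_key = "label") {
  note_corpus(tibble::tibble(
    note_id = c("n1", "n2", "n3"),
    patient_id = c("p1", "p1", "p2"),
    text = c(
      "Patient reports pelvic pain. Pelvic pain is chronic.",
      "Denies pelvic pain today.\nEar tubes placed in 2015.",
      "Routine visit. No complaints."
    ),
    note_date = c("2020-01-02", "2020-02-03", "2020-01-15"),
    metadata = list(c(label = "case"), c(label = "case"), c(label = "noncase"))
  ), label_key = label_key)
}

tiny_features <- function() {
  feature_set(tibble::tibble(
    name = c("pelvic pain", "denies pelvic pain", "ear tubes"),
    pattern = c("pelvic pain", "(denies|no).{0,35}pelvic pain", "(E|e)ar tubes?"),
    case_sensitive = c(FALSE, FALSE, TRUE)
  ))
}

# ICU-based count of non-overlapping matches (independent of gregexpr/PCRE)
oracle_count <- function(sentence, pattern, case_sensitive = TRUE) {
  stringr::str_count(sentence, stringr::regex(pattern, ignore_case = !case_sensitive))
}

# naive triple loop: patients x sentences x features, with an explicit mean
oracle_patient_vectors <- function(corpus, features) {
  pats <- corpus_patients(corpus)
  out <- matrix(0, nrow(pats), nrow(features),
                dimnames = list(pats$patient_id, features$name))
  for (p in pats$patient_id) {
    notes <- corpus$text[corpus$patient_id == p]
    note_vecs <- matrix(0, length(notes), nrow(features))
    for (i in seq_along(notes)) {
      for (s in segment_sentences(notes[i])) {
        for (j in seq_len(nrow(features))) {
          note_vecs[i, j] <- note_vecs[i, j] +
            oracle_count(s, features$pattern[j], features$case_sensitive[j])
        }
      }
    }
    out[p, ] <- colSums(note_vecs) / length(notes)
  }
  out
}

# random corpus with phrases planted from a pool both regex dialects parse
random_oracle_corpus <- function(n_patients, max_notes = 5, n_features = NULL) {
  pool_features <- tibble::tibble(
    name = c("pelvic pain", "denies pelvic pain", "ear tubes", "situs",
             "diabetes", "insulin", "bleeding", "fibroids"),
    pattern = c("pelvic pain", "(denies|no).{0,35}pelvic pain",
                "(E|e)ar tubes?", "(s|S)itus (inversus|ambiguous)",
                "(D|d)iabetes", "insulin", "bleeding", "fibroid(s)?"),
    case_sensitive = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  )
  phrases <- c(
    "reports pelvic pain", "denies pelvic pain", "no recent pelvic pain",
    "Ear tubes placed", "ear tube noted", "situs inversus seen",
    "Diabetes in family", "diabetes mellitus", "insulin dependent",
    "heavy bleeding", "multiple fibroids", "large uterine fibroid",
    "routine visit", "vitals stable", "plan reviewed", "return as needed"
  )
  if (is.null(n_features)) n_features <- sample(2:8, 1)
  fs <- feature_set(pool_features[sample.int(nrow(pool_features), n_features), ])
  notes <- purrr::map(seq_len(n_patients), function(p) {
    n_notes <- sample.int(max_notes, 1)
    purrr::map(seq_len(n_notes), function(k) {
      n_sent <- sample.int(5, 1)
      text <- paste(paste0(sample(phrases, n_sent, replace = TRUE), "."),
                    collapse = " ")
      if (stats::runif(1) < 0.1) text <- ""  # empty notes are observations too
      tibble::tibble(
        note_id = sprintf("p%03d-n%02d", p, k),
        patient_id = sprintf("p%03d", p),
        text = text,
        metadata = list(c(label = sample(c("case", "noncase"), 1)))
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  # one label per patient
  labs <- tapply(seq_len(nrow(notes)), notes$patient_id, function(ix) ix[1])
  for (p in unique(notes$patient_id)) {
    lab <- notes$metadata[[labs[[p]]]]
    notes$metadata[notes$patient_id == p] <- list(lab)
  }
  list(corpus = note_corpus(notes), features = fs)
}

# independent metric formulas for cross-checking compute_metrics
oracle_binary_metrics <- function(tp, fn, fp, tn) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- div(tp, tp + fn); ppv <- div(tp, tp + fp)
  list(
    sensitivity = sens,
    specificity = div(tn, tn + fp),
    ppv = ppv,
    npv = div(tn, tn + fn),
    f1 = if (is.na(sens) || is.na(ppv) || sens + ppv == 0) NA_real_
         else 2 * sens * ppv / (sens + ppv)
  )
}

# all-pairs concordance AUROC with half credit for ties
oracle_auroc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
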