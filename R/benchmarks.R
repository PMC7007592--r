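#' Benchmark scenarios for end-to-end evaluation
#'
#' Three canonical study designs, each a generated corpus with a matched
#' feature set and a stated difficulty, mirroring the settings phenotyping
#' studies actually face:
#'
#' * `balanced` — two classes of 25 patients, planted-phrase emission 0.3 per
#'   sentence for cases vs 0.01 for noncases on both features; cleanly
#'   separable, so a competent pipeline should reach out-of-fold accuracy
#'   well above 0.95.
#' * `imbalanced` — 20 cases vs 200 controls (about 1:10, the one-vs-rest
#'   shape of registry-based designs) with a weaker signal (0.08 vs 0.01);
#'   specificity near 1 is easy while sensitivity degrades.
#' * `negation` — symptomatic vs asymptomatic classes that *both* mention the
#'   key phrase at the same rate, but the asymptomatic class always in
#'   negated surface form ("denies pelvic pain", "no pelvic pain today").
#'   `features` contains both the keyword and the negation pattern;
#'   `features_naive` is the keyword alone and cannot separate the classes.
#'
#' @param seed Integer seed; each scenario derives its own sub-seed from it.
#' @return Named list of scenarios; each has `corpus`, `ground_truth`,
#'   `features`, `difficulty`, and for `negation` also `features_naive`.
#' @export
make_benchmark_suite <- function(seed = 1L) {
  seed <- as.integer(seed)

  core_features <- feature_set(tibble::tibble(
    name = c("pelvic pain", "ear tubes"),
    pattern = c("pelvic pain", "(E|e)ar tubes?"),
    case_sensitive = c(FALSE, TRUE)
  ))
  core_bank <- tibble::tibble(
    feature = c(rep("pelvic pain", 3), rep("ear tubes", 3),
                rep("pelvic pain", 2), rep("ear tubes", 1)),
    phrase = c(
      "reports worsening pelvic pain", "chronic pelvic pain noted",
      "pelvic pain with menses",
      "Ear tubes placed last year", "bilateral ear tubes in place",
      "ear tube noted on exam",
      "pelvis unremarkable on imaging", "lower abdominal fullness",
      "ears clear bilaterally"
    ),
    type = c(rep("match", 6), rep("decoy", 3))
  )

  balanced <- generate_corpus(generator_config(
    classes = tibble::tibble(
      class = c("case", "noncase"), n_patients = c(25L, 25L),
      `pelvic pain` = c(0.3, 0.01), `ear tubes` = c(0.3, 0.01)
    ),
    features = core_features, phrase_bank = core_bank,
    notes_per_patient = c(3L, 5L), sentences_per_note = c(4L, 8L),
    seed = seed
  ))
  balanced$features <- core_features
  balanced$difficulty <- "separable"

  imbalanced <- generate_corpus(generator_config(
    classes = tibble::tibble(
      class = c("case", "control"), n_patients = c(20L, 200L),
      `pelvic pain` = c(0.08, 0.01), `ear tubes` = c(0.08, 0.01)
    ),
    features = core_features, phrase_bank = core_bank,
    notes_per_patient = c(2L, 4L), sentences_per_note = c(3L, 6L),
    seed = seed + 1L
  ))
  imbalanced$features <- core_features
  imbalanced$difficulty <- "imbalanced, weak signal"

  negation_features <- feature_set(tibble::tibble(
    name = c("pelvic pain", "denies pelvic pain"),
    pattern = c("pelvic pain", "(denies|no).{0,35}pelvic pain"),
    case_sensitive = c(FALSE, FALSE)
  ))
  negation_bank <- tibble::tibble(
    feature = rep("pelvic pain", 6),
    phrase = c(
      "reports worsening pelvic pain", "chronic pelvic pain noted",
      "pelvic pain with menses",
      "denies pelvic pain", "no pelvic pain today",
      "denies any recent pelvic pain"
    ),
    type = c(rep("match", 3), rep("negated", 3))
  )
  negation <- generate_corpus(generator_config(
    classes = tibble::tibble(
      class = c("asymptomatic", "symptomatic"), n_patients = c(25L, 25L),
      `pelvic pain` = c(0.3, 0.3),
      negation_rate = c(1, 0)
    ),
    features = negation_features, phrase_bank = negation_bank,
    notes_per_patient = c(3L, 5L), sentences_per_note = c(4L, 8L),
    seed = seed + 2L
  ))
  negation$features <- negation_features
  negation$features_naive <- feature_set(negation_features[1, , drop = FALSE])
  negation$difficulty <- "negation-dominated"

  list(balanced = balanced, imbalanced = imbalanced, negation = negation)
}
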