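small_config <- function(seed = 42, p_case = 0.3, p_noncase = 0.01,
                         n_per_class = 10L) {
  fs <- feature_set(tibble::tibble(
    name = c("pelvic pain", "ear tubes"),
    pattern = c("pelvic pain", "(E|e)ar tubes?"),
    case_sensitive = c(FALSE, TRUE)
  ))
  bank <- tibble::tibble(
    feature = c("pelvic pain", "pelvic pain", "ear tubes", "ear tubes",
                "pelvic pain"),
    phrase = c("reports pelvic pain", "chronic pelvic pain noted",
               "Ear tubes placed", "ear tube in place",
               "pelvis unremarkable"),
    type = c("match", "match", "match", "match", "decoy")
  )
  generator_config(
    classes = tibble::tibble(
      class = c("case", "noncase"), n_patients = c(n_per_class, n_per_class),
      `pelvic pain` = c(p_case, p_noncase), `ear tubes` = c(p_case, p_noncase)
    ),
    features = fs, phrase_bank = bank,
    notes_per_patient = c(2L, 3L), sentences_per_note = c(3L, 5L), seed = seed
  )
}

test_that("generated ground truth equals the feature engine's counts exactly", {
  gen <- generate_corpus(small_config(seed = 42))
  nv <- vectorize_notes(gen$corpus, gen$config$features)
  gt <- tidyr::pivot_wider(gen$ground_truth, names_from = "feature",
                           values_from = "planted_count")
  joined <- dplyr::inner_join(nv, gt, by = c("note_id", "patient_id"),
                              suffix = c("_engine", "_planted"))
  expect_equal(nrow(joined), nrow(nv))
  for (f in gen$config$features$name) {
    expect_equal(joined[[paste0(f, "_engine")]], joined[[paste0(f, "_planted")]],
                 label = f)
  }
})

test_that("generation is byte-identical under a fixed seed and varies across seeds", {
  g1 <- generate_corpus(small_config(seed = 7))
  g2 <- generate_corpus(small_config(seed = 7))
  expect_identical(tibble::as_tibble(g1$corpus), tibble::as_tibble(g2$corpus))
  expect_identical(g1$ground_truth, g2$ground_truth)
  g3 <- generate_corpus(small_config(seed = 8))
  expect_false(identical(g1$corpus$text, g3$corpus$text))
})

test_that("zero emission probability yields all-zero patient vectors", {
  gen <- generate_corpus(small_config(seed = 3, p_case = 0, p_noncase = 0))
  pv <- vectorize_patients(gen$corpus, gen$config$features)
  expect_true(all(pv[["pelvic pain"]] == 0))
  expect_true(all(pv[["ear tubes"]] == 0))
})

test_that("phrase banks and filler are verified against the dialect at build time", {
  fs <- feature_set(tibble::tibble(name = "ear tubes", pattern = "(E|e)ar tubes?"))
  bad_match <- tibble::tibble(feature = "ear tubes", phrase = "hearing intact",
                              type = "match")
  expect_error(
    generator_config(
      classes = tibble::tibble(class = c("a", "b"), n_patients = c(2L, 2L),
                               `ear tubes` = c(0.5, 0)),
      features = fs, phrase_bank = bad_match
    ),
    "does not match its feature"
  )
  bad_decoy <- tibble::tibble(feature = "ear tubes",
                              phrase = c("Ear tubes placed", "ear tubes again"),
                              type = c("match", "decoy"))
  expect_error(
    generator_config(
      classes = tibble::tibble(class = c("a", "b"), n_patients = c(2L, 2L),
                               `ear tubes` = c(0.5, 0)),
      features = fs, phrase_bank = bad_decoy
    ),
    "decoys must match nothing"
  )
  expect_error(
    generator_config(
      classes = tibble::tibble(class = c("a", "b"), n_patients = c(2L, 2L),
                               `ear tubes` = c(0.5, 0)),
      features = fs,
      phrase_bank = tibble::tibble(feature = "ear tubes",
                                   phrase = "Ear tubes placed", type = "match"),
      filler_vocabulary = c("patient", "ear", "tubes")
    ),
    "filler must be neutral"
  )
})

test_that("accuracy responds monotonically to the emission-probability gap", {
  accs <- vapply(c(0.02, 0.1, 0.3), function(p_case) {
    gen <- generate_corpus(small_config(seed = 5, p_case = p_case,
                                        p_noncase = 0.01, n_per_class = 15L))
    pv <- vectorize_patients(gen$corpus, gen$config$features)
    crossval(pv, "random_forest", n_folds = 5, seed = 5)$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], 0.9)
})

test_that("the benchmark suite covers the three canonical study designs", {
  suite <- make_benchmark_suite(seed = 101)
  expect_named(suite, c("balanced", "imbalanced", "negation"))
  bal <- corpus_patients(suite$balanced$corpus)
  expect_equal(as.integer(table(bal$label)), c(25L, 25L))
  imb <- corpus_patients(suite$imbalanced$corpus)
  expect_equal(sort(as.integer(table(imb$label))), c(20L, 200L))
  neg <- suite$negation
  expect_equal(nrow(neg$features), 2)
  expect_equal(nrow(neg$features_naive), 1)
  # asymptomatic patients mention the phrase only in negated surface form
  nv <- vectorize_notes(neg$corpus, neg$features)
  pats <- corpus_patients(neg$corpus)
  asym <- nv$patient_id %in% pats$patient_id[pats$label == "asymptomatic"]
  expect_true(all(nv[["denies pelvic pain"]][asym] <= nv[["pelvic pain"]][asym]))
  sym <- !asym
  expect_true(all(nv[["denies pelvic pain"]][sym] == 0))
})
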