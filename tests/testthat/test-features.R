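test_that("feature sets compile in order and reject invalid patterns by name", {
  fs <- tiny_features()
  expect_s3_class(fs, "feature_set")
  expect_equal(fs$name, c("pelvic pain", "denies pelvic pain", "ear tubes"))
  expect_error(
    feature_set(tibble::tibble(name = "broken", pattern = "([A")),
    "feature 'broken'.*invalid regular expression"
  )
  expect_error(
    feature_set(tibble::tibble(name = c("a", "a"), pattern = c("x", "y"))),
    "duplicate feature name"
  )
})

test_that("printed-idiom clinical patterns compile and match their phrasing", {
  # the published feature idiom: explicit case alternation, bounded gaps,
  # optional groups, long-range co-occurrence windows
  fs <- read_features(system.file("extdata", "example_features_fibroids.json",
                                  package = "phenotext"))
  expect_equal(nrow(fs), 3)
  expect_equal(count_matches("Patient denies any pelvic pain today",
                             fs$pattern[2]), 1L)
  expect_equal(count_matches("Multiple uterine fibroids seen",
                             fs$pattern[1]), 1L)
  pcd <- read_features(system.file("extdata", "example_features_pcd.json",
                                   package = "phenotext"))
  expect_equal(count_matches("situs inversus noted", pcd$pattern[1]), 1L)
  expect_equal(count_matches("no history of shortness of breath", pcd$pattern[2]), 1L)
})

test_that("case sensitivity is honored per feature", {
  s <- "Diabetes runs in family; diabetes mellitus noted; DIABETES"
  expect_equal(count_matches(s, "(D|d)iabetes"), 2L)  # uppercase 3rd unmatched
  expect_equal(count_matches(s, "(D|d)iabetes", case_sensitive = FALSE), 3L)
})

test_that("feature files round-trip as JSON and load from clinician CSV", {
  fs <- tiny_features()
  path <- withr::local_tempfile(fileext = ".json")
  write_features(fs, path)
  expect_equal(as.data.frame(read_features(path)), as.data.frame(fs))

  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(name = "bleeding", pattern = "bleeding"), csv)
  got <- read_features(csv)
  expect_true(got$case_sensitive)  # CSV defaults to case-sensitive
  expect_equal(got$name, "bleeding")
})

test_that("sentence segmentation splits on terminators and hard newlines", {
  expect_equal(segment_sentences("Patient denies pelvic pain. BMI is 42."),
               c("Patient denies pelvic pain.", "BMI is 42."))
  expect_equal(segment_sentences("No SOB.\nEar tubes placed in 2015."),
               c("No SOB.", "Ear tubes placed in 2015."))
  expect_equal(segment_sentences(""), character())
  expect_equal(segment_sentences("   \n \n"), character())
})

test_that("abbreviations do not split and unpunctuated text is one sentence", {
  expect_equal(
    segment_sentences("Seen by Dr. Smith today. Stable."),
    c("Seen by Dr. Smith today.", "Stable.")
  )
  expect_equal(segment_sentences("Pt. doing well"), "Pt. doing well")
  # long unpunctuated runs stay whole so long-range window patterns can match
  long_run <- paste(rep("word", 200), collapse = " ")
  expect_length(segment_sentences(long_run), 1)
})

test_that("segmentation preserves all non-whitespace content", {
  texts <- c(
    "One. Two? Three! Four",
    "Line one\nline two. And three.",
    "Dr. A saw pt. B vs. C... odd spacing.  Next."
  )
  for (tx in texts) {
    sents <- segment_sentences(tx)
    expect_identical(gsub("\\s", "", paste(sents, collapse = "")),
                     gsub("\\s", "", tx))
  }
})

test_that("match counting is non-overlapping and agrees with an independent engine", {
  cases <- list(
    list(s = "Patient denies any pelvic pain today",
         p = "(denies|no).{0,35}pelvic pain", n = 1L),
    # greedy gap: one match swallows through the later phrase occurrence
    list(s = "no pain. no pelvic pain. denies pelvic pain",
         p = "(denies|no).{0,35}pelvic pain", n = 1L),
    list(s = "denies pelvic pain today; denies pelvic pain nightly and much later denies pelvic pain",
         p = "(denies|no).{0,10}pelvic pain", n = 3L),
    list(s = "aaaa", p = "aa", n = 2L),  # non-overlapping leftmost scan
    list(s = "", p = "anything", n = 0L)
  )
  for (cs in cases) {
    expect_equal(count_matches(cs$s, cs$p), cs$n, label = cs$s)
    expect_equal(oracle_count(cs$s, cs$p), cs$n, label = paste("oracle:", cs$s))
  }
})

test_that("match spans are half-open 0-based offsets consistent with counts", {
  sp <- match_spans("Ear tubes placed", "(E|e)ar tubes?")
  expect_equal(sp, tibble::tibble(start = 0L, end = 9L))
  expect_equal(nrow(match_spans("", "x")), 0)

  withr::local_seed(11)
  sentences <- c("no pelvic pain and more pelvic pain", "aaaa aa", "Ear tubes; ear tube")
  patterns <- c("pelvic pain", "aa", "(E|e)ar tubes?")
  for (i in seq_along(sentences)) {
    sp <- match_spans(sentences[i], patterns[i])
    expect_equal(nrow(sp), count_matches(sentences[i], patterns[i]))
    expect_true(all(diff(sp$start) > 0))
    expect_true(all(sp$end > sp$start))
    expect_true(all(utils::head(sp$end, -1) <= utils::tail(sp$start, -1)))
    # spans excise the exact matched substrings
    for (j in seq_len(nrow(sp))) {
      frag <- substr(sentences[i], sp$start[j] + 1, sp$end[j])
      expect_equal(count_matches(frag, patterns[i]), 1L)
    }
  }
})
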