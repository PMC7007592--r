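#' Define a set of regular-expression features
#'
#' A feature is a named Perl-compatible regular expression authored by a
#' clinical expert; its per-sentence match count becomes one coordinate of the
#' patient feature vector. Feature order is fixed: it defines the coordinate
#' order of every vector downstream. Every pattern is compiled at construction
#' time; a pattern the engine cannot compile (as happens with typographic
#' corruption when expressions are transcribed from print) is rejected with
#' the compiler's diagnostic rather than silently accepted.
#'
#' Matching defaults to case-sensitive because clinical feature authors encode
#' case deliberately (e.g. `(D|d)iabetes`, `(s|S)itus`); set
#' `case_sensitive = FALSE` per feature to override.
#'
#' @param features A data frame with columns `name` and `pattern`, optionally
#'   `case_sensitive` (default `TRUE`).
#' @return A `feature_set` tibble with columns `name`, `pattern`,
#'   `case_sensitive`, in the given order.
#' @examples
#' feature_set(tibble::tibble(
#'   name = c("pelvic pain", "denies pelvic pain"),
#'   pattern = c("pelvic pain", "(denies|no).{0,35}pelvic pain")
#' ))
#' @export
feature_set <- function(features) {
  stopifnot(is.data.frame(features))
  if (!all(c("name", "pattern") %in% names(features))) {
    stop("feature definitions need 'name' and 'pattern' columns", call. = FALSE)
  }
  fs <- tibble::tibble(
    name = as.character(features$name),
    pattern = as.character(features$pattern),
    case_sensitive = if ("case_sensitive" %in% names(features)) {
      as.logical(features$case_sensitive)
    } else TRUE
  )
  fs$case_sensitive[is.na(fs$case_sensitive)] <- TRUE
  if (nrow(fs) == 0) stop("a feature set must contain at least one feature", call. = FALSE)
  if (any(is.na(fs$name) | fs$name == "")) {
    stop("every feature needs a nonempty name", call. = FALSE)
  }
  if (anyDuplicated(fs$name)) {
    stop("duplicate feature name(s): ",
         paste(unique(fs$name[duplicated(fs$name)]), collapse = ", "), call. = FALSE)
  }
  purrr::pwalk(fs, function(name, pattern, case_sensitive) {
    err <- regex_compile_error(pattern)
    if (!is.null(err)) {
      stop("feature '", name, "': invalid regular expression: ", err, call. = FALSE)
    }
  })
  structure(fs, class = c("feature_set", class(tibble::tibble())))
}

# NULL if the pattern compiles under PCRE, else the compiler's message.
regex_compile_error <- function(pattern) {
  res <- tryCatch(
    { regexpr(pattern, "", perl = TRUE); NULL },
    warning = function(w) conditionMessage(w),
    error = function(e) conditionMessage(e)
  )
  res
}

#' Read feature definitions from JSON or CSV
#'
#' JSON files hold an array of `{name, pattern, case_sensitive}` objects;
#' two-column CSV (`name,pattern`) is accepted for clinician-authored lists
#' and defaults to case-sensitive matching.
#'
#' @param path Path to a `.json` or `.csv` feature file.
#' @return A validated [feature_set()] preserving file order.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("feature file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    recs <- tryCatch(
      jsonlite::fromJSON(path, simplifyVector = FALSE),
      error = function(e) stop("malformed feature JSON in '", path, "': ",
                               conditionMessage(e), call. = FALSE)
    )
    purrr::map(recs, function(r) {
      tibble::tibble(
        name = as.character(r$name %||% NA_character_),
        pattern = as.character(r$pattern %||% NA_character_),
        case_sensitive = isTRUE(r$case_sensitive %||% TRUE)
      )
    }) |> purrr::list_rbind()
  }
  feature_set(raw)
}

#' Write feature definitions to JSON
#' @param features A `feature_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "feature_set"))
  json <- jsonlite::toJSON(purrr::pmap(features, function(name, pattern, case_sensitive) {
    list(name = name, pattern = pattern, case_sensitive = case_sensitive)
  }), auto_unbox = TRUE, pretty = TRUE)
  write_atomically(json, path)
  invisible(path)
}

#' Abbreviations protected from sentence splitting
#'
#' Trailing tokens (lowercased) after which a period does not end a sentence.
#' Covers titles and the chart shorthand common in clinical notes.
#' @export
clinical_abbreviations <- c(
  "dr.", "mr.", "mrs.", "ms.", "prof.", "st.",
  "pt.", "vs.", "e.g.", "i.e.", "etc.", "approx.",
  "dx.", "hx.", "tx.", "rx."
)

#' Split note text into sentences
#'
#' Deterministic rule-based segmentation: hard newlines always end a sentence;
#' within a line, a run of `.?!` followed by whitespace ends a sentence unless
#' the token it terminates is a protected abbreviation. Text with no sentence
#' punctuation is returned as a single sentence, so long-range patterns
#' (some span hundreds of characters) remain usable on unpunctuated note
#' sections. Matching never crosses a sentence boundary downstream.
#'
#' @param text A single character string (empty allowed).
#' @param abbreviations Lowercased tokens (with trailing period) that suppress
#'   a split.
#' @return Character vector of sentences; all non-whitespace content of `text`
#'   is preserved, in order.
#' @examples
#' segment_sentences("Patient denies pelvic pain. BMI is 42.")
#' segment_sentences("No SOB.\nEar tubes placed in 2015.")
#' @export
segment_sentences <- function(text, abbreviations = clinical_abbreviations) {
  stopifnot(length(text) == 1)
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  text <- gsub("\r\n?", "\n", text)
  lines <- strsplit(text, "\n+", fixed = FALSE)[[1]]
  out <- unlist(lapply(lines, split_line_sentences, abbreviations = abbreviations),
                use.names = FALSE)
  out <- trimws(out)
  out[nzchar(out)]
}

split_line_sentences <- function(line, abbreviations) {
  if (!nzchar(trimws(line))) return(character())
  cand <- gregexpr("[.?!]+(?=\\s)", line, perl = TRUE)[[1]]
  if (cand[1] == -1) return(line)
  ends <- cand + attr(cand, "match.length") - 1L
  keep <- vapply(seq_along(ends), function(i) {
    prefix <- substr(line, 1, ends[i])
    token <- regmatches(prefix, regexpr("\\S+$", prefix))
    !(tolower(token) %in% abbreviations)
  }, logical(1))
  ends <- ends[keep]
  if (length(ends) == 0) return(line)
  starts <- c(1L, ends + 1L)
  stops <- c(ends, nchar(line))
  substring(line, starts, stops)
}

#' Count regular-expression matches
#'
#' Counts non-overlapping matches by a left-to-right scan (after each match
#' the scan resumes at the match end), the counting rule used throughout the
#' vectorization engine.
#'
#' @param x Character vector of sentences (or any strings).
#' @param pattern Perl-compatible regular expression.
#' @param case_sensitive Match case-sensitively (default `TRUE`).
#' @return Integer vector of match counts, one per element of `x`.
#' @examples
#' count_matches("Patient denies any pelvic pain today",
#'               "(denies|no).{0,35}pelvic pain")
#' @export
count_matches <- function(x, pattern, case_sensitive = TRUE) {
  if (length(x) == 0) return(integer())
  m <- gregexpr(pattern, x, perl = TRUE, ignore.case = !case_sensitive)
  vapply(m, function(mi) if (mi[1] == -1L) 0L else length(mi), integer(1))
}

#' Locate regular-expression matches
#'
#' Returns the character offsets of the same non-overlapping matches counted
#' by [count_matches()], as half-open 0-based `[start, end)` intervals — the
#' audit-trail analogue of highlighting matches in a note browser.
#'
#' @inheritParams count_matches
#' @param x A single string.
#' @return A tibble with integer columns `start` and `end`, sorted,
#'   non-overlapping; zero rows when nothing matches.
#' @examples
#' match_spans("Ear tubes placed", "(E|e)ar tubes?")
#' @export
match_spans <- function(x, pattern, case_sensitive = TRUE) {
  stopifnot(length(x) == 1)
  m <- gregexpr(pattern, x, perl = TRUE, ignore.case = !case_sensitive)[[1]]
  if (m[1] == -1L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  tibble::tibble(
    start = as.integer(m) - 1L,
    end = as.integer(m) - 1L + attr(m, "match.length")
  )
}
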