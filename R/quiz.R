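#' Load a terminology quiz bank
#'
#' Reads a term bank — a JSON array of `{"term": ..., "definition": ...}`
#' objects, optionally wrapped in a `{"version": ..., "entries": [...]}`
#' envelope — from a local file or an http(s) URL, so an instructor can point
#' a class at their own bank. A bank with fewer than four entries loads but
#' is flagged as too small to quiz from (four answer options are needed).
#'
#' @param source Path to a JSON file or an http(s) URL.
#' @return A tibble of class `term_bank` with columns `term` and `definition`
#'   and attributes `source`, `version` (may be `NA`) and `quizzable`.
#' @examples
#' bank <- load_term_bank(system.file("extdata", "starter_terms.json",
#'                                    package = "genevolve"))
#' nrow(bank)
#' @export
load_term_bank <- function(source) {
  raw <- tryCatch(jsonlite::fromJSON(source, simplifyVector = TRUE),
                  error = function(e) {
                    abort(sprintf("Could not parse term bank '%s': %s", source,
                                  conditionMessage(e)))
                  })
  version <- NA_character_
  if (is.list(raw) && !is.data.frame(raw) && !is.null(raw$entries)) {
    version <- as.character(raw$version %||% NA_character_)
    raw <- raw$entries
  }
  if (!is.data.frame(raw) || !all(c("term", "definition") %in% names(raw))) {
    abort(sprintf("Term bank '%s' must be a JSON array of {term, definition} objects.", source))
  }
  entries <- tibble(term = as.character(raw$term),
                    definition = as.character(raw$definition))
  if (any(is.na(entries$term)) || any(!nzchar(entries$term))) {
    abort("Every entry needs a non-empty term.")
  }
  dup <- unique(entries$term[duplicated(entries$term)])
  if (length(dup) > 0) {
    abort(sprintf("Duplicate term(s) in bank: %s.", paste(dup, collapse = ", ")))
  }
  quizzable <- nrow(entries) >= 4L
  if (!quizzable) {
    warn(sprintf("Bank has only %d entries; at least 4 are needed to quiz (quizzing disabled).",
                 nrow(entries)))
  }
  structure(entries, class = c("term_bank", class(entries)),
            source = source, version = version, quizzable = quizzable)
}

#' Write a term bank to JSON
#'
#' Inverse of [load_term_bank()]: writes the envelope form
#' `{"version": ..., "entries": [...]}` so a write-then-load round trip
#' reproduces the entries exactly.
#'
#' @param bank A `term_bank` or a data frame with columns `term`,
#'   `definition`.
#' @param path Output path.
#' @param version Optional version tag.
#' @return `path`, invisibly.
#' @export
write_term_bank <- function(bank, path, version = NULL) {
  if (!all(c("term", "definition") %in% names(bank))) {
    abort("`bank` needs columns `term` and `definition`.")
  }
  obj <- list(entries = data.frame(term = bank$term, definition = bank$definition))
  if (!is.null(version)) obj <- c(list(version = version), obj)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

check_quizzable <- function(bank) {
  if (!is.data.frame(bank) || !all(c("term", "definition") %in% names(bank))) {
    abort("`bank` must be a term bank (columns `term`, `definition`).")
  }
  if (nrow(bank) < 4L) {
    abort("The bank needs at least 4 entries to build four-option questions.")
  }
  invisible(bank)
}

make_one_question <- function(bank) {
  i <- sample.int(nrow(bank), 1L)
  distractors <- sample(bank$term[-i], 3L)
  opts <- sample(c(bank$term[i], distractors))
  list(definition = bank$definition[i], options = opts,
       answer = bank$term[i], correct_index = match(bank$term[i], opts))
}

#' Draw one four-option definition question
#'
#' Picks a bank entry uniformly at random, samples three distractor terms
#' without replacement from the remaining terms, and shuffles the four
#' options.
#'
#' @param bank A [load_term_bank()] bank (or data frame) with >= 4 entries.
#' @param seed Optional seed for a reproducible question.
#' @return A list of class `quiz_question`: `definition`, `options` (4
#'   distinct terms), `answer`, `correct_index`.
#' @export
make_question <- function(bank, seed = NULL) {
  check_quizzable(bank)
  q <- with_seed(seed, make_one_question(bank))
  structure(q, class = "quiz_question")
}

#' @export
print.quiz_question <- function(x, ...) {
  cat("Which term fits this definition?\n")
  cat(sprintf("  \"%s\"\n", x$definition))
  for (i in seq_along(x$options)) cat(sprintf("  %d) %s\n", i, x$options[i]))
  invisible(x)
}

#' Generate a reproducible quiz
#'
#' @inheritParams make_question
#' @param n Number of questions.
#' @param seed Optional seed; the same seed yields the identical question
#'   sequence.
#' @return A tibble of class `quiz` with one row per question: `question`,
#'   `definition`, `options` (list-column of 4 terms), `answer`,
#'   `correct_index`.
#' @examples
#' bank <- load_term_bank(system.file("extdata", "starter_terms.json",
#'                                    package = "genevolve"))
#' quiz_questions(bank, n = 3, seed = 7)
#' @export
quiz_questions <- function(bank, n = 10, seed = NULL) {
  check_quizzable(bank)
  if (!is_count(n)) abort("`n` must be a positive integer.")
  qs <- with_seed(seed, lapply(seq_len(n), function(i) make_one_question(bank)))
  out <- tibble(
    question = seq_len(n),
    definition = vapply(qs, `[[`, character(1), "definition"),
    options = lapply(qs, `[[`, "options"),
    answer = vapply(qs, `[[`, character(1), "answer"),
    correct_index = vapply(qs, `[[`, integer(1), "correct_index")
  )
  class(out) <- c("quiz", class(out))
  out
}

#' Grade an answered quiz
#'
#' @param quiz A [quiz_questions()] tibble.
#' @param answers Integer vector of chosen option indices (1-4), one per
#'   question; `NA` marks an unanswered question (counted wrong).
#' @return A list of class `quiz_grade`: `n`, `n_correct`, `score`
#'   (proportion; `NaN` for an empty quiz), and `per_term` (tibble of
#'   accuracy by correct term).
#' @examples
#' bank <- load_term_bank(system.file("extdata", "starter_terms.json",
#'                                    package = "genevolve"))
#' qz <- quiz_questions(bank, n = 4, seed = 7)
#' grade_quiz(qz, qz$correct_index)  # a perfect score
#' @export
grade_quiz <- function(quiz, answers) {
  if (!inherits(quiz, "quiz")) abort("`quiz` must come from quiz_questions().")
  if (length(answers) != nrow(quiz)) {
    abort("Provide one answer (or NA) per question.")
  }
  if (any(!is.na(answers) & (answers < 1 | answers > 4))) {
    abort("Answers must index one of the four options (1-4).")
  }
  correct <- !is.na(answers) & answers == quiz$correct_index
  per_term <- tibble(term = quiz$answer, correct = correct) |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(n = dplyr::n(), n_correct = sum(.data$correct),
                     accuracy = mean(.data$correct), .groups = "drop")
  structure(list(
    n = nrow(quiz),
    n_correct = sum(correct),
    score = if (nrow(quiz) == 0) NaN else mean(correct),
    per_term = per_term
  ), class = "quiz_grade")
}

#' @export
print.quiz_grade <- function(x, ...) {
  if (x$n == 0) {
    cat("Empty quiz: nothing to grade.\n")
  } else {
    cat(sprintf("Score: %d/%d (%.0f%%)\n", x$n_correct, x$n, 100 * x$score))
  }
  invisible(x)
}

#' @export
tidy.quiz_grade <- function(x, ...) x$per_term

#' @export
glance.quiz_grade <- function(x, ...) {
  tibble(n = x$n, n_correct = x$n_correct, score = x$score)
}
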