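#' Response codes used in wide-format response tables
#'
#' Item-level responses on a timed multiple-choice task are trichotomous:
#' correct, incorrect, or timed out (no response before the deadline).
#' In files and in [response tables][read_response_table] these are coded
#' `"1"`, `"0"` and `"T"` respectively.
#'
#' @format Named character vector with elements `correct`, `incorrect`,
#'   `timeout`.
#' @export
response_codes <- c(correct = "1", incorrect = "0", timeout = "T")

meta_cols <- c("subject_id", "group", "cohort")

#' Item columns of a response table
#'
#' @param tbl A response table (see [read_response_table()]).
#' @return Character vector of item column names, in table order.
#' @export
item_columns <- function(tbl) {
  setdiff(names(tbl), c(meta_cols, ".planted"))
}

validate_response_table <- function(tbl, call = rlang::caller_env()) {
  missing <- setdiff(meta_cols, names(tbl))
  if (length(missing) > 0) {
    abort(
      sprintf("Response table is missing required column(s): %s.",
              paste(missing, collapse = ", ")),
      class = "eyestrat_format_error", call = call
    )
  }
  items <- item_columns(tbl)
  if (length(items) == 0) {
    abort("Response table has no item columns.",
          class = "eyestrat_format_error", call = call)
  }
  dup <- tbl$subject_id[duplicated(tbl$subject_id)]
  if (length(dup) > 0) {
    abort(
      sprintf("Duplicate subject_id value(s): %s.",
              paste(unique(dup), collapse = ", ")),
      class = "eyestrat_validation_error", call = call
    )
  }
  for (col in items) {
    vals <- as.character(tbl[[col]])
    bad <- which(!vals %in% response_codes | is.na(vals))
    if (length(bad) > 0) {
      abort(
        sprintf(
          "Unknown response code %s at row %d, column '%s' (allowed: %s).",
          if (is.na(vals[bad[1]])) "NA" else sprintf("'%s'", vals[bad[1]]),
          bad[1], col, paste(response_codes, collapse = ", ")
        ),
        class = "eyestrat_validation_error", call = call
      )
    }
  }
  invisible(tbl)
}

#' Read a wide-format response table
#'
#' Reads a delimited text file with one row per subject: columns
#' `subject_id`, `group`, `cohort`, then one column per item holding the
#' codes in [response_codes]. All subjects must have a code for every item;
#' subject IDs must be unique. Row and column order are preserved.
#'
#' @param path Path to the delimited file.
#' @param delim Field delimiter (default `","`).
#' @return A tibble with character meta columns and character item columns.
#' @seealso [write_response_table()], [filter_timeouts()],
#'   [binarize_responses()]
#' @export
read_response_table <- function(path, delim = ",") {
  if (!file.exists(path)) {
    abort(sprintf("Response file not found: '%s'.", path),
          class = "eyestrat_io_error")
  }
  tbl <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  tbl <- tibble::as_tibble(tbl)
  validate_response_table(tbl)
  tbl
}

#' Write a wide-format response table
#'
#' Inverse of [read_response_table()]: writing then reading reproduces the
#' table exactly. The planted-label bookkeeping column `.planted` (added by
#' [simulate_cohort()]) is dropped on write.
#'
#' @param tbl A validated response table.
#' @inheritParams read_response_table
#' @return `path`, invisibly.
#' @export
write_response_table <- function(tbl, path, delim = ",") {
  validate_response_table(tbl)
  out <- tbl[, c(meta_cols, item_columns(tbl))]
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), as.character))
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Exclude subjects with excessive timeouts
#'
#' Subjects who timed out on `max_timeouts` or more items are removed before
#' any analysis, guarding against response patterns dominated by
#' non-response. The default of 9 on a 36-item task removes subjects who
#' failed to respond to a quarter or more of the items; the rule is
#' "count >= threshold excludes".
#'
#' @param tbl A response table.
#' @param max_timeouts Exclusion threshold (a count, not a proportion);
#'   subjects with this many timeouts or more are dropped. Must be >= 1.
#' @return The filtered table, with the dropped IDs available via
#'   [excluded_subjects()] (attribute `excluded_subjects`).
#' @examples
#' tbl <- simulate_cohort(profile_bank("asc_like", seed = 1), n = 20,
#'                        timeout_rate = 0.2, seed = 2)
#' kept <- filter_timeouts(tbl)
#' excluded_subjects(kept)
#' @export
filter_timeouts <- function(tbl, max_timeouts = 9) {
  validate_response_table(tbl)
  if (!is.numeric(max_timeouts) || length(max_timeouts) != 1 ||
      max_timeouts < 1) {
    abort("`max_timeouts` must be a single count >= 1.",
          class = "eyestrat_parameter_error")
  }
  items <- item_columns(tbl)
  n_timeout <- Reduce(`+`, lapply(tbl[items], function(x) {
    as.integer(as.character(x) == response_codes[["timeout"]])
  }))
  drop <- n_timeout >= max_timeouts
  out <- tbl[!drop, , drop = FALSE]
  attr(out, "excluded_subjects") <- tbl$subject_id[drop]
  out
}

#' Subject IDs removed by the timeout filter
#'
#' @param tbl A table returned by [filter_timeouts()].
#' @return Character vector of excluded subject IDs (empty if none).
#' @export
excluded_subjects <- function(tbl) {
  attr(tbl, "excluded_subjects") %||% character(0)
}

#' Binarize a response table
#'
#' Collapses the trichotomous codes to the binary scoring used throughout
#' the analysis: correct responses become 1; incorrect responses and
#' timeouts both become 0 (a timed-out item is scored as wrong). Apply
#' [filter_timeouts()] first so that subjects whose patterns are dominated
#' by timeouts do not enter the binary matrix.
#'
#' @param tbl A response table.
#' @return A tibble with the same meta columns and integer 0/1 item columns.
#' @export
binarize_responses <- function(tbl) {
  validate_response_table(tbl)
  items <- item_columns(tbl)
  keep <- c(meta_cols, items, intersect(".planted", names(tbl)))
  out <- tbl[, keep]
  out <- dplyr::mutate(out, dplyr::across(
    dplyr::all_of(items),
    function(x) as.integer(as.character(x) == response_codes[["correct"]])
  ))
  out
}

is_binary_table <- function(tbl) {
  items <- item_columns(tbl)
  all(meta_cols %in% names(tbl)) && length(items) > 0 &&
    all(vapply(tbl[items], function(x) {
      is.numeric(x) && all(x %in% c(0L, 1L))
    }, logical(1)))
}

assert_binary_table <- function(tbl, call = rlang::caller_env()) {
  if (!is_binary_table(tbl)) {
    abort(
      "Expected a binarized response table (see `binarize_responses()`): meta columns plus 0/1 item columns.",
      class = "eyestrat_validation_error", call = call
    )
  }
  invisible(tbl)
}

#' Extract the subjects-by-items binary matrix
#'
#' @param tbl A binarized response table (see [binarize_responses()]).
#' @return Integer matrix, subjects in rows (rownames = subject IDs),
#'   items in columns.
#' @export
response_matrix <- function(tbl) {
  assert_binary_table(tbl)
  m <- as.matrix(tbl[, item_columns(tbl)])
  storage.mode(m) <- "integer"
  rownames(m) <- tbl$subject_id
  m
}

#' Per-subject total scores
#'
#' The total score is the number of items answered correctly (row sum of
#' the binary matrix); on a 36-item task it ranges from 0 to 36.
#'
#' @param tbl A binarized response table.
#' @return A tibble with `subject_id`, `group`, `cohort`, `total`.
#' @export
total_scores <- function(tbl) {
  assert_binary_table(tbl)
  dplyr::bind_cols(
    tbl[, meta_cols],
    tibble::tibble(total = as.integer(rowSums(tbl[, item_columns(tbl)])))
  )
}
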