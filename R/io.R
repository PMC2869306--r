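# Delimited-text I/O for fight tables, rosters, and subordination signals.
#
# Fight table columns: fight_id, period_id, date, start_s, end_s,
# participants (";"-joined ids), roles (";"-joined "id:role"), contact and
# redirected (";"-joined ids). Extra columns round-trip untouched.

join_ids <- function(x) vapply(x, function(v) paste(v, collapse = ";"), character(1))

split_ids <- function(x) {
  lapply(x, function(v) {
    if (is.na(v) || !nzchar(v)) character(0) else strsplit(v, ";", fixed = TRUE)[[1]]
  })
}

join_roles <- function(x) {
  vapply(x, function(v) {
    if (length(v) == 0L) "" else paste(paste0(names(v), ":", v), collapse = ";")
  }, character(1))
}

split_roles <- function(x) {
  lapply(x, function(v) {
    if (is.na(v) || !nzchar(v)) return(stats::setNames(character(0), character(0)))
    parts <- strsplit(strsplit(v, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    stats::setNames(
      vapply(parts, `[`, character(1), 2L),
      vapply(parts, `[`, character(1), 1L)
    )
  })
}

#' Read a conflict series from a fight table
#'
#' @param path Path to a delimited fight table (CSV) with columns `fight_id`,
#'   `period_id`, `date`, `start_s`, `end_s`, `participants` (ids joined by
#'   `";"`), and optional `roles` (`"id:role"` pairs joined by `";"`),
#'   `contact`, `redirected` (ids joined by `";"`). Unknown columns are kept.
#' @param roster_path Optional path to a roster CSV with columns `id` and
#'   optionally `sex`, `age_class`, `power_score`.
#' @return A validated [conflict_series].
#' @export
read_conflicts <- function(path, roster_path = NULL) {
  if (!file.exists(path)) abort_igt(sprintf("File not found: %s", path))
  raw <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort_igt(sprintf("Failed to parse %s: %s", path, conditionMessage(e)))
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0L) {
    abort_igt(sprintf(
      "Malformed fight table %s at line %d: %s",
      path, probs$row[1] + 1L, probs$expected[1]
    ))
  }
  required <- c("fight_id", "period_id", "start_s", "end_s", "participants")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    abort_igt(paste0("Fight table lacks columns: ", paste(missing, collapse = ", ")))
  }
  raw$participants <- split_ids(as.character(raw$participants))
  if ("roles" %in% names(raw)) raw$roles <- split_roles(as.character(raw$roles))
  if ("contact" %in% names(raw)) raw$contact <- split_ids(as.character(raw$contact))
  if ("redirected" %in% names(raw)) raw$redirected <- split_ids(as.character(raw$redirected))
  if ("cascade_id" %in% names(raw)) raw$cascade_id <- as.integer(raw$cascade_id)
  roster <- if (!is.null(roster_path)) {
    if (!file.exists(roster_path)) abort_igt(sprintf("File not found: %s", roster_path))
    readr::read_csv(roster_path, show_col_types = FALSE, progress = FALSE)
  }
  conflict_series(raw, roster = roster)
}

#' Write a conflict series as a fight table
#'
#' Inverse of [read_conflicts()]: `read_conflicts(write_conflicts(s, f))`
#' reproduces fights, ordering, and annotations exactly, and repeated writes
#' of the same series are byte-identical.
#'
#' @param series A [conflict_series].
#' @param path Output CSV path.
#' @param roster_path Optional path for the roster CSV.
#' @return `path`, invisibly.
#' @export
write_conflicts <- function(series, path, roster_path = NULL) {
  flat <- tibble::as_tibble(series)
  flat$participants <- join_ids(flat$participants)
  flat$roles <- join_roles(flat$roles)
  flat$contact <- join_ids(flat$contact)
  flat$redirected <- join_ids(flat$redirected)
  readr::write_csv(flat, path, progress = FALSE)
  if (!is.null(roster_path)) {
    readr::write_csv(roster_of(series), roster_path, progress = FALSE)
  }
  invisible(path)
}

#' Read a subordination-signal table
#'
#' @param path CSV with columns `sender`, `receiver`, `count`.
#' @return A tibble with those columns.
#' @export
read_signals <- function(path) {
  if (!file.exists(path)) abort_igt(sprintf("File not found: %s", path))
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("sender", "receiver", "count"), names(x))
  if (length(missing) > 0L) {
    abort_igt(paste0("Signal table lacks columns: ", paste(missing, collapse = ", ")))
  }
  x
}
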