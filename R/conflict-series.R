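# Conflict series: one fight per row, grouped into observation periods.
#
# A `conflict_series` is a tibble with one row per fight and the columns
#   fight_id, period_id, date, start_s, end_s  -- scalar metadata
#   participants                               -- list column of id vectors
#   roles, contact, redirected                 -- list columns of annotations
# plus any extra columns (e.g. cascade_id) preserved as opaque annotations.
# The roster (tibble with at least `id`) travels as an attribute.

#' Construct a conflict series
#'
#' Builds and validates the central container of the package: an ordered table
#' of multiparty conflict events ("fights"), grouped into observation periods
#' (days). Fights are ordered by start time within each period; transition
#' pairs never span periods.
#'
#' @param fights A data frame with columns `fight_id`, `period_id`, `start_s`,
#'   `end_s`, and a list column `participants` of character id vectors.
#'   Optional: `date` (one tag per period), list columns `roles` (named
#'   character vectors, values among `"aggressor"`, `"recipient"`,
#'   `"intervener"`, `"other"`), `contact` and `redirected` (character vectors
#'   of participant ids that received that aggression type), and any further
#'   annotation columns.
#' @param roster Optional data frame with column `id` (plus e.g. `sex`,
#'   `age_class`, `power_score`). Defaults to all ids seen in `participants`.
#' @return A `conflict_series` tibble, rows sorted by period then start time.
#' @export
conflict_series <- function(fights, roster = NULL) {
  fights <- tibble::as_tibble(fights)
  required <- c("fight_id", "period_id", "start_s", "end_s", "participants")
  missing <- setdiff(required, names(fights))
  if (length(missing) > 0L) {
    abort_igt(paste0("Missing fight columns: ", paste(missing, collapse = ", ")))
  }
  fights$fight_id <- as.integer(fights$fight_id)
  fights$period_id <- as.integer(fights$period_id)
  if (!"date" %in% names(fights)) {
    fights$date <- sprintf("day%03d", fights$period_id)
  }
  fights$participants <- lapply(fights$participants, as.character)
  for (col in c("roles", "contact", "redirected")) {
    if (!col %in% names(fights)) {
      fights[[col]] <- replicate(nrow(fights), character(0), simplify = FALSE)
    }
  }

  if (is.null(roster)) {
    roster <- tibble::tibble(id = sort(unique(unlist(fights$participants))))
  } else {
    roster <- tibble::as_tibble(roster)
    if (!"id" %in% names(roster)) abort_igt("`roster` needs an `id` column.")
    roster$id <- as.character(roster$id)
  }
  if (anyDuplicated(roster$id)) abort_igt("Roster ids must be unique.")

  ord <- order(fights$period_id, fights$start_s, fights$fight_id)
  fights <- fights[ord, ]
  out <- structure(fights,
    roster = roster,
    class = c("conflict_series", class(tibble::tibble()))
  )
  validate_conflict_series(out)
  out
}

#' @export
print.conflict_series <- function(x, ...) {
  cat(sprintf(
    "<conflict_series> %d fights, %d periods, %d individuals\n",
    nrow(x), length(unique(x$period_id)), nrow(roster_of(x))
  ))
  NextMethod()
}

#' Roster of a conflict series
#' @param series A `conflict_series`.
#' @return The roster tibble (at least an `id` column).
#' @export
roster_of <- function(series) attr(series, "roster")

roster_ids <- function(series) roster_of(series)$id

#' Fight sizes of a conflict series
#' @param series A `conflict_series`.
#' @return Integer vector of participant counts, one per fight.
#' @export
fight_sizes <- function(series) {
  vapply(series$participants, length, integer(1))
}

validate_conflict_series <- function(x) {
  sizes <- fight_sizes(x)
  if (any(sizes < 2L)) {
    bad <- x$fight_id[sizes < 2L]
    abort_igt(sprintf(
      "Fights must have >= 2 participants; offending fight_id: %s",
      paste(bad, collapse = ", ")
    ))
  }
  dup <- vapply(x$participants, anyDuplicated, integer(1)) > 0L
  if (any(dup)) {
    abort_igt(sprintf(
      "Duplicate participant within fight_id: %s",
      paste(x$fight_id[dup], collapse = ", ")
    ))
  }
  if (anyDuplicated(x$fight_id)) abort_igt("`fight_id` must be unique.")
  if (any(x$end_s < x$start_s)) {
    abort_igt(sprintf(
      "end_s < start_s for fight_id: %s",
      paste(x$fight_id[x$end_s < x$start_s], collapse = ", ")
    ))
  }
  ids <- roster_ids(x)
  unknown <- setdiff(unique(unlist(x$participants)), ids)
  if (length(unknown) > 0L) {
    abort_igt(paste0("Participants absent from roster: ", paste(unknown, collapse = ", ")))
  }
  # Annotation keys must be participants; redirected aggression is undefined
  # in fights of size two (there is no third party).
  for (i in seq_len(nrow(x))) {
    p <- x$participants[[i]]
    r <- x$roles[[i]]
    if (length(r) > 0L && !all(names(r) %in% p)) {
      abort_igt(sprintf("Role for non-participant in fight_id %d.", x$fight_id[i]))
    }
    if (!all(x$contact[[i]] %in% p) || !all(x$redirected[[i]] %in% p)) {
      abort_igt(sprintf("Aggression flag for non-participant in fight_id %d.", x$fight_id[i]))
    }
    if (length(p) == 2L && length(x$redirected[[i]]) > 0L) {
      abort_igt(sprintf(
        "Redirected aggression recorded in size-2 fight_id %d.", x$fight_id[i]
      ))
    }
  }
  # Overlapping fights are tolerated but worth a warning: ordering falls back
  # to start time then fight_id.
  by_period <- split(seq_len(nrow(x)), x$period_id)
  for (rows in by_period) {
    if (length(rows) > 1L) {
      starts <- x$start_s[rows]
      ends <- x$end_s[rows]
      if (any(starts[-1L] < ends[-length(ends)])) {
        rlang::warn(
          "Overlapping fights detected; ordered by start time then fight_id.",
          class = "igt_overlap_warning"
        )
        break
      }
    }
  }
  invisible(x)
}

#' Consecutive same-period fight pairs
#'
#' Enumerates the transition pairs the correlation estimators condition on:
#' each fight paired with its `lag`-step successor in the same observation
#' period. Pairs never span periods, so correlations are never estimated
#' across days.
#'
#' @param series A `conflict_series`.
#' @param lag Positive integer step (1 = immediate successor).
#' @return A tibble with columns `period_id`, `prev_id`, `next_id` (fight
#'   ids), and `prev_row`, `next_row` (row indices into `series`).
#' @export
#' @examples
#' s <- toy_series()
#' transition_pairs(s)
transition_pairs <- function(series, lag = 1L) {
  assert_count(lag, "lag", min = 1L)
  n <- nrow(series)
  if (n <= lag) {
    return(tibble::tibble(
      period_id = integer(0), prev_id = integer(0), next_id = integer(0),
      prev_row = integer(0), next_row = integer(0)
    ))
  }
  prev <- seq_len(n - lag)
  nxt <- prev + lag
  keep <- series$period_id[prev] == series$period_id[nxt]
  tibble::tibble(
    period_id = series$period_id[prev[keep]],
    prev_id = series$fight_id[prev[keep]],
    next_id = series$fight_id[nxt[keep]],
    prev_row = prev[keep],
    next_row = nxt[keep]
  )
}

#' A small fixed example series
#'
#' Four fights in one period over four individuals; handy for examples and
#' by-hand enumeration.
#' @return A `conflict_series`.
#' @export
toy_series <- function() {
  conflict_series(tibble::tibble(
    fight_id = 1:4,
    period_id = 1L,
    start_s = c(0, 100, 200, 300),
    end_s = c(10, 110, 210, 310),
    participants = list(c("a", "b"), c("b", "c"), c("a", "c"), c("a", "b"))
  ))
}
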