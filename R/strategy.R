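# (n,k) + combinator strategy matrices.
#
# A strategy matrix assigns to every (source n-tuple, target k-tuple) a
# signed value in [-1, 1]: the probability that the appearance of the source
# tuple in a fight leads to a recommendation that the target tuple join
# (positive sign, attraction) or avoid (negative sign, inhibition) the next
# fight. Absent entries are 0 ("don't care"). Internally the entries live in
# a dense sources x targets matrix keyed by canonical tuple keys.

#' Construct a strategy matrix
#'
#' @param entries Data frame with columns `source`, `target` (tuple keys, ids
#'   joined by `"|"`, or single ids), and `value` in `[-1, 1]`; or `NULL` for
#'   an all-zero matrix.
#' @param n,k Source / target tuple sizes (1 or 2).
#' @param combinator `"AND"` (conflict-averse) or `"OR"` (conflict-prone).
#' @param roster Character vector of individual ids.
#' @return An object of class `strategy_matrix`.
#' @export
strategy_matrix <- function(entries = NULL, n = 1L, k = 1L,
                            combinator = c("AND", "OR"), roster) {
  combinator <- match.arg(combinator)
  if (!n %in% 1:2 || !k %in% 1:2) abort_igt("`n` and `k` must be 1 or 2.")
  roster <- as.character(roster)
  if (anyDuplicated(roster)) abort_igt("Roster ids must be unique.")
  src <- tuple_universe(roster, n)
  tgt <- tuple_universe(roster, k)
  M <- matrix(0, length(src$keys), length(tgt$keys),
    dimnames = list(src$keys, tgt$keys)
  )
  if (!is.null(entries) && nrow(entries) > 0L) {
    skey <- canonical_keys(entries$source, n)
    tkey <- canonical_keys(entries$target, k)
    si <- match(skey, src$keys)
    ti <- match(tkey, tgt$keys)
    if (anyNA(si) || anyNA(ti)) {
      abort_igt("Entry tuple size or ids do not match (n, k, roster).")
    }
    if (any(abs(entries$value) > 1)) abort_igt("Entry magnitudes must be <= 1.")
    M[cbind(si, ti)] <- entries$value
  }
  new_strategy_matrix(M, n, k, combinator, roster, src, tgt)
}

new_strategy_matrix <- function(M, n, k, combinator, roster, src = NULL, tgt = NULL) {
  src <- src %||% tuple_universe(roster, n)
  tgt <- tgt %||% tuple_universe(roster, k)
  structure(
    list(
      n = as.integer(n), k = as.integer(k), combinator = combinator,
      roster = roster, M = M,
      source_members = src$members, target_members = tgt$members
    ),
    class = "strategy_matrix"
  )
}

canonical_keys <- function(x, size) {
  parts <- strsplit(as.character(x), "|", fixed = TRUE)
  bad <- lengths(parts) != size
  if (any(bad)) abort_igt("Entry tuple size does not match the declared n/k.")
  vapply(parts, function(p) paste(sort(p), collapse = "|"), character(1))
}

#' @export
print.strategy_matrix <- function(x, ...) {
  cat(sprintf(
    "<strategy_matrix> (%d,%d)+%s, roster %d, %d/%d nonzero entries\n",
    x$n, x$k, x$combinator, length(x$roster), sum(x$M != 0), length(x$M)
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a strategy matrix into its entry table
#'
#' @param x A `strategy_matrix`.
#' @param all Include zero ("don't care") entries (default: nonzero only).
#' @param ... Unused.
#' @return A tibble with `source`, `target`, `value`.
#' @export
tidy.strategy_matrix <- function(x, all = FALSE, ...) {
  out <- tibble::tibble(
    source = rep(rownames(x$M), times = ncol(x$M)),
    target = rep(colnames(x$M), each = nrow(x$M)),
    value = as.vector(x$M)
  )
  if (!all) out <- out[out$value != 0, ]
  out
}

#' One-line summary of a strategy matrix
#' @param x A `strategy_matrix`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `k`, `combinator`, `roster_size`,
#'   `n_entries`, `n_nonzero`, `density`, `mean_positive`, `mean_negative`.
#' @export
glance.strategy_matrix <- function(x, ...) {
  v <- as.vector(x$M)
  tibble::tibble(
    n = x$n, k = x$k, combinator = x$combinator,
    roster_size = length(x$roster),
    n_entries = length(v), n_nonzero = sum(v != 0),
    density = mean(v != 0),
    mean_positive = if (any(v > 0)) mean(v[v > 0]) else NA_real_,
    mean_negative = if (any(v < 0)) mean(v[v < 0]) else NA_real_
  )
}

#' Build a strategy matrix from measured correlations
#'
#' The model-fitting step: each strategy entry is set equal to the measured
#' lag-1 `delta_p` between the corresponding source and target tuples. This
#' first-guess assignment (reasonable when fights are small and change size
#' slowly, and the maximum-likelihood search over the full transition matrix
#' is hopeless at ~10^3 events) is what turns a correlation table into a
#' generative model. Cells flagged undefined contribute 0; values are clipped
#' to `[-1, 1]` and the number of clipped cells recorded in the
#' `"n_clipped"` attribute.
#'
#' @param results Correlation table from [fight_correlations()] with source
#'   tuples of size `n`, target tuples of size `k`, lag 1.
#' @param n,k Tuple sizes the results were computed at.
#' @param combinator `"AND"` or `"OR"`.
#' @param roster Character vector of ids (defaults to ids seen in `results`).
#' @return A `strategy_matrix`.
#' @export
fit_strategy <- function(results, n = 1L, k = 1L, combinator = c("AND", "OR"),
                         roster = NULL) {
  combinator <- match.arg(combinator)
  if (any(results$lag != 1L)) abort_igt("The strategy ansatz uses lag-1 correlations.")
  src_sizes <- lengths(split_key(results$source))
  tgt_sizes <- lengths(split_key(results$target))
  if (any(src_sizes != n) || any(tgt_sizes != k)) {
    abort_igt("Tuple sizes in `results` do not match (n, k).")
  }
  if (is.null(roster)) {
    roster <- sort(unique(unlist(c(split_key(results$source), split_key(results$target)))))
  }
  val <- ifelse(results$undefined, 0, results$delta_p)
  n_clipped <- sum(abs(val) > 1)
  val <- pmin(pmax(val, -1), 1)
  out <- strategy_matrix(
    tibble::tibble(source = results$source, target = results$target, value = val),
    n = n, k = k, combinator = combinator, roster = roster
  )
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Write / read a strategy matrix as keyed text
#'
#' JSON serialization with sorted tuple keys, so files diff reproducibly:
#' a header (`n`, `k`, `combinator`, `roster`) plus `source | target | value`
#' records for the nonzero entries.
#'
#' @param strategy A `strategy_matrix`.
#' @param path File path.
#' @return `path` invisibly (write); a `strategy_matrix` (read).
#' @export
write_strategy <- function(strategy, path) {
  entries <- tidy(strategy)
  entries <- entries[order(entries$source, entries$target), ]
  payload <- list(
    n = strategy$n, k = strategy$k, combinator = strategy$combinator,
    roster = strategy$roster,
    entries = as.data.frame(entries)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_strategy
#' @export
read_strategy <- function(path) {
  if (!file.exists(path)) abort_igt(sprintf("File not found: %s", path))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- payload$entries
  if (is.null(entries) || length(entries) == 0L) entries <- NULL
  strategy_matrix(
    entries,
    n = payload$n, k = payload$k,
    combinator = payload$combinator, roster = payload$roster
  )
}
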