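# Internal helpers: tuple keys, seed streams, small argument checks.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom rlang abort warn
NULL

abort_igt <- function(msg, class = "igt_error") {
  rlang::abort(msg, class = class)
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort_igt(sprintf("`%s` must be TRUE or FALSE.", name))
  }
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort_igt(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
}

#' Canonical key for a tuple of individual ids
#'
#' Tuples of one or two ids are keyed by sorting members lexicographically and
#' joining with `"|"`, so `{B, A}` and `{A, B}` share the key `"A|B"`.
#'
#' @param members Character vector of 1 or 2 distinct individual ids.
#' @return A single string key.
#' @export
#' @examples
#' tuple_key(c("b", "a"))
tuple_key <- function(members) {
  members <- as.character(members)
  if (length(members) < 1L || length(members) > 2L) {
    abort_igt("A tuple has 1 or 2 members.")
  }
  if (anyDuplicated(members)) abort_igt("Tuple members must be distinct.")
  paste(sort(members), collapse = "|")
}

split_key <- function(key) strsplit(key, "|", fixed = TRUE)

# All size-`size` tuple keys over `ids`, in canonical order, plus the member
# index matrix (tuples x size) into `ids`.
tuple_universe <- function(ids, size) {
  if (size == 1L) {
    list(keys = ids, members = matrix(seq_along(ids), ncol = 1L))
  } else {
    cmb <- utils::combn(seq_along(ids), 2L)
    list(
      keys = paste(ids[cmb[1L, ]], ids[cmb[2L, ]], sep = "|"),
      members = t(cmb)
    )
  }
}

# Row lookup for unordered pairs: pair_row_matrix(n)[i, j] gives the index of
# pair {i, j} in the combn(n, 2) ordering.
pair_row_matrix <- function(n) {
  m <- matrix(NA_integer_, n, n)
  cmb <- utils::combn(n, 2L)
  idx <- seq_len(ncol(cmb))
  m[cbind(cmb[1L, ], cmb[2L, ])] <- idx
  m[cbind(cmb[2L, ], cmb[1L, ])] <- idx
  m
}

# Deterministic child seeds: one top-level seed fans out to independent
# substream seeds without consuming the R RNG. Polynomial string hash mod a
# Mersenne prime, kept below 2^31 - 1 (R seeds are 32-bit integers).
child_seed <- function(seed, ...) {
  tags <- paste(c(seed, ...), collapse = "/")
  h <- 17
  for (b in utf8ToInt(tags)) h <- (h * 131 + b) %% 2147483647
  as.integer(h %% 2147483546) + 1L
}

with_rng <- function(seed, code) {
  withr::with_seed(seed, code)
}

# sample() without the length-1 surprise.
sample_safe <- function(x, ...) {
  if (length(x) <= 1L) return(x)
  sample(x, ...)
}
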