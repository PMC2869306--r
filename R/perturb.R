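# Strategy perturbations: shuffles and coarse-graining.
#
# These probe how specific the fitted strategies are: shuffles destroy the
# association between tuples and values while preserving value multisets
# (globally, per source, or per target); coarse-graining limits how graded a
# response can be by snapping values to a small set of representative levels
# per sign.

#' Total shuffle of a strategy matrix
#'
#' Randomly reassigns the full multiset of entry values (including zeros)
#' across all (source, target) cells. Shape, roster, `n`, `k`, and the
#' combinator are untouched.
#'
#' @param strategy A `strategy_matrix`.
#' @param seed Integer seed (deterministic output given it).
#' @return A perturbed `strategy_matrix`.
#' @export
total_shuffle <- function(strategy, seed = 1L) {
  M <- strategy$M
  with_rng(seed, {
    M[] <- sample(as.vector(strategy$M))
  })
  new_strategy_matrix(M, strategy$n, strategy$k, strategy$combinator, strategy$roster)
}

#' Outgoing shuffle of a strategy matrix
#'
#' For each source tuple independently, reassigns its values over outgoing
#' targets by repeated pairwise swaps: two targets are chosen, their values
#' swapped, and the process repeated until all of the source's values have
#' been reassigned. When possible, swaps pair values of opposite sign, so
#' attraction and inhibition trade places. The per-source value multiset is
#' preserved exactly. Requires `k = 1`.
#'
#' @inheritParams total_shuffle
#' @return A perturbed `strategy_matrix`.
#' @export
outgoing_shuffle <- function(strategy, seed = 1L) {
  if (strategy$k != 1L) abort_igt("Outgoing shuffle is defined for k = 1 strategies.")
  M <- strategy$M
  with_rng(seed, {
    for (s in seq_len(nrow(M))) {
      M[s, ] <- swap_row(M[s, ])
    }
  })
  new_strategy_matrix(M, strategy$n, strategy$k, strategy$combinator, strategy$roster)
}

# Pairwise-swap reassignment of one value vector, preferring opposite-sign
# partners; an odd leftover element keeps its place.
swap_row <- function(v) {
  pos <- sample_safe(which(v > 0))
  neg <- sample_safe(which(v < 0))
  zero <- sample_safe(which(v == 0))
  n_mixed <- min(length(pos), length(neg))
  first <- c(
    if (n_mixed > 0L) pos[seq_len(n_mixed)],
    if (length(pos) > n_mixed) pos[-seq_len(n_mixed)],
    if (length(neg) > n_mixed) neg[-seq_len(n_mixed)]
  )
  second <- c(
    if (n_mixed > 0L) neg[seq_len(n_mixed)],
    zero
  )
  # Pair opposite signs first, then whatever remains, two at a time.
  queue <- c(
    as.vector(rbind(first[seq_len(n_mixed)], second[seq_len(n_mixed)])),
    sample_safe(c(
      if (length(first) > n_mixed) first[-seq_len(n_mixed)],
      if (length(second) > n_mixed) second[-seq_len(n_mixed)]
    ))
  )
  i <- 1L
  while (i + 1L <= length(queue)) {
    a <- queue[i]
    b <- queue[i + 1L]
    tmp <- v[a]
    v[a] <- v[b]
    v[b] <- tmp
    i <- i + 2L
  }
  v
}

#' Incoming shuffle of a strategy matrix
#'
#' For each target individual independently, randomly permutes its incoming
#' values across source tuples: the target keeps the same distribution of
#' values, but they are associated with different source tuples than in the
#' original. Per-target value multisets are preserved. Requires `k = 1`.
#'
#' @inheritParams total_shuffle
#' @return A perturbed `strategy_matrix`.
#' @export
incoming_shuffle <- function(strategy, seed = 1L) {
  if (strategy$k != 1L) abort_igt("Incoming shuffle is defined for k = 1 strategies.")
  M <- strategy$M
  with_rng(seed, {
    for (t in seq_len(ncol(M))) {
      M[, t] <- sample(M[, t])
    }
  })
  new_strategy_matrix(M, strategy$n, strategy$k, strategy$combinator, strategy$roster)
}

#' Coarse-grain a strategy matrix
#'
#' Limits how graded responses can be: entries are snapped to a small set of
#' representative values per sign, modelling decision-makers with a few
#' discrete response levels ("strongly avoid", "avoid", "don't care",
#' "join", "strongly join") rather than a continuum.
#'
#' At `level = 1`, each strictly negative entry becomes the mean of all
#' strictly negative entries and each strictly positive entry the mean of
#' all strictly positive ones. At `level >= 2`, each sign gets `level`
#' representative magnitudes spaced logarithmically between the smallest and
#' largest nonzero magnitude of that sign (a logarithmic perceptual bias),
#' and every entry maps to the nearest representative in log-magnitude
#' distance, ties to the smaller magnitude. Zeros stay zero; signs never
#' flip; the operation is idempotent at a fixed level.
#'
#' @param strategy A `strategy_matrix`.
#' @param level Integer >= 1: number of allowed magnitudes per sign.
#' @return A coarse-grained `strategy_matrix`.
#' @export
coarse_grain <- function(strategy, level = 1L) {
  assert_count(level, "level", min = 1L)
  M <- strategy$M
  for (sgn in c(-1, 1)) {
    sel <- sign(M) == sgn
    if (!any(sel)) next
    mags <- abs(M[sel])
    if (level == 1L) {
      M[sel] <- sgn * mean(mags)
    } else {
      reps <- exp(seq(log(min(mags)), log(max(mags)), length.out = level))
      idx <- vapply(mags, function(m) which.min(abs(log(m) - log(reps))), integer(1))
      M[sel] <- sgn * reps[idx]
    }
  }
  new_strategy_matrix(M, strategy$n, strategy$k, strategy$combinator, strategy$roster)
}
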