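# Cross-fight membership correlations against a Monte Carlo time-shuffle null.
#
# The estimator: for a source tuple S and target tuple T at lag L,
#   p_hat(T | S) = N(fights containing T that sit L steps after a fight
#                    containing S, within one period)
#                / N(fights containing S that have a lag-L successor in the
#                    same period)
# The null reorders fights uniformly at random within each period, leaving
# fight compositions untouched; delta_p = p_hat - mean(null p_hat).

# Membership matrices (fights x tuples, 0/1) for tuples of size 1 or 2.
membership_matrix <- function(series, size) {
  ids <- roster_ids(series)
  n_f <- nrow(series)
  Mi <- matrix(0, n_f, length(ids), dimnames = list(NULL, ids))
  for (i in seq_len(n_f)) {
    Mi[i, match(series$participants[[i]], ids)] <- 1
  }
  if (size == 1L) {
    return(list(keys = ids, M = Mi))
  }
  uni <- tuple_universe(ids, 2L)
  M <- Mi[, uni$members[, 1L], drop = FALSE] * Mi[, uni$members[, 2L], drop = FALSE]
  colnames(M) <- uni$keys
  list(keys = uni$keys, M = M)
}

# p_hat for every (source, target) cell at once. `order` optionally permutes
# the fight sequence (a time-shuffle surrogate).
phat_core <- function(Msrc, Mtgt, prev, nxt, order = NULL) {
  if (!is.null(order)) {
    prev <- order[prev]
    nxt <- order[nxt]
  }
  A <- Msrc[prev, , drop = FALSE]
  den <- colSums(A)
  num <- crossprod(A, Mtgt[nxt, , drop = FALSE])
  p <- num / den
  p[is.nan(p)] <- 0
  list(p = p, den = den)
}

# One uniform reordering of fights within each period. Consumes the RNG.
perm_within_periods <- function(period_ids) {
  idx <- seq_along(period_ids)
  unlist(lapply(split(idx, period_ids), sample_safe), use.names = FALSE)
}

#' Conditional membership probability across fights
#'
#' Estimates \eqn{\hat p(\mathrm{target} \mid \mathrm{source})} at a given
#' lag: the fraction of fights containing every member of `source`, and
#' possessing a `lag`-step successor in the same period, whose successor
#' contains every member of `target`. Restricting the denominator to fights
#' with a valid successor is the estimator's definition (otherwise it would
#' be biased by period-final fights that cannot be followed).
#'
#' @param series A [conflict_series].
#' @param source,target Character vectors of 1 or 2 individual ids. Source
#'   and target may overlap (self-correlation measures persistence).
#' @param lag Positive integer step.
#' @return A one-row tibble with `p_hat` and `n_source` (conditioning
#'   fights). `p_hat` is 0 when `n_source` is 0.
#' @export
p_hat <- function(series, source, target, lag = 1L) {
  assert_count(lag, "lag", min = 1L)
  source <- as.character(source)
  target <- as.character(target)
  tp <- transition_pairs(series, lag = lag)
  num <- 0L
  den <- 0L
  for (i in seq_len(nrow(tp))) {
    if (all(source %in% series$participants[[tp$prev_row[i]]])) {
      den <- den + 1L
      if (all(target %in% series$participants[[tp$next_row[i]]])) num <- num + 1L
    }
  }
  tibble::tibble(p_hat = if (den == 0L) 0 else num / den, n_source = den)
}

#' Time-shuffled surrogate of a conflict series
#'
#' Reorders fights uniformly at random within each observation period,
#' keeping fight compositions (and all within-fight annotations) intact and
#' reassigning the period's original time slots to the new order. This is the
#' null model for all correlation estimates: it preserves everything about
#' the series except the temporal adjacency structure.
#'
#' @param series A [conflict_series].
#' @param seed Integer seed; the surrogate is deterministic given it.
#' @return A `conflict_series` with the same fights in shuffled order.
#' @export
shuffle_series <- function(series, seed = 1L) {
  with_rng(seed, {
    ord <- perm_within_periods(series$period_id)
  })
  out <- series
  keep <- c("period_id", "start_s", "end_s", "date")
  moved <- setdiff(names(series), keep)
  for (col in moved) out[[col]] <- series[[col]][ord]
  # Row order is already by period/slot; revalidate invariants cheaply.
  attr(out, "roster") <- roster_of(series)
  out
}

#' Membership correlations for all tuple pairs
#'
#' Computes `delta_p` for every (source n-tuple, target k-tuple) cell: the
#' observed conditional membership probability minus its expectation under
#' the within-period time-shuffle null, with empirical two-sided 95%
#' significance from the null ensemble. Because `p_hat` is discrete, ties
#' with null values are counted at half weight (mid-p), which keeps the
#' two-sided rate at its nominal level on independent series.
#'
#' @param series A [conflict_series].
#' @param n,k Source / target tuple sizes (1 or 2).
#' @param lag Positive integer step (1 for the one-step estimator).
#' @param n_shuffles Size of the Monte Carlo null ensemble.
#' @param seed Integer seed for the null ensemble.
#' @param alpha Two-sided significance level (default 0.05).
#' @return A tibble with one row per (source, target) cell: `source`,
#'   `target`, `lag`, `p_hat`, `null_mean`, `null_sd`, `delta_p`,
#'   `n_source`, `significant_95`, `undefined`. Cells with no conditioning
#'   fights are flagged `undefined` and report `delta_p = 0`.
#' @export
fight_correlations <- function(series, n = 1L, k = 1L, lag = 1L,
                               n_shuffles = 1000L, seed = 1L, alpha = 0.05) {
  if (!n %in% 1:2 || !k %in% 1:2) abort_igt("`n` and `k` must be 1 or 2.")
  assert_count(lag, "lag", min = 1L)
  assert_count(n_shuffles, "n_shuffles", min = 1L)
  src <- membership_matrix(series, n)
  tgt <- if (k == n) src else membership_matrix(series, k)
  tp <- transition_pairs(series, lag = lag)
  S <- length(src$keys)
  T_ <- length(tgt$keys)

  if (nrow(tp) == 0L) {
    obs <- list(p = matrix(0, S, T_), den = rep(0, S))
  } else {
    obs <- phat_core(src$M, tgt$M, tp$prev_row, tp$next_row)
  }

  sum_p <- matrix(0, S, T_)
  sumsq <- matrix(0, S, T_)
  gt <- matrix(0L, S, T_)
  lt <- matrix(0L, S, T_)
  tol <- 1e-12
  with_rng(seed, {
    for (b in seq_len(n_shuffles)) {
      ord <- perm_within_periods(series$period_id)
      pp <- if (nrow(tp) == 0L) {
        matrix(0, S, T_)
      } else {
        phat_core(src$M, tgt$M, tp$prev_row, tp$next_row, order = ord)$p
      }
      sum_p <- sum_p + pp
      sumsq <- sumsq + pp * pp
      gt <- gt + (pp > obs$p + tol)
      lt <- lt + (pp < obs$p - tol)
    }
  })
  null_mean <- sum_p / n_shuffles
  null_var <- pmax(sumsq / n_shuffles - null_mean^2, 0)
  null_sd <- sqrt(null_var * n_shuffles / max(n_shuffles - 1L, 1L))

  undefined <- obs$den == 0
  # mid-p tie handling: p_hat is heavily discrete (small integer numerators
  # over modest denominators), so counting null ties fully against the
  # observation makes the empirical test markedly conservative; ties at half
  # weight keep the two-sided rate at its nominal level.
  eq <- n_shuffles - gt - lt
  cut <- alpha / 2 * n_shuffles
  sig <- (gt + 0.5 * eq < cut) | (lt + 0.5 * eq < cut)
  sig[undefined, ] <- FALSE
  p_obs <- obs$p
  dp <- p_obs - null_mean
  p_obs[undefined, ] <- 0
  dp[undefined, ] <- 0

  tibble::tibble(
    source = rep(src$keys, times = T_),
    target = rep(tgt$keys, each = S),
    lag = lag,
    p_hat = as.vector(p_obs),
    null_mean = as.vector(null_mean),
    null_sd = as.vector(null_sd),
    delta_p = as.vector(dp),
    n_source = rep(as.integer(obs$den), times = T_),
    significant_95 = as.vector(sig),
    undefined = rep(undefined, times = T_)
  )
}

#' Single-cell membership correlation
#'
#' Convenience wrapper returning one row of [fight_correlations()] for a
#' named source/target tuple pair.
#'
#' @inheritParams p_hat
#' @inheritParams fight_correlations
#' @return A one-row correlation tibble (see [fight_correlations()]).
#' @export
delta_p <- function(series, source, target, lag = 1L,
                    n_shuffles = 1000L, seed = 1L, alpha = 0.05) {
  res <- fight_correlations(
    series,
    n = length(source), k = length(target), lag = lag,
    n_shuffles = n_shuffles, seed = seed, alpha = alpha
  )
  res[res$source == tuple_key(source) & res$target == tuple_key(target), ]
}

# Count of significant positive delta_p cells for one dataset (optionally a
# permuted surrogate of it), with its own inner null of `n_shuffles`.
count_sig_positive <- function(Msrc, Mtgt, period_ids, prev, nxt,
                               n_shuffles, alpha, seed, order = NULL) {
  if (length(prev) == 0L) return(0L)
  obs <- phat_core(Msrc, Mtgt, prev, nxt, order = order)
  S <- ncol(Msrc)
  T_ <- ncol(Mtgt)
  gt <- matrix(0L, S, T_)
  lt <- matrix(0L, S, T_)
  sum_p <- matrix(0, S, T_)
  tol <- 1e-12
  with_rng(seed, {
    for (b in seq_len(n_shuffles)) {
      inner <- perm_within_periods(period_ids)
      ord2 <- if (is.null(order)) inner else order[inner]
      pp <- phat_core(Msrc, Mtgt, prev, nxt, order = ord2)$p
      sum_p <- sum_p + pp
      gt <- gt + (pp > obs$p + tol)
      lt <- lt + (pp < obs$p - tol)
    }
  })
  eq <- n_shuffles - gt - lt
  cut <- alpha / 2 * n_shuffles
  sig <- (gt + 0.5 * eq < cut) | (lt + 0.5 * eq < cut)
  sig[obs$den == 0, ] <- FALSE
  pos <- obs$p - sum_p / n_shuffles > 0
  sum(sig & pos)
}

#' Excess of significant positive correlations
#'
#' Individual `delta_p` detections are not independent (within-fight
#' correlations survive the null), so overall significance is assessed by
#' re-running the full detection pipeline on time-shuffle surrogates: each
#' surrogate is treated as data, with its own inner null ensemble, and the
#' count of significant positive `delta_p` cells is recorded. The p-value is
#' the fraction of surrogates whose count reaches the observed count.
#'
#' @inheritParams fight_correlations
#' @param n_surrogates Number of outer surrogate datasets.
#' @return A list of class `igt_excess` with `observed` (count in the data),
#'   `null_counts` (one per surrogate), and `p_value`.
#' @export
excess_significance <- function(series, n = 1L, k = 1L, lag = 1L,
                                n_shuffles = 200L, n_surrogates = 100L,
                                seed = 1L, alpha = 0.05) {
  assert_count(n_surrogates, "n_surrogates", min = 1L)
  if (n_surrogates < 20L) {
    rlang::warn("Fewer than 20 surrogates: excess-significance quantiles are unstable.")
  }
  src <- membership_matrix(series, n)
  tgt <- if (k == n) src else membership_matrix(series, k)
  tp <- transition_pairs(series, lag = lag)
  if (nrow(tp) == 0L) abort_igt("Series has no transition pairs at this lag.")

  observed <- count_sig_positive(
    src$M, tgt$M, series$period_id, tp$prev_row, tp$next_row,
    n_shuffles, alpha, seed = child_seed(seed, "obs")
  )
  null_counts <- integer(n_surrogates)
  orders <- with_rng(child_seed(seed, "outer"), {
    lapply(seq_len(n_surrogates), function(i) perm_within_periods(series$period_id))
  })
  for (i in seq_len(n_surrogates)) {
    null_counts[i] <- count_sig_positive(
      src$M, tgt$M, series$period_id, tp$prev_row, tp$next_row,
      n_shuffles, alpha,
      seed = child_seed(seed, "inner", i), order = orders[[i]]
    )
  }
  structure(
    list(
      observed = observed,
      null_counts = null_counts,
      p_value = mean(null_counts >= observed)
    ),
    class = "igt_excess"
  )
}

#' @export
print.igt_excess <- function(x, ...) {
  cat(sprintf(
    "Excess-significance test: observed %d significant positive cells;\n null mean %.1f (%d surrogates); p = %.4g\n",
    x$observed, mean(x$null_counts), length(x$null_counts), x$p_value
  ))
  invisible(x)
}

#' Fight-size autocorrelation
#'
#' Pearson correlation of fight sizes at increasing lags, pooling
#' (size_t, size_(t+lag)) pairs within periods only. Near-zero coefficients
#' at all lags are the motivation for looking at membership, rather than
#' size, correlations.
#'
#' @param series A [conflict_series].
#' @param max_lag Largest lag to report.
#' @return A tibble with `lag`, `r` (NA when fewer than 3 pooled pairs or
#'   zero variance), and `n_pairs`.
#' @export
size_autocorrelation <- function(series, max_lag = 10L) {
  assert_count(max_lag, "max_lag", min = 1L)
  sizes <- fight_sizes(series)
  purrr::map_dfr(seq_len(max_lag), function(l) {
    tp <- transition_pairs(series, lag = l)
    x <- sizes[tp$prev_row]
    y <- sizes[tp$next_row]
    r <- if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      NA_real_
    } else {
      stats::cor(x, y)
    }
    tibble::tibble(lag = l, r = r, n_pairs = length(x))
  })
}

#' Directed edge list of strong correlations
#'
#' Exports the network view of a correlation table: directed edges (source ->
#' target, forward in time) whose `delta_p` magnitude clears a threshold at
#' 95% confidence. The default threshold of 0.06 keeps only edges above 6%.
#'
#' @param results Output of [fight_correlations()].
#' @param threshold Minimum `|delta_p|`.
#' @param significant_only Keep only cells flagged `significant_95`.
#' @return A tibble with `from`, `to`, `delta_p`, `sign`.
#' @export
correlation_edges <- function(results, threshold = 0.06, significant_only = TRUE) {
  keep <- abs(results$delta_p) > threshold & !results$undefined
  if (significant_only) keep <- keep & results$significant_95
  out <- results[keep, c("source", "target", "delta_p")]
  names(out)[1:2] <- c("from", "to")
  out$sign <- ifelse(out$delta_p > 0, "attraction", "inhibition")
  out
}
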