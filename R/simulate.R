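# Conflict cascade simulation from a strategy matrix.
#
# A cascade starts from a spontaneous seed pair (the whole first fight).
# At each step, every source n-tuple inside the current fight issues, for
# every target k-tuple, an independent recommendation with probability
# |entry| -- to join if the entry is positive, to avoid if negative. Per
# target, recommendations are resolved by the combinator; the next fight is
# the union of the members of all joining k-tuples. The cascade ends when
# fewer than two individuals would fight next.
#
# Because recommendations are independent Bernoulli draws, the per-target
# join probability has a closed form (products over the relevant sources),
# so each target is sampled once per step instead of sampling every
# (source, target) recommendation; the resulting distribution is identical.

#' Draw a spontaneous seed pair
#'
#' @param roster Character vector of ids (size >= 2).
#' @param mode `"uniform"`: uniform over unordered distinct pairs;
#'   `"empirical"`: pairs drawn proportional to `weights`.
#' @param weights For `"empirical"`: nonnegative weights, either named by
#'   pair key (`"a|b"`) or aligned with the canonical pair ordering.
#' @param seed Integer seed.
#' @return Character vector of two ids (sorted).
#' @export
draw_seed <- function(roster, mode = c("uniform", "empirical"),
                      weights = NULL, seed = 1L) {
  mode <- match.arg(mode)
  roster <- as.character(roster)
  if (length(roster) < 2L) abort_igt("Seed draws need a roster of >= 2.")
  uni <- tuple_universe(roster, 2L)
  w <- seed_weights(uni$keys, mode, weights)
  i <- with_rng(seed, sample.int(length(uni$keys), 1L, prob = w))
  sort(roster[uni$members[i, ]])
}

seed_weights <- function(keys, mode, weights) {
  if (mode == "uniform") return(NULL)
  if (is.null(weights)) abort_igt("Empirical seed mode needs `weights`.")
  if (!is.null(names(weights))) {
    w <- weights[keys]
    w[is.na(w)] <- 0
  } else {
    if (length(weights) != length(keys)) {
      abort_igt("Unnamed seed weights must match the number of pairs.")
    }
    w <- weights
  }
  if (any(w < 0) || sum(w) <= 0) abort_igt("Seed weights must be nonnegative, not all zero.")
  w
}

# Per-target join probabilities for one step; `current` is an integer vector
# of roster indices. Consumes the RNG.
step_probs <- function(strategy, current, strict_and = FALSE) {
  n <- strategy$n
  rows <- if (n == 1L) {
    current
  } else {
    pr <- strategy_pair_rows(strategy)
    cmb <- utils::combn(current, 2L)
    pr[cbind(cmb[1L, ], cmb[2L, ])]
  }
  sub <- strategy$M[rows, , drop = FALSE]
  pos <- pmax(sub, 0)
  neg <- pmax(-sub, 0)
  p_no_join <- exp(colSums(log1p(-pos)))
  if (strategy$combinator == "OR") {
    return(1 - p_no_join)
  }
  if (!strict_and) {
    # Unanimity among received recommendations: at least one recommendation,
    # all of them to join.
    return((1 - p_no_join) * exp(colSums(log1p(-neg))))
  }
  # Strict reading: every relevant source (nonzero entry) must recommend join.
  relevant <- sub != 0
  any_neg <- colSums(neg > 0) > 0
  n_rel <- colSums(relevant)
  logp <- colSums(ifelse(sub > 0, log(pos + (sub <= 0)), 0))
  out <- exp(logp)
  out[any_neg | n_rel == 0L] <- 0
  out
}

strategy_pair_rows <- function(strategy) {
  pr <- attr(strategy, "pair_rows")
  if (is.null(pr)) pr <- pair_row_matrix(length(strategy$roster))
  pr
}

#' One cascade step
#'
#' Given the current fight's participant set, samples the next fight's
#' participant set under the strategy's recommendation model. The next set
#' may be empty or a singleton, in which case the cascade terminates.
#'
#' @param strategy A `strategy_matrix`.
#' @param current Character vector of current participants (>= 2).
#' @param strict_and Use the strict AND reading (every relevant source must
#'   recommend joining) instead of the default unanimity-among-received
#'   reading. Strict AND makes joining vanish combinatorially as fights
#'   grow, which is why unanimity is the default.
#' @param seed Integer seed.
#' @return Character vector of next-fight participants (possibly length < 2).
#' @export
cascade_step <- function(strategy, current, strict_and = FALSE, seed = 1L) {
  idx <- match(as.character(current), strategy$roster)
  if (anyNA(idx)) abort_igt("Current participants must be in the strategy roster.")
  if (length(idx) < 2L) abort_igt("A fight has at least two participants.")
  with_rng(seed, {
    nxt <- sample_next(strategy, idx, strict_and)
  })
  sort(strategy$roster[nxt])
}

sample_next <- function(strategy, current, strict_and) {
  pj <- step_probs(strategy, current, strict_and)
  joins <- which(stats::runif(length(pj)) < pj)
  if (strategy$k == 1L) {
    joins
  } else {
    sort(unique(as.vector(strategy$target_members[joins, ])))
  }
}

# Core cascade loop on integer indices; assumes RNG is set by the caller.
run_cascade_int <- function(strategy, seed_pair, max_fights, strict_and,
                            seed_members = NULL, seed_w = NULL) {
  if (is.null(seed_pair)) {
    if (is.null(seed_members)) seed_members <- tuple_universe(strategy$roster, 2L)$members
    i <- if (is.null(seed_w)) {
      sample.int(nrow(seed_members), 1L)
    } else {
      sample.int(nrow(seed_members), 1L, prob = seed_w)
    }
    seed_pair <- seed_members[i, ]
  }
  fights <- vector("list", 8L)
  fights[[1L]] <- as.integer(seed_pair)
  n_f <- 1L
  terminated <- NA_character_
  current <- fights[[1L]]
  while (TRUE) {
    if (n_f >= max_fights) {
      terminated <- "max_fights"
      break
    }
    nxt <- sample_next(strategy, current, strict_and)
    if (length(nxt) < 2L) {
      terminated <- if (length(nxt) == 0L) "no_recommendation" else "single_joiner"
      break
    }
    n_f <- n_f + 1L
    if (n_f > length(fights)) fights <- c(fights, vector("list", length(fights)))
    fights[[n_f]] <- nxt
    current <- nxt
  }
  list(fights = fights[seq_len(n_f)], terminated_by = terminated)
}

#' Run a single conflict cascade
#'
#' Iterates [cascade_step()] from a seed-pair fight until fewer than two
#' individuals would join (recording whether no one, or only a single
#' individual, was recommended) or a safety cap is reached (forest-fire
#' regimes never die down on their own).
#'
#' @param strategy A `strategy_matrix`.
#' @param seed_pair Optional character vector of two ids; drawn uniformly at
#'   random when `NULL`.
#' @param max_fights Cap on fights per cascade (default 10x roster size).
#' @param strict_and See [cascade_step()].
#' @param seed Integer seed.
#' @return A list of class `cascade_record`: `seed` (pair key), `fights`
#'   (list of participant id vectors), `sizes`, `terminated_by` (one of
#'   `"no_recommendation"`, `"single_joiner"`, `"max_fights"`).
#' @export
run_cascade <- function(strategy, seed_pair = NULL,
                        max_fights = 10L * length(strategy$roster),
                        strict_and = FALSE, seed = 1L) {
  assert_count(max_fights, "max_fights", min = 1L)
  if (!is.null(seed_pair)) {
    seed_pair <- match(as.character(seed_pair), strategy$roster)
    if (anyNA(seed_pair) || length(seed_pair) != 2L) {
      abort_igt("`seed_pair` must be two roster ids.")
    }
  }
  res <- with_rng(seed, {
    run_cascade_int(strategy, seed_pair, max_fights, strict_and)
  })
  fights <- lapply(res$fights, function(ix) sort(strategy$roster[ix]))
  structure(
    list(
      seed = tuple_key(fights[[1L]]),
      fights = fights,
      sizes = lengths(fights),
      terminated_by = res$terminated_by
    ),
    class = "cascade_record"
  )
}

#' @export
print.cascade_record <- function(x, ...) {
  cat(sprintf(
    "<cascade_record> seed %s, %d fights (max size %d), terminated by %s\n",
    x$seed, length(x$fights), max(x$sizes), x$terminated_by
  ))
  invisible(x)
}

#' Simulate a conflict series from a strategy matrix
#'
#' Concatenates cascades (each started by a fresh spontaneous seed pair)
#' until at least `n_fights` fights have accumulated, then lays the fights
#' into synthetic observation periods. Cascade membership is retained in a
#' `cascade_id` column, and capped cascades are flagged in the
#' `cascade_capped` column so forest-fire artefacts can be excluded from
#' fight-size summaries.
#'
#' @param strategy A `strategy_matrix`.
#' @param n_fights Target number of fights (the last cascade is kept whole,
#'   so the result can slightly exceed it).
#' @param fights_per_period Fights laid into each synthetic period.
#' @param seed Integer seed; identical seeds give byte-identical series.
#' @param seed_mode,seed_weights Passed to the seed draw (see [draw_seed()]).
#' @param max_fights Per-cascade cap; when more than half the cascades hit
#'   it, a warning is recorded (and emitted) since the model is in a
#'   forest-fire regime.
#' @param strict_and See [cascade_step()].
#' @return A [conflict_series] over the strategy's roster with `cascade_id`
#'   and `cascade_capped` columns and a `sim_meta` attribute (seed, model
#'   summary, cap statistics).
#' @export
simulate_series <- function(strategy, n_fights, fights_per_period = 60L,
                            seed = 1L, seed_mode = c("uniform", "empirical"),
                            seed_weights = NULL,
                            max_fights = 10L * length(strategy$roster),
                            strict_and = FALSE) {
  assert_count(n_fights, "n_fights", min = 1L)
  seed_mode <- match.arg(seed_mode)
  uni2 <- tuple_universe(strategy$roster, 2L)
  seed_w <- seed_weights(uni2$keys, seed_mode, seed_weights)

  if (strategy$n == 2L) {
    attr(strategy, "pair_rows") <- pair_row_matrix(length(strategy$roster))
  }
  cascades <- vector("list", 256L)
  capped <- logical(256L)
  n_casc <- 0L
  total <- 0L
  with_rng(seed, {
    while (total < n_fights) {
      n_casc <- n_casc + 1L
      if (n_casc > length(cascades)) {
        cascades <- c(cascades, vector("list", length(cascades)))
        capped <- c(capped, logical(length(capped)))
      }
      res <- run_cascade_int(strategy, NULL, max_fights, strict_and,
        seed_members = uni2$members, seed_w = seed_w
      )
      cascades[[n_casc]] <- res$fights
      capped[n_casc] <- res$terminated_by == "max_fights"
      total <- total + length(res$fights)
    }
  })
  cascades <- cascades[seq_len(n_casc)]
  capped <- capped[seq_len(n_casc)]
  fights <- unlist(cascades, recursive = FALSE, use.names = FALSE)
  cascade_id <- rep.int(seq_len(n_casc), lengths(cascades))
  capped_frac <- mean(capped)
  if (capped_frac > 0.5) {
    rlang::warn(sprintf(
      "Forest-fire regime: %.0f%% of cascades hit the %d-fight cap.",
      100 * capped_frac, max_fights
    ), class = "igt_forest_fire_warning")
  }
  n_total <- length(fights)
  period <- (seq_len(n_total) - 1L) %/% fights_per_period + 1L
  slot <- (seq_len(n_total) - 1L) %% fights_per_period
  capped_by_fight <- capped[cascade_id]
  series <- conflict_series(
    tibble::tibble(
      fight_id = seq_len(n_total),
      period_id = period,
      date = sprintf("day%03d", period),
      start_s = slot * 120,
      end_s = slot * 120 + 60,
      participants = lapply(fights, function(ix) sort(strategy$roster[ix])),
      cascade_id = cascade_id,
      cascade_capped = capped_by_fight
    ),
    roster = tibble::tibble(id = strategy$roster)
  )
  attr(series, "sim_meta") <- list(
    seed = seed, model = glance(strategy),
    n_cascades = n_casc, capped_fraction = capped_frac,
    max_fights = max_fights, strict_and = strict_and, seed_mode = seed_mode
  )
  series
}
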