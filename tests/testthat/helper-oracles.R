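# Independent oracles used across the suite: brute-force enumeration of the
# correlation estimator, exhaustive signed-rank enumeration, and small random
# series generators. These stay deliberately naive -- loops over raw fights --
# so they share no code path with the implementations they check.

# Numerator/denominator of p_hat by direct enumeration over transition chains.
brute_phat <- function(participants, period_ids, source, target, lag) {
  num <- 0L
  den <- 0L
  n <- length(participants)
  for (t in seq_len(n)) {
    t2 <- t + lag
    if (t2 > n) next
    if (period_ids[t] != period_ids[t2]) next
    if (all(source %in% participants[[t]])) {
      den <- den + 1L
      if (all(target %in% participants[[t2]])) num <- num + 1L
    }
  }
  c(num = num, den = den)
}

# Exact one-tailed signed-rank p-value by enumerating all 2^n sign vectors.
brute_signed_rank <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(NA_real_)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mean(v_all >= v_obs)
}

# A random valid series: <= max_fights fights over a small roster, 1-2 periods.
random_small_series <- function(seed, roster = c("a", "b", "c", "d"),
                                max_fights = 10L) {
  withr::with_seed(seed, {
    n_f <- sample(2:max_fights, 1L)
    periods <- sort(sample(1:2, n_f, replace = TRUE))
    participants <- lapply(seq_len(n_f), function(i) {
      sort(sample(roster, sample(2:length(roster), 1L)))
    })
    slot <- stats::ave(seq_len(n_f), periods, FUN = seq_along)
    conflict_series(
      tibble::tibble(
        fight_id = seq_len(n_f),
        period_id = periods,
        start_s = (slot - 1) * 60,
        end_s = (slot - 1) * 60 + 30,
        participants = participants
      ),
      roster = tibble::tibble(id = roster)
    )
  })
}

# All tuple keys of a given size over a roster (as id vectors).
all_tuples <- function(roster, size) {
  if (size == 1L) {
    as.list(roster)
  } else {
    cmb <- utils::combn(roster, 2L)
    lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  }
}

expect_series_equal <- function(a, b) {
  expect_equal(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_equal(roster_of(a), roster_of(b))
}
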