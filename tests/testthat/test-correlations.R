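# Membership correlation estimator, time-shuffle null, excess significance.

test_that("p_hat matches by-hand enumeration on the toy series", {
  s <- toy_series() # {a,b},{b,c},{a,c},{a,b} in one period
  expect_equal(p_hat(s, "a", "b", 1), tibble::tibble(p_hat = 1, n_source = 2L))
  expect_equal(p_hat(s, c("a", "b"), "c", 1), tibble::tibble(p_hat = 1, n_source = 1L))
  # fights with b and a successor: #1 (succ {b,c}: no a), #2 (succ {a,c}: a)
  expect_equal(p_hat(s, "b", "a", 1), tibble::tibble(p_hat = 0.5, n_source = 2L))
  s1 <- conflict_series(tibble::tibble(
    fight_id = 1L, period_id = 1L, start_s = 0, end_s = 10,
    participants = list(c("a", "b"))
  ))
  expect_equal(p_hat(s1, "a", "b", 1), tibble::tibble(p_hat = 0, n_source = 0L))
  expect_error(p_hat(s, "a", "b", 0), "lag")
})

test_that("batch estimator agrees with brute-force enumeration (property)", {
  roster <- c("a", "b", "c", "d")
  for (seed in 1:30) {
    s <- random_small_series(seed, roster = roster)
    for (lag in 1:2) {
      for (n in 1:2) {
        for (k in 1:2) {
          res <- fight_correlations(s, n = n, k = k, lag = lag, n_shuffles = 2, seed = 1)
          for (src in all_tuples(roster, n)) {
            for (tgt in all_tuples(roster, k)) {
              ref <- brute_phat(s$participants, s$period_id, src, tgt, lag)
              row <- res[res$source == tuple_key(src) & res$target == tuple_key(tgt), ]
              expect_equal(row$n_source, unname(ref["den"]))
              expect_equal(
                row$p_hat * max(row$n_source, 1L),
                unname(ref["num"])
              )
            }
          }
        }
      }
    }
  }
})

test_that("time shuffles preserve composition and are uniform over orderings", {
  s <- conflict_series(tibble::tibble(
    fight_id = 1:4, period_id = c(1L, 1L, 1L, 2L),
    start_s = c(0, 60, 120, 0), end_s = c(0, 60, 120, 0) + 30,
    participants = list(c("a", "b"), c("b", "c"), c("c", "d"), c("a", "d"))
  ))
  orders <- character(600)
  for (i in seq_len(600)) {
    sh <- shuffle_series(s, seed = i)
    # multiset of compositions preserved within each period
    expect_setequal(
      vapply(sh$participants[sh$period_id == 1L], paste, "", collapse = ","),
      vapply(s$participants[s$period_id == 1L], paste, "", collapse = ",")
    )
    # the single-fight period is untouched
    expect_identical(sh$participants[[4]], s$participants[[4]])
    expect_identical(sh$start_s, s$start_s) # slots keep their times
    orders[i] <- paste(sh$fight_id[1:3], collapse = "")
  }
  freq <- table(orders)
  expect_equal(length(freq), 6L) # all 3! orderings occur
  expect_true(all(abs(freq / 600 - 1 / 6) < 3 * sqrt((1 / 6) * (5 / 6) / 600)))
})

test_that("delta_p vanishes when conditioning is vacuous", {
  # source in every fight: p_hat equals the marginal rate of the target in
  # successor slots, which the shuffle null reproduces exactly
  others <- list(c("a", "b"), c("a", "c"), c("a", "d"), c("a", "b", "d"))
  parts <- withr::with_seed(5, sample(rep(others, 6)))
  s <- conflict_series(tibble::tibble(
    fight_id = 1:24, period_id = 1L, start_s = 0:23 * 60, end_s = 0:23 * 60 + 30,
    participants = parts
  ))
  res <- delta_p(s, "a", "b", n_shuffles = 400, seed = 5)
  expect_lt(abs(res$delta_p), 0.05)
  expect_false(res$significant_95)
})

test_that("a planted alternating series yields attraction and self-inhibition", {
  # {a,b},{c,d},{a,b},{c,d},... : a predicts c, a anti-predicts a
  parts <- rep(list(c("a", "b"), c("c", "d")), 10)
  s <- conflict_series(tibble::tibble(
    fight_id = 1:20, period_id = 1L, start_s = 0:19 * 60, end_s = 0:19 * 60 + 30,
    participants = parts
  ))
  ac <- delta_p(s, "a", "c", n_shuffles = 300, seed = 7)
  aa <- delta_p(s, "a", "a", n_shuffles = 300, seed = 7)
  expect_gt(ac$delta_p, 0.3)
  expect_true(ac$significant_95)
  expect_lt(aa$delta_p, -0.3)
  expect_true(aa$significant_95)
})

test_that("results are equivariant under individual relabelling", {
  s <- random_small_series(11)
  res <- fight_correlations(s, n = 1, k = 1, n_shuffles = 40, seed = 3)
  # swap labels a <-> d (preserves lexicographic sorting of the other ids)
  relab <- c(a = "d", b = "b", c = "c", d = "a")
  s2 <- conflict_series(
    tibble::tibble(
      fight_id = s$fight_id, period_id = s$period_id,
      start_s = s$start_s, end_s = s$end_s,
      participants = lapply(s$participants, function(p) sort(unname(relab[p])))
    ),
    roster = tibble::tibble(id = sort(unname(relab[roster_of(s)$id])))
  )
  res2 <- fight_correlations(s2, n = 1, k = 1, n_shuffles = 40, seed = 3)
  for (i in seq_len(nrow(res))) {
    row2 <- res2[
      res2$source == unname(relab[res$source[i]]) &
        res2$target == unname(relab[res$target[i]]),
    ]
    expect_equal(row2$p_hat, res$p_hat[i])
    expect_equal(row2$delta_p, res$delta_p[i])
    expect_equal(row2$significant_95, res$significant_95[i])
  }
})

test_that("undefined cells are flagged and report zero delta_p", {
  s <- toy_series()
  res <- fight_correlations(s, n = 2, k = 1, n_shuffles = 20, seed = 1)
  bd <- res[res$source == "b|d", ] # d never fights
  expect_true(all(bd$undefined))
  expect_true(all(bd$delta_p == 0))
  expect_false(any(bd$significant_95))
})

test_that("excess significance is tiny for planted structure, with guardrails", {
  # a planted, mostly-attractive strategy produces far more significant
  # positive cells than any time-shuffled surrogate
  s <- suppressWarnings(generate_observed(synthetic_spec(
    roster_size = 12, n = 1, k = 1, density = 0.25, mag_range = c(0.3, 0.8),
    sign_prob = 0.8, n_fights = 400, periods = 4, seed = 8
  )))$series
  ex <- suppressWarnings(
    excess_significance(s, n_shuffles = 60, n_surrogates = 30, seed = 2)
  )
  expect_lte(ex$p_value, 1 / 31)
  expect_gt(ex$observed, mean(ex$null_counts))
  expect_warning(
    excess_significance(s, n_shuffles = 30, n_surrogates = 10, seed = 2),
    "surrogates"
  )
  s1 <- conflict_series(tibble::tibble(
    fight_id = 1L, period_id = 1L, start_s = 0, end_s = 10,
    participants = list(c("a", "b"))
  ))
  expect_error(excess_significance(s1, seed = 1), "transition pairs")
})

test_that("size autocorrelation handles alternating, i.i.d., and constant sizes", {
  mk <- function(sizes) {
    conflict_series(tibble::tibble(
      fight_id = seq_along(sizes), period_id = 1L,
      start_s = seq_along(sizes) * 60, end_s = seq_along(sizes) * 60 + 30,
      participants = lapply(sizes, function(s) sprintf("m%02d", 1:s))
    ))
  }
  alt <- mk(rep(c(2L, 6L), 10))
  expect_equal(size_autocorrelation(alt, 1)$r, -1)

  const <- mk(rep(3L, 10))
  expect_true(is.na(size_autocorrelation(const, 1)$r))

  iid <- iid_series(roster_size = 20, n_fights = 600, periods = 3, seed = 9)
  ac <- size_autocorrelation(iid, 5)
  expect_true(all(abs(ac$r) <= 3 / sqrt(ac$n_pairs)))
})

test_that("edge export applies the magnitude threshold at 95% confidence", {
  res <- tibble::tibble(
    source = c("a", "b", "c"), target = c("b", "c", "a"), lag = 1L,
    p_hat = c(0.5, 0.4, 0.3), null_mean = c(0.3, 0.37, 0.4),
    null_sd = 0.01, delta_p = c(0.2, 0.03, -0.1), n_source = 10L,
    significant_95 = c(TRUE, TRUE, FALSE), undefined = FALSE
  )
  edges <- correlation_edges(res)
  expect_equal(edges$from, "a")
  expect_equal(edges$sign, "attraction")
  all_edges <- correlation_edges(res, significant_only = FALSE)
  expect_setequal(all_edges$from, c("a", "c"))
})
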