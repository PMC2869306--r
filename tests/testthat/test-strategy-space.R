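# Strategy matrices, the correlation ansatz, shuffles, coarse-graining.

roster5 <- c("a", "b", "c", "d", "e")

rand_strategy <- function(seed, n = 2L, k = 1L, roster = roster5) {
  spec <- synthetic_spec(
    roster_size = length(roster), n = n, k = k, density = 0.5,
    mag_range = c(0.05, 0.9), sign_prob = 0.5, seed = seed
  )
  S <- plant_strategy(spec)
  S$roster <- roster
  rownames(S$M) <- vapply(
    seq_len(nrow(S$M)),
    function(i) paste(roster[S$source_members[i, ]], collapse = "|"), ""
  )
  colnames(S$M) <- vapply(
    seq_len(ncol(S$M)),
    function(i) paste(roster[S$target_members[i, ]], collapse = "|"), ""
  )
  S
}

test_that("strategy construction validates entries and keys tuples canonically", {
  sm <- strategy_matrix(
    tibble::tibble(source = "b|a", target = "c", value = 0.3),
    n = 2, k = 1, combinator = "AND", roster = c("a", "b", "c")
  )
  expect_equal(sm$M["a|b", "c"], 0.3)
  expect_error(
    strategy_matrix(
      tibble::tibble(source = "a", target = "c", value = 1.2),
      n = 1, k = 1, roster = c("a", "c")
    ),
    "magnitudes"
  )
  expect_error(
    strategy_matrix(
      tibble::tibble(source = "a|b", target = "c", value = 0.2),
      n = 1, k = 1, roster = c("a", "b", "c")
    ),
    "size"
  )
  g <- glance(sm)
  expect_equal(g$n_nonzero, 1L)
  expect_equal(g$n, 2L)
})

test_that("the ansatz maps measured delta_p into entries, zeroing undefined cells", {
  empty <- fit_strategy(
    tibble::tibble(
      source = character(0), target = character(0), lag = integer(0),
      delta_p = numeric(0), undefined = logical(0)
    ),
    n = 1, k = 1, roster = c("a", "b")
  )
  expect_true(all(empty$M == 0))

  res <- tibble::tibble(
    source = c("a", "a"), target = c("b", "c"), lag = 1L,
    delta_p = c(0.3, 0.9), undefined = c(FALSE, TRUE)
  )
  fit <- fit_strategy(res, n = 1, k = 1, roster = c("a", "b", "c"))
  expect_equal(fit$M["a", "b"], 0.3)
  expect_equal(fit$M["a", "c"], 0) # undefined -> don't care
  expect_error(fit_strategy(dplyr::mutate(res, lag = 2L), n = 1, k = 1), "lag-1")

  # planted alternating series: positive a->c, negative a->a entries
  parts <- rep(list(c("a", "b"), c("c", "d")), 10)
  s <- conflict_series(tibble::tibble(
    fight_id = 1:20, period_id = 1L, start_s = 0:19 * 60, end_s = 0:19 * 60 + 30,
    participants = parts
  ))
  cyc <- fit_strategy(
    fight_correlations(s, n_shuffles = 100, seed = 2),
    n = 1, k = 1, roster = c("a", "b", "c", "d")
  )
  expect_gt(cyc$M["a", "c"], 0)
  expect_lt(cyc$M["a", "a"], 0)
})

test_that("all perturbations preserve shape, roster, and combinator", {
  S <- rand_strategy(4)
  for (P in list(
    total_shuffle(S, 1), outgoing_shuffle(S, 1),
    incoming_shuffle(S, 1), coarse_grain(S, 2)
  )) {
    expect_equal(dim(P$M), dim(S$M))
    expect_equal(P$roster, S$roster)
    expect_equal(c(P$n, P$k), c(S$n, S$k))
    expect_equal(P$combinator, S$combinator)
  }
})

test_that("total shuffle preserves the global value multiset", {
  S <- rand_strategy(5)
  Tt <- total_shuffle(S, seed = 9)
  expect_equal(unname(sort(as.vector(Tt$M))), unname(sort(as.vector(S$M))))
  expect_false(identical(Tt$M, S$M)) # many distinct values: reassigned w.h.p.
  # all-equal entries: shuffling is a no-op
  E <- S
  E$M[] <- 0.25
  expect_equal(total_shuffle(E, seed = 1)$M, E$M)
  # distinct seeds give distinct assignments (>= 10 distinct values)
  expect_false(identical(total_shuffle(S, 1)$M, total_shuffle(S, 2)$M))
})

test_that("outgoing shuffle preserves per-source multisets and forces opposite-sign swaps", {
  S <- rand_strategy(6)
  O <- outgoing_shuffle(S, seed = 3)
  for (i in seq_len(nrow(S$M))) {
    expect_equal(unname(sort(O$M[i, ])), unname(sort(S$M[i, ])))
  }
  # a source with exactly {+0.4, -0.4} must swap them
  P <- strategy_matrix(
    tibble::tibble(source = c("a|b", "a|b"), target = c("a", "b"), value = c(0.4, -0.4)),
    n = 2, k = 1, roster = c("a", "b")
  )
  for (seed in 1:5) {
    Ps <- outgoing_shuffle(P, seed = seed)
    expect_equal(Ps$M["a|b", "a"], -0.4)
    expect_equal(Ps$M["a|b", "b"], 0.4)
  }
  # all-positive rows still get reassigned (multiset preserved regardless)
  AP <- S
  AP$M <- abs(AP$M)
  APs <- outgoing_shuffle(AP, seed = 2)
  for (i in seq_len(nrow(AP$M))) {
    expect_equal(unname(sort(APs$M[i, ])), unname(sort(AP$M[i, ])))
  }
  expect_error(outgoing_shuffle(rand_strategy(1, k = 2L)), "k = 1")
})

test_that("incoming shuffle preserves per-target multisets", {
  S <- rand_strategy(7)
  I <- incoming_shuffle(S, seed = 4)
  for (j in seq_len(ncol(S$M))) {
    expect_equal(unname(sort(I$M[, j])), unname(sort(S$M[, j])))
  }
  expect_false(identical(I$M, S$M))
  expect_error(incoming_shuffle(rand_strategy(1, k = 2L)), "k = 1")
})

test_that("coarse-graining collapses to per-sign means at level 1", {
  S <- strategy_matrix(
    tibble::tibble(
      source = c("a", "a", "b"), target = c("b", "c", "c"),
      value = c(0.1, 0.3, -0.2)
    ),
    n = 1, k = 1, roster = c("a", "b", "c")
  )
  C <- coarse_grain(S, 1)
  expect_equal(C$M["a", "b"], 0.2)
  expect_equal(C$M["a", "c"], 0.2)
  expect_equal(C$M["b", "c"], -0.2)
  expect_equal(sum(C$M != 0), 3L) # zeros stay zero
  # one-sided matrices collapse only the populated side
  P <- strategy_matrix(
    tibble::tibble(source = c("a", "b"), target = "c", value = c(0.2, 0.6)),
    n = 1, k = 1, roster = c("a", "b", "c")
  )
  expect_equal(unique(coarse_grain(P, 1)$M[coarse_grain(P, 1)$M != 0]), 0.4)
})

test_that("coarse-graining refines with level and is idempotent", {
  S <- rand_strategy(8)
  # within the log-grid family the worst-case log-magnitude displacement is
  # bounded by half the grid spacing, which shrinks as levels are added
  log_err <- function(l, sgn) {
    C <- coarse_grain(S, l)$M
    sel <- sign(S$M) == sgn
    max(abs(log(abs(S$M[sel])) - log(abs(C[sel]))))
  }
  for (sgn in c(-1, 1)) {
    mags <- abs(S$M[sign(S$M) == sgn])
    span <- log(max(mags)) - log(min(mags))
    for (l in c(2L, 4L, 8L)) {
      expect_lte(log_err(l, sgn), span / (2 * (l - 1)) + 1e-12)
    }
    # realized displacement at many levels is far below the two-level one
    expect_lt(log_err(8L, sgn), log_err(2L, sgn))
  }
  for (l in c(1L, 2L, 4L)) {
    once <- coarse_grain(S, l)
    expect_equal(coarse_grain(once, l)$M, once$M)
  }
  Z <- strategy_matrix(NULL, 1, 1, roster = roster5)
  expect_equal(coarse_grain(Z, 3)$M, Z$M)
  # signs never flip
  C2 <- coarse_grain(S, 2)
  expect_true(all(sign(C2$M) == sign(S$M)))
})

test_that("strategy files round-trip through keyed text", {
  S <- rand_strategy(9)
  f <- withr::local_tempfile(fileext = ".json")
  write_strategy(S, f)
  back <- read_strategy(f)
  expect_equal(back$M, S$M)
  expect_equal(back$roster, S$roster)
  expect_equal(back$combinator, S$combinator)
  # zero matrix round-trips too
  Z <- strategy_matrix(NULL, 2, 1, roster = roster5)
  write_strategy(Z, f)
  expect_equal(read_strategy(f)$M, Z$M)
})
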