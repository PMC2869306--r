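# Seed draws, recommendation resolution, cascade loops, series simulation.

test_that("seed pairs are uniform over unordered pairs, or follow weights", {
  expect_equal(draw_seed(c("a", "b"), seed = 1), c("a", "b"))
  draws <- vapply(1:6000, function(i) {
    tuple_key(draw_seed(c("a", "b", "c", "d"), seed = i))
  }, "")
  freq <- table(draws)
  expect_equal(length(freq), 6L)
  expect_true(all(abs(freq / 6000 - 1 / 6) < 3 * sqrt((1 / 6) * (5 / 6) / 6000)))

  w <- c("a|b" = 100, "c|d" = 0.01)
  conc <- vapply(1:200, function(i) {
    tuple_key(draw_seed(c("a", "b", "c", "d"), mode = "empirical", weights = w, seed = i))
  }, "")
  expect_gte(mean(conc == "a|b"), 0.99)
  expect_error(draw_seed(c("a", "b", "c"), mode = "empirical"), "weights")
  expect_error(draw_seed("a"), "roster")
})

test_that("a cascade step resolves recommendations by combinator", {
  # all-zero strategy: nobody is recommended
  Z <- strategy_matrix(NULL, 1, 1, roster = c("a", "b", "x"))
  expect_length(cascade_step(Z, c("a", "x"), seed = 1), 0L)

  # single deterministic entry, OR: exactly the target joins
  S <- strategy_matrix(
    tibble::tibble(source = "a", target = "b", value = 1),
    n = 1, k = 1, combinator = "OR", roster = c("a", "b", "x")
  )
  expect_equal(cascade_step(S, c("a", "x"), seed = 1), "b")

  # conflicting recommendations: {a}->{c}=+1, {b}->{c}=-1
  tt <- tibble::tibble(source = c("a", "b"), target = "c", value = c(1, -1))
  or_model <- strategy_matrix(tt, 1, 1, "OR", roster = c("a", "b", "c"))
  and_model <- strategy_matrix(tt, 1, 1, "AND", roster = c("a", "b", "c"))
  for (seed in 1:5) {
    expect_equal(cascade_step(or_model, c("a", "b"), seed = seed), "c")
    expect_length(cascade_step(and_model, c("a", "b"), seed = seed), 0L)
  }

  # strict AND: every relevant source must recommend joining
  half <- strategy_matrix(
    tibble::tibble(source = c("a", "b"), target = "c", value = c(1, 0.5)),
    n = 1, k = 1, combinator = "AND", roster = c("a", "b", "c")
  )
  joins <- vapply(1:400, function(i) {
    length(cascade_step(half, c("a", "b"), strict_and = TRUE, seed = i))
  }, integer(1))
  expect_true(abs(mean(joins == 1L) - 0.5) < 3 * sqrt(0.25 / 400))
})

test_that("cascades terminate correctly and respect the fight-size floor", {
  Z <- strategy_matrix(NULL, 1, 1, roster = c("a", "b", "c"))
  r <- run_cascade(Z, seed_pair = c("a", "b"), seed = 1)
  expect_equal(length(r$fights), 1L)
  expect_equal(r$terminated_by, "no_recommendation")
  expect_equal(r$seed, "a|b")

  # single-joiner termination
  S1 <- strategy_matrix(
    tibble::tibble(source = "a", target = "b", value = 1),
    n = 1, k = 1, combinator = "OR", roster = c("a", "b")
  )
  r1 <- run_cascade(S1, seed_pair = c("a", "b"), seed = 2)
  expect_equal(r1$terminated_by, "single_joiner")

  # deterministic 2-cycle under (1,2): {a}->{c,d} = +1 keeps itself alive
  fp <- strategy_matrix(
    tibble::tibble(source = c("a", "c"), target = c("c|d", "a|b"), value = 1),
    n = 1, k = 2, combinator = "OR", roster = c("a", "b", "c", "d")
  )
  rf <- run_cascade(fp, seed_pair = c("a", "b"), max_fights = 7, seed = 3)
  expect_equal(rf$terminated_by, "max_fights")
  expect_equal(length(rf$fights), 7L)
  expect_true(all(rf$sizes >= 2L))

  # sizes >= 2 across random strategies
  for (seed in 1:10) {
    S <- plant_strategy(synthetic_spec(
      roster_size = 8, n = 1, k = 2, density = 0.3,
      mag_range = c(0.2, 0.8), seed = seed
    ))
    r <- run_cascade(S, max_fights = 20, seed = seed)
    expect_true(all(r$sizes >= 2L))
  }
})

test_that("simulated series hit the fight target and stay on the roster", {
  Z <- strategy_matrix(NULL, 2, 1, roster = sprintf("m%02d", 1:6))
  s <- simulate_series(Z, n_fights = 100, fights_per_period = 30, seed = 4)
  expect_equal(nrow(s), 100L)
  expect_true(all(fight_sizes(s) == 2L))
  expect_equal(length(unique(s$cascade_id)), 100L)
  expect_equal(max(s$period_id), 4L)
  expect_true(all(unlist(s$participants) %in% roster_of(s)$id))
})

test_that("identical seeds give identical series; different seeds differ", {
  fx <- regime_benchmark(roster_size = 8, seed = 2)[["21_AND"]]
  a <- simulate_series(fx, n_fights = 150, seed = 9)
  b <- simulate_series(fx, n_fights = 150, seed = 9)
  expect_series_equal(a, b)
  c2 <- simulate_series(fx, n_fights = 150, seed = 10)
  expect_false(identical(a$participants, c2$participants))
})

test_that("forest-fire regimes trigger the cap warning", {
  fp <- strategy_matrix(
    tibble::tibble(source = c("a", "c"), target = c("c|d", "a|b"), value = 1),
    n = 1, k = 2, combinator = "OR", roster = c("a", "b", "c", "d")
  )
  expect_warning(
    simulate_series(fp, n_fights = 50, max_fights = 10, seed = 1),
    class = "igt_forest_fire_warning"
  )
})

test_that("an equal-entry (2,1) model nests the pairwise model it is built from", {
  # (1,1)+OR with per-individual join values u; the (2,1)+OR matrix whose
  # pair entry combines them as 1-(1-u_a)(1-u_b) generates the same
  # fight-size distribution while cascades stay in the small-fight regime
  roster <- sprintf("m%02d", 1:8)
  u <- withr::with_seed(31, stats::runif(8 * 8, 0.005, 0.03))
  M11 <- matrix(u, 8, 8, dimnames = list(roster, roster))
  S11 <- igt:::new_strategy_matrix(M11, 1L, 1L, "OR", roster)
  cmb <- utils::combn(8, 2)
  M21 <- 1 - (1 - M11[cmb[1, ], , drop = FALSE]) * (1 - M11[cmb[2, ], , drop = FALSE])
  rownames(M21) <- paste(roster[cmb[1, ]], roster[cmb[2, ]], sep = "|")
  S21 <- igt:::new_strategy_matrix(M21, 2L, 1L, "OR", roster)

  sizes <- function(S, seed) {
    fight_sizes(simulate_series(S, n_fights = 12000, seed = seed, max_fights = 40))
  }
  ks <- suppressWarnings(stats::ks.test(sizes(S11, 51), sizes(S21, 52)))
  expect_gt(ks$p.value, 0.01)
})
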