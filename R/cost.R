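# Population cost of conflict by fight-size class.
#
# Cost is measured with respect to ALL roster individuals, not only those
# who fight: the frequency with which an individual receives contact (or
# redirected) aggression in fights of a size class, zeros included. This
# captures the group-level consequence of strategies that produce large
# fights -- ten individuals fighting cost a group of ten more than a group
# of one hundred.

cost_classes <- function(kind) {
  if (kind == "contact") c("2", "3", "4", ">4") else c("3", "4", ">4")
}

size_class_of <- function(sizes, kind) {
  cls <- ifelse(sizes > 4L, ">4", as.character(sizes))
  if (kind == "redirected") cls[sizes < 3L] <- NA_character_
  factor(cls, levels = cost_classes(kind))
}

#' Per-individual aggression frequencies by fight-size class
#'
#' For every roster individual and every fight-size class (2, 3, 4, >4 for
#' contact aggression; 3, 4, >4 for redirected, which cannot occur in a
#' fight of size two), computes the fraction of the class's fights in which
#' the individual received that aggression type. Frequencies are indicator
#' means (received at least once in the fight); set `mode = "count"` to
#' average receipt counts instead when annotations are richer.
#'
#' @param series A [conflict_series] carrying `contact` / `redirected`
#'   annotations.
#' @param kind `"contact"` or `"redirected"`.
#' @return A `cost_table`: a tibble with one row per (id, class) --
#'   `id`, `class`, `received`, `n_fights`, `frequency` -- with the class
#'   fight counts in the `n_fights` attribute. Classes with zero fights have
#'   `frequency = NA` and are reported in the `empty_classes` attribute.
#' @export
cost_table <- function(series, kind = c("contact", "redirected")) {
  kind <- match.arg(kind)
  sizes <- fight_sizes(series)
  cls <- size_class_of(sizes, kind)
  ids <- roster_ids(series)
  ann <- series[[if (kind == "contact") "contact" else "redirected"]]
  levels_k <- cost_classes(kind)

  n_class <- table(cls)
  rows <- purrr::map_dfr(levels_k, function(cl) {
    in_class <- which(!is.na(cls) & cls == cl)
    rec <- table(factor(unlist(ann[in_class]), levels = ids))
    tibble::tibble(
      id = ids,
      class = cl,
      received = as.integer(rec),
      n_fights = length(in_class),
      frequency = if (length(in_class) == 0L) NA_real_ else as.integer(rec) / length(in_class)
    )
  })
  rows$class <- factor(rows$class, levels = levels_k)
  structure(rows,
    kind = kind,
    n_fights_by_class = stats::setNames(
      as.integer(n_class[levels_k]), levels_k
    ),
    empty_classes = levels_k[tabulate(cls, nbins = length(levels_k)) == 0L],
    class = c("cost_table", class(tibble::tibble()))
  )
}

#' Population summary of a cost table
#'
#' @param x A `cost_table`.
#' @param ... Unused.
#' @return A tibble with one row per class: unweighted population mean
#'   frequency over the whole roster, quartiles, and fight counts.
#' @export
glance.cost_table <- function(x, ...) {
  q_or_na <- function(x, p) {
    if (all(is.na(x))) NA_real_ else stats::quantile(x, p, names = FALSE)
  }
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$class),
    population_mean = mean(.data$frequency),
    median = q_or_na(.data$frequency, 0.5),
    q25 = q_or_na(.data$frequency, 0.25),
    q75 = q_or_na(.data$frequency, 0.75),
    n_fights = .data$n_fights[1],
    .groups = "drop"
  )
}

#' @export
tidy.cost_table <- function(x, ...) tibble::as_tibble(x)

#' Paired signed-rank comparison of adjacent size classes
#'
#' Tests whether individuals receive aggression more frequently in the
#' larger of two adjacent fight-size classes, pairing frequencies over
#' roster individuals: a one-tailed Wilcoxon signed-rank test of
#' H1: frequency(upper) > frequency(lower). Zero differences are dropped
#' (the standard signed-rank convention); mid-ranks handle ties. The null
#' distribution is permutation-exact (conditional on the observed ranks) for
#' up to 25 informative pairs, and a normal approximation with tie and
#' continuity corrections above that. Each adjacent pair is tested
#' independently; no multiplicity correction is applied by default.
#'
#' @param table A `cost_table`.
#' @param lower,upper Class labels, e.g. `"3"`, `"4"`, `">4"`.
#' @param exact_max Largest number of informative pairs for which the exact
#'   null is enumerated.
#' @return A one-row tibble: `lower`, `upper`, `n_pairs` (informative),
#'   `n_zero_dropped`, `statistic` (V, rank sum of positive differences),
#'   `p_value`, `method`. All-zero differences give `p_value = NA` with
#'   method `"undefined"`.
#' @export
adjacent_class_test <- function(table, lower, upper, exact_max = 25L) {
  tab <- tibble::as_tibble(table)
  lv <- levels(tab$class)
  if (!lower %in% lv || !upper %in% lv) {
    abort_igt("`lower` and `upper` must be size-class labels of the table.")
  }
  lo <- tab[tab$class == lower, ]
  hi <- tab[tab$class == upper, ]
  lo <- lo[match(hi$id, lo$id), ]
  if (anyNA(lo$frequency) || anyNA(hi$frequency)) {
    abort_igt("Both classes must contain fights to be compared.")
  }
  res <- signed_rank_test(hi$frequency, lo$frequency, exact_max = exact_max)
  tibble::tibble(
    lower = lower, upper = upper,
    n_pairs = res$n, n_zero_dropped = res$n_zero,
    statistic = res$statistic, p_value = res$p_value, method = res$method
  )
}

# One-tailed (greater) paired Wilcoxon signed-rank test. Exact null by
# dynamic programming over the 2^n equiprobable sign assignments of the
# observed mid-ranks (doubled to integers so tied half-ranks stay exact);
# normal approximation with tie and continuity corrections for larger n.
signed_rank_test <- function(x, y, exact_max = 25L) {
  d <- x - y
  d <- d[d != 0]
  n_zero <- length(x) - length(d)
  n <- length(d)
  if (n == 0L) {
    return(list(
      statistic = NA_real_, p_value = NA_real_, n = 0L,
      n_zero = n_zero, method = "undefined"
    ))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # distribution of 2*V over sign assignments: polynomial product of
    # (1 + z^(2r_i)) / 2^n
    r2 <- as.integer(round(2 * r))
    dist <- numeric(sum(r2) + 1L)
    dist[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), dist[seq_len(length(dist) - ri)])
      dist <- (dist + shifted) / 2
    }
    v2 <- as.integer(round(2 * v))
    p <- sum(dist[(v2 + 1L):length(dist)])
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    p <- stats::pnorm((v - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
    method <- "normal"
  }
  list(statistic = v, p_value = p, n = n, n_zero = n_zero, method = method)
}
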