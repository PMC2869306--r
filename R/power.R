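# Power scores from peacefully-emitted subordination signals.

#' Entropy-corrected power scores
#'
#' A power score summarises how much consensus there is in the group about an
#' individual's capacity to use force: the total frequency of peaceful
#' subordination signals an individual receives over the study duration,
#' corrected for how uniformly those signals are spread over potential
#' senders. For receiver \eqn{i} with total signal count \eqn{F_i} and sender
#' proportions \eqn{q_j},
#' \deqn{score_i = F_i \cdot H_i / \log(S - 1), \quad
#'       H_i = -\sum_j q_j \log q_j,}
#' where \eqn{S} is the roster size, so \eqn{S-1} is the number of potential
#' senders. Signals from a single sender carry no consensus (entropy 0, score
#' 0); uniform signalling leaves the raw frequency unchanged when every
#' potential sender participates. The exact published correction lives in an
#' external reference; this entropy-normalised frequency is a documented
#' stand-in, and only the induced ranking is used downstream (e.g. octile
#' grouping for [chi_square_by_group()]), so any monotone variant serves.
#'
#' @param signals Data frame with columns `sender`, `receiver`, `count`
#'   (nonnegative; `sender != receiver`).
#' @param roster Character vector of all roster ids (receivers with no
#'   signals score 0). Defaults to the ids present in `signals`.
#' @return A tibble with columns `id`, `n_signals`, `entropy` (nats),
#'   `power_score`, sorted by decreasing score.
#' @export
#' @examples
#' sig <- tibble::tibble(
#'   sender = c("a", "b", "c"), receiver = "d", count = c(4, 4, 4)
#' )
#' power_scores(sig, roster = c("a", "b", "c", "d"))
power_scores <- function(signals, roster = NULL) {
  signals <- tibble::as_tibble(signals)
  if (is.null(roster)) {
    roster <- sort(unique(c(signals$sender, signals$receiver)))
  }
  roster <- as.character(roster)
  if (length(roster) == 0L) abort_igt("Empty roster.")
  if (any(signals$count < 0)) abort_igt("Signal counts must be nonnegative.")
  if (any(signals$sender == signals$receiver)) {
    abort_igt("Self-directed signals are not allowed.")
  }
  s_max <- log(max(length(roster) - 1L, 1L))
  per <- lapply(roster, function(id) {
    rows <- signals[signals$receiver == id & signals$count > 0, ]
    f <- sum(rows$count)
    if (f == 0) {
      return(tibble::tibble(id = id, n_signals = 0, entropy = 0, power_score = 0))
    }
    cnt <- tapply(rows$count, rows$sender, sum)
    q <- cnt / f
    h <- -sum(q * log(q))
    score <- if (s_max > 0) f * h / s_max else 0
    tibble::tibble(id = id, n_signals = f, entropy = h, power_score = score)
  })
  out <- dplyr::bind_rows(per)
  dplyr::arrange(out, dplyr::desc(.data$power_score), .data$id)
}

#' Group individuals into power octiles
#'
#' Sorts individuals by decreasing power score and cuts them into consecutive
#' groups of `group_size` (units of eight for a 48-individual roster), the
#' grouping used to ask whether high- and low-power individuals play
#' different strategies than the bulk of the group.
#'
#' @param scores Output of [power_scores()], or any tibble with `id` and
#'   `power_score`.
#' @param group_size Individuals per group (default 8).
#' @return Named integer vector: group index (1 = highest power) per id.
#' @export
power_groups <- function(scores, group_size = 8L) {
  assert_count(group_size, "group_size", min = 1L)
  ord <- order(-scores$power_score, scores$id)
  grp <- ceiling(seq_along(ord) / group_size)
  stats::setNames(grp, scores$id[ord])
}
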