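# Summary statistics for model-data comparison.

#' Long fraction of fight sizes
#'
#' The cascade-severity observable: the number of fights of size `s` divided
#' by the total number of fights larger than two,
#' \deqn{F(s) = N(s) / \sum_{s' > 2} N(s'), \qquad s \ge 3.}
#' Fights of size two are excluded to reduce the influence of seed-pair
#' composition.
#'
#' @param series A [conflict_series].
#' @param drop_capped Exclude fights belonging to cascades that hit the
#'   simulation cap (only applies to simulated series carrying a
#'   `cascade_capped` column).
#' @return A tibble with `size`, `count`, `fraction` for the observed sizes
#'   `>= 3`; zero rows (with an `empty` attribute set) when no fight exceeds
#'   size two. Fractions sum to one otherwise.
#' @export
long_fraction <- function(series, drop_capped = TRUE) {
  sizes <- fight_sizes(series)
  if (drop_capped && "cascade_capped" %in% names(series)) {
    sizes <- sizes[!series$cascade_capped]
  }
  sizes <- sizes[sizes > 2L]
  if (length(sizes) == 0L) {
    out <- tibble::tibble(size = integer(0), count = integer(0), fraction = numeric(0))
    attr(out, "empty") <- TRUE
    return(out)
  }
  tab <- table(sizes)
  tibble::tibble(
    size = as.integer(names(tab)),
    count = as.integer(tab),
    fraction = as.integer(tab) / length(sizes)
  )
}

#' Observable battery of a conflict series
#'
#' Computes the summary statistics used to compare observed and simulated
#' series beyond the fight-size distribution: per-individual and connected
#' pair appearance probabilities, mean fight size conditional on appearance,
#' and the lag-1 individual-to-individual `delta_p` map. "Connected pair"
#' means co-membership in the same fight, the only within-fight information
#' the estimators use.
#'
#' @param series A [conflict_series].
#' @param deltap_shuffles Monte Carlo budget for the `delta_p` map (0 skips
#'   it, e.g. for ensembles where only scalar observables are needed).
#' @param seed Seed for the `delta_p` null ensemble.
#' @return An `observable_set`: a list with `n_fights`, `size_counts`,
#'   `long_fraction`, `individual` (tibble `id`, `p_appear`, `cond_size`),
#'   `pair` (tibble `pair`, `p_appear`, `cond_size`), and `deltap`
#'   (tibble from [fight_correlations()], or `NULL`).
#' @export
observable_set <- function(series, deltap_shuffles = 200L, seed = 1L) {
  sizes <- fight_sizes(series)
  ids <- roster_ids(series)
  mem <- membership_matrix(series, 1L)
  n_f <- nrow(series)

  p_ind <- unname(colMeans(mem$M))
  cond_ind <- as.vector(crossprod(mem$M, sizes)) / unname(colSums(mem$M))
  cond_ind[is.nan(cond_ind)] <- NA_real_

  uni2 <- tuple_universe(ids, 2L)
  M2 <- mem$M[, uni2$members[, 1L], drop = FALSE] * mem$M[, uni2$members[, 2L], drop = FALSE]
  p_pair <- unname(colMeans(M2))
  cond_pair <- as.vector(crossprod(M2, sizes)) / colSums(M2)
  cond_pair[is.nan(cond_pair)] <- NA_real_

  deltap <- if (deltap_shuffles > 0L) {
    fight_correlations(series,
      n = 1L, k = 1L, lag = 1L,
      n_shuffles = deltap_shuffles, seed = seed
    )
  }
  tab <- table(factor(sizes, levels = 2:max(c(sizes, 2L))))
  structure(
    list(
      n_fights = n_f,
      size_counts = tibble::tibble(
        size = as.integer(names(tab)), count = as.integer(tab)
      ),
      long_fraction = long_fraction(series),
      individual = tibble::tibble(id = ids, p_appear = p_ind, cond_size = cond_ind),
      pair = tibble::tibble(pair = uni2$keys, p_appear = p_pair, cond_size = cond_pair),
      deltap = deltap
    ),
    class = "observable_set"
  )
}

#' @export
print.observable_set <- function(x, ...) {
  cat(sprintf(
    "<observable_set> %d fights, %d individuals%s\n",
    x$n_fights, nrow(x$individual),
    if (is.null(x$deltap)) "" else ", with delta_p map"
  ))
  invisible(x)
}

observable_class_values <- function(obs, class) {
  switch(class,
    p_ind = stats::setNames(obs$individual$p_appear, obs$individual$id),
    p_pair = stats::setNames(obs$pair$p_appear, obs$pair$pair),
    cond_size_ind = stats::setNames(obs$individual$cond_size, obs$individual$id),
    cond_size_pair = stats::setNames(obs$pair$cond_size, obs$pair$pair),
    deltap = {
      if (is.null(obs$deltap)) {
        stats::setNames(numeric(0), character(0))
      } else {
        d <- obs$deltap
        v <- ifelse(d$undefined, NA_real_, d$delta_p)
        stats::setNames(v, paste(d$source, d$target, sep = ">"))
      }
    },
    abort_igt(sprintf("Unknown observable class: %s", class))
  )
}

#' Pearson battery between two observable sets
#'
#' For each observable class -- individual appearance probability P(A),
#' connected-pair appearance P(AB), conditional fight sizes given individual
#' or pair appearance, and the lag-1 `delta_p` map -- computes the Pearson
#' correlation between matched keys of an observed and a simulated series.
#' Keys undefined on either side (never-appearing individuals or pairs,
#' undefined correlation cells) are excluded and counted.
#'
#' @param obs,sim `observable_set`s over a shared roster.
#' @return A tibble with `class`, `r` (NA when fewer than 3 matched keys),
#'   `n_keys`, `n_excluded`. Symmetric in its arguments.
#' @export
pearson_battery <- function(obs, sim) {
  if (!setequal(obs$individual$id, sim$individual$id)) {
    abort_igt("Observable sets must share a roster.")
  }
  classes <- c("p_ind", "p_pair", "cond_size_ind", "cond_size_pair", "deltap")
  purrr::map_dfr(classes, function(cl) {
    a <- observable_class_values(obs, cl)
    b <- observable_class_values(sim, cl)
    keys <- intersect(names(a), names(b))
    x <- a[keys]
    y <- b[keys]
    ok <- !is.na(x) & !is.na(y)
    n_ok <- sum(ok)
    r <- if (n_ok < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      NA_real_
    } else {
      stats::cor(x[ok], y[ok])
    }
    tibble::tibble(
      class = cl, r = r, n_keys = n_ok,
      n_excluded = length(union(names(a), names(b))) - n_ok
    )
  })
}

#' Goodness of fit by individual group
#'
#' Scores how well a model ensemble reproduces each individual's observables,
#' aggregated over groups (e.g. power-score octiles): for every individual,
#' the per-individual observables -- P(A), mean fight size given appearance,
#' and the `delta_p` cells involving the individual as source or target --
#' are compared to the ensemble's Monte Carlo mean and variance, and
#' \eqn{\chi^2 = \sum (obs - mean)^2 / var} is summed over each group.
#' A variance floor `max(var, eps*|mean| + eps^2)` guards against
#' division blow-ups; zero-variance observables below the floor are counted.
#'
#' @param obs An `observable_set` of the observed series (with `delta_p` map).
#' @param sim_ensemble A list of `observable_set`s from replicate simulations.
#' @param grouping Named vector or tibble (`id`, `group`) mapping ids to
#'   groups (see [power_groups()]).
#' @param eps Variance-floor scale.
#' @return A tibble with `group`, `chi_square`, `n_obs` (observables
#'   entering the sum), `n_individuals`.
#' @export
chi_square_by_group <- function(obs, sim_ensemble, grouping, eps = 1e-3) {
  if (is.data.frame(grouping)) {
    grouping <- stats::setNames(grouping$group, grouping$id)
  }
  classes <- c("p_ind", "cond_size_ind", "deltap")
  key_of <- function(o) {
    unlist(lapply(classes, function(cl) {
      v <- observable_class_values(o, cl)
      stats::setNames(v, paste(cl, names(v), sep = ":"))
    }))
  }
  obs_v <- key_of(obs)
  sims <- vapply(sim_ensemble, function(o) key_of(o)[names(obs_v)], numeric(length(obs_v)))
  mu <- rowMeans(sims, na.rm = TRUE)
  vr <- apply(sims, 1L, stats::var, na.rm = TRUE)
  floor_v <- pmax(vr, eps * abs(mu) + eps^2, na.rm = TRUE)
  ok <- !is.na(obs_v) & !is.na(mu)
  contrib <- (obs_v - mu)^2 / floor_v
  usable <- names(obs_v)[ok]

  # A delta_p cell involves both its endpoints, so it contributes to the
  # group of its source and of its target (a row plus a column of the map
  # per individual).
  ids <- names(grouping)
  rows <- purrr::map_dfr(ids, function(id) {
    keys <- c(paste0("p_ind:", id), paste0("cond_size_ind:", id))
    if (!is.null(obs$deltap)) {
      d <- obs$deltap
      inv <- d$source == id | d$target == id
      keys <- c(keys, paste0("deltap:", paste(d$source[inv], d$target[inv], sep = ">")))
    }
    keys <- intersect(keys, usable)
    tibble::tibble(
      id = id, group = unname(grouping[id]),
      chi = sum(contrib[keys]), n_obs = length(keys)
    )
  })
  res <- dplyr::summarise(
    dplyr::group_by(rows, .data$group),
    chi_square = sum(.data$chi),
    n_obs = sum(.data$n_obs),
    n_individuals = dplyr::n(),
    .groups = "drop"
  )
  dplyr::arrange(res, .data$group)
}

#' Compare models by AIC
#'
#' `AIC = 2 * param_count - 2 * log_lik`; models are ranked by AIC and
#' reported with the difference from the best. The effective parameter count
#' of a strategy model is genuinely ambiguous (nominal cell counts overstate
#' how many parameters the data constrain), so it is supplied by the caller
#' rather than derived.
#'
#' @param models Data frame with columns `model`, `log_lik`, `param_count`.
#' @return The input with `aic` and `delta_aic`, sorted best-first.
#' @export
aic_compare <- function(models) {
  models <- tibble::as_tibble(models)
  if (nrow(models) == 0L) abort_igt("No models to compare.")
  if (any(models$param_count < 0)) abort_igt("`param_count` must be >= 0.")
  models$aic <- 2 * models$param_count - 2 * models$log_lik
  models <- dplyr::arrange(models, .data$aic)
  models$delta_aic <- models$aic - models$aic[1]
  models
}

#' Multinomial log-likelihood of a fight-size distribution
#'
#' Log-likelihood of the observed fight-size counts under the size
#' frequencies of a simulated series, with additive smoothing `eps` on every
#' cell so unobserved simulated sizes carry a finite penalty. This is the
#' likelihood fed to [aic_compare()].
#'
#' @param obs_series,sim_series [conflict_series] objects.
#' @param eps Additive smoothing pseudo-count per size cell.
#' @return A single log-likelihood value.
#' @export
size_log_likelihood <- function(obs_series, sim_series, eps = 0.5) {
  obs_sizes <- fight_sizes(obs_series)
  sim_sizes <- fight_sizes(sim_series)
  if ("cascade_capped" %in% names(sim_series)) {
    sim_sizes <- sim_sizes[!sim_series$cascade_capped]
  }
  cells <- 2:max(c(obs_sizes, sim_sizes))
  obs_n <- tabulate(factor(obs_sizes, levels = cells), nbins = length(cells))
  sim_n <- tabulate(factor(sim_sizes, levels = cells), nbins = length(cells))
  freq <- (sim_n + eps) / (sum(sim_n) + eps * length(cells))
  sum(obs_n * log(freq))
}
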