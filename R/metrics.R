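#' Market shares from colour counts
#'
#' @param counts Per-colour counts (named or in `urn_colors()` order).
#' @param total Number of individuals; must equal `sum(counts)` unless some
#'   individuals are still undecided, in which case `total` is the number of
#'   deciders to normalise by.
#' @return A tibble with columns `color`, `count`, `share`.
#' @export
market_share <- function(counts, total) {
  total <- check_count(total, "total", 1L)
  if (sum(counts) > total)
    abort("Counts exceed `total`.", class = "hyperurn_invalid_config")
  cols <- names(counts) %||% URN_COLORS[seq_along(counts)]
  tibble(color = cols, count = as.integer(counts),
         share = as.numeric(counts) / total)
}

#' Unpredictability of an ensemble: mean pairwise absolute difference
#'
#' For one colour's final shares across `W` independent runs,
#' `u = sum_{i<j} |M_i - M_j| / choose(W, 2)`: 0 when every run ends
#' identically (a fully predictable market), approaching 1 when runs split
#' between the extremes. Computed via the sorted-order identity
#' `sum_i (2i - W - 1) * M_(i)` in `O(W log W)`; `unpredictability_naive()`
#' is the literal `O(W^2)` double loop kept as an independent cross-check.
#'
#' @param shares Numeric vector of one colour's per-run shares (`W >= 2`).
#' @return A single value in `[0, 1]`.
#' @export
unpredictability <- function(shares) {
  W <- length(shares)
  if (W < 2L)
    abort("Unpredictability needs at least two runs.",
          class = "hyperurn_invalid_config")
  stopifnot(all(shares >= 0 & shares <= 1))
  s <- sort(shares)
  sum((2 * seq_len(W) - W - 1) * s) / choose(W, 2)
}

#' @rdname unpredictability
#' @export
unpredictability_naive <- function(shares) {
  W <- length(shares)
  if (W < 2L)
    abort("Unpredictability needs at least two runs.",
          class = "hyperurn_invalid_config")
  acc <- 0
  for (i in seq_len(W - 1L))
    acc <- acc + sum(abs(shares[i] - shares[(i + 1L):W]))
  acc / choose(W, 2)
}

#' Overall unpredictability across colours
#'
#' The arithmetic mean of the per-colour unpredictability values. With two
#' colours and complete decisions the per-run shares are complements, so
#' both colours have equal unpredictability and `U` equals either one.
#'
#' @param u_values Numeric vector of per-colour unpredictability values.
#' @return Their mean.
#' @export
overall_unpredictability <- function(u_values) {
  stopifnot(length(u_values) >= 1L)
  mean(u_values)
}

#' Inequality of one run's market shares
#'
#' The Gini-type index
#' `G = sum_{i<j} |M_i - M_j| / (2 * N * sum_k M_k)` over the `N` colours of
#' a single run, exactly as printed in the source formulation (note the
#' denominator uses `2 N sum(M)` where a textbook Gini would use
#' `2 N^2 mean(M)`; the printed form is implemented verbatim and, for two
#' colours summing to 1, equals `|M_1 - M_2| / 4` with maximum 0.25).
#' `standard = TRUE` switches to the textbook denominator.
#'
#' @param shares Numeric vector of one run's per-colour shares (`N >= 2`,
#'   not all zero).
#' @param standard Use the textbook Gini denominator instead?
#' @return A single non-negative value.
#' @export
inequality <- function(shares, standard = FALSE) {
  N <- length(shares)
  if (N < 2L)
    abort("Inequality needs at least two colours.",
          class = "hyperurn_invalid_config")
  if (sum(shares) <= 0)
    abort("Inequality is undefined when all shares are zero.",
          class = "hyperurn_invalid_config")
  pair_sum <- 0
  for (i in seq_len(N - 1L))
    pair_sum <- pair_sum + sum(abs(shares[i] - shares[(i + 1L):N]))
  denom <- if (standard) 2 * N^2 * mean(shares) else 2 * N * sum(shares)
  pair_sum / denom
}

#' Ensemble summary statistics
#'
#' Per-ensemble unpredictability and inequality. Inequality is computed per
#' run and averaged over the ensemble (one value per parameter cell);
#' `inequality_of_mean` applies the index to the ensemble-mean shares
#' instead and is reported alongside.
#'
#' @param ens An `urn_ensemble`.
#' @return A one-row tibble: `runs`, `mean_red`, `sd_red`, `se_red`,
#'   `u_red`, `u_blue`, `U`, `mean_G`, `inequality_of_mean`.
#' @export
ensemble_stats <- function(ens) {
  red <- ens$shares$red
  u_red <- unpredictability(red)
  u_blue <- unpredictability(ens$shares$blue)
  tibble(
    runs = ens$runs,
    mean_red = mean(red),
    sd_red = sd(red),
    se_red = sd(red) / sqrt(ens$runs),
    u_red = u_red, u_blue = u_blue,
    U = overall_unpredictability(c(u_red, u_blue)),
    mean_G = mean(vapply(seq_len(ens$runs), function(w)
      inequality(c(red[w], 1 - red[w])), numeric(1))),
    inequality_of_mean = inequality(c(mean(red), 1 - mean(red))))
}

#' Time-resolved unpredictability
#'
#' Unpredictability computed on the share-so-far at every decision index of
#' an ensemble recorded with `record_time = TRUE`. At index `t` (0 = the
#' post-seed state) the share of a run is its running RED count divided by
#' the number of individuals that have decided by then (`seeds + t`), so
#' early indices compare small decided populations.
#'
#' @param ens An `urn_ensemble` with recorded time shares.
#' @return A tibble of class `urn_time_u` with columns `index`, `decided`,
#'   `u_red`, `u_blue`, `U`.
#' @export
time_resolved_unpredictability <- function(ens) {
  if (is.null(ens$time_red))
    abort("Ensemble was not recorded with `record_time = TRUE`.",
          class = "hyperurn_invalid_config")
  n_idx <- ncol(ens$time_red)
  decided <- ens$n_seeds + seq_len(n_idx) - 1L
  out <- purrr::map_dfr(seq_len(n_idx), function(i) {
    red <- ens$time_red[, i] / decided[i]
    u_r <- unpredictability(red)
    u_b <- unpredictability(1 - red)
    tibble(index = i - 1L, decided = decided[i],
           u_red = u_r, u_blue = u_b,
           U = overall_unpredictability(c(u_r, u_b)))
  })
  class(out) <- c("urn_time_u", class(out))
  out
}

#' Export ensemble metrics as a long tidy table
#'
#' One row per statistic, in the long format
#' (`ps`, `pc`, `delta1`, `start`, `statistic`, `value`).
#'
#' @param ens An `urn_ensemble`.
#' @param path Optional CSV path; when given the table is also written.
#' @return The long tibble.
#' @export
metrics_long <- function(ens, path = NULL) {
  st <- ensemble_stats(ens)
  out <- tidyr::pivot_longer(
    dplyr::bind_cols(
      tibble(ps = ens$params$ps, pc = ens$params$pc,
             delta1 = ens$params$delta1, start = ens$start$condition),
      st),
    cols = -c("ps", "pc", "delta1", "start"),
    names_to = "statistic", values_to = "value")
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
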