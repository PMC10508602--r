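#' Tidy a trajectory: the per-decision table
#'
#' @param x An `urn_trajectory`.
#' @param ... Unused.
#' @return A tibble: `step`, `node`, `color`, `n_red`, `n_blue`,
#'   `share_red` (running share among deciders).
#' @export
tidy.urn_trajectory <- function(x, ...) {
  dplyr::mutate(x$decisions,
                share_red = .data$n_red / (.data$n_red + .data$n_blue))
}

#' @export
glance.urn_trajectory <- function(x, ...) {
  last <- x$decisions[nrow(x$decisions), ]
  tibble(node_count = x$hn$node_count,
         decided = nrow(x$decisions),
         n_red = last$n_red, n_blue = last$n_blue,
         share_red = last$n_red / x$hn$node_count,
         ps = x$params$ps, pc = x$params$pc,
         delta1 = x$params$delta1, qs = x$params$qs,
         start = x$start$condition)
}

#' Tidy an ensemble: per-run final shares
#'
#' @param x An `urn_ensemble`.
#' @param ... Unused.
#' @export
tidy.urn_ensemble <- function(x, ...) {
  tidyr::pivot_longer(x$shares, c("red", "blue"),
                      names_to = "color", values_to = "share") |>
    dplyr::mutate(color = toupper(.data$color))
}

#' One-row ensemble summary
#'
#' @param x An `urn_ensemble`.
#' @param ... Unused.
#' @return [ensemble_stats()] plus the cell's parameters.
#' @export
glance.urn_ensemble <- function(x, ...) {
  dplyr::bind_cols(
    tibble(ps = x$params$ps, pc = x$params$pc, delta1 = x$params$delta1,
           qs = x$params$qs, start = x$start$condition,
           node_count = x$node_count),
    ensemble_stats(x))
}

#' Tidy an analytic distribution
#'
#' @param x An `analytic_distribution`.
#' @param ... Unused.
#' @return A tibble: `j` (focal choices among entrants), `count`
#'   (including initial choosers), `share`, `probability`.
#' @export
tidy.analytic_distribution <- function(x, ...) {
  j <- 0:x$n
  tibble(j = j, count = j + x$B_i, share = (j + x$B_i) / (x$n + x$B),
         probability = x$probs)
}

#' @export
glance.analytic_distribution <- function(x, ...) {
  tibble(n = x$n, B = x$B, B_i = x$B_i,
         expected_share = distribution_mean_share(x),
         ps = x$params$ps, pc = x$params$pc,
         delta = x$params$delta, q = x$params$q)
}
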