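#' Mean-field parameters for the analytic recursions
#'
#' The closed-form results describe the dynamics inside one hyperedge (a
#' fully-mixed group with a single norm): `ps` is the social-influence
#' probability, `pc` the conformity probability, `delta` the probability the
#' group's norm is the focal colour, and `q` the intrinsic preference for
#' the focal colour (its market share in an influence-free world). The
#' composite *baseline probability* `alpha = delta * pc + (1 - pc) * q`
#' recurs throughout: it is the chance a non-imitating individual picks the
#' focal colour.
#'
#' @param ps,pc,delta,q Probabilities in `[0, 1]`.
#' @return A list of class `analytic_params`.
#' @export
analytic_params <- function(ps, pc, delta, q = 1) {
  structure(list(ps = check_prob(ps, "ps"), pc = check_prob(pc, "pc"),
                 delta = check_prob(delta, "delta"), q = check_prob(q, "q")),
            class = "analytic_params")
}

#' Baseline choice probability
#'
#' Probability that an individual deciding without any social information
#' (the first mover in an empty market) picks the focal colour:
#' `delta * pc + (1 - pc) * q`.
#'
#' @param params An [analytic_params()] object.
#' @return A single probability.
#' @export
baseline_probability <- function(params) {
  params$delta * params$pc + (1 - params$pc) * params$q
}

#' Next-entrant choice probability given the current market share
#'
#' `ps * share + (1 - ps) * baseline_probability(params)`: imitate the
#' current market with probability `ps`, otherwise fall back on norms and
#' preference.
#'
#' @param current_share Market share of the focal colour among prior
#'   deciders, in `[0, 1]`.
#' @inheritParams baseline_probability
#' @return A single probability.
#' @export
next_choice_probability <- function(current_share, params) {
  stopifnot(all(current_share >= 0 & current_share <= 1))
  params$ps * current_share + (1 - params$ps) * baseline_probability(params)
}

#' Exact distribution of the focal-colour count
#'
#' Forward recursion for the probability that, after `n` new individuals
#' enter a market that started with `B` deciders (`B_i` of them on the
#' focal colour), exactly `j + B_i` individuals hold the focal colour, for
#' `j = 0..n`. Entrant `t` faces `T = B + t - 1` prior deciders of whom `c`
#' chose the focal colour and picks it with probability
#' `ps * c / T + (1 - ps) * alpha` (just `alpha` when `T = 0`, the
#' empty-market base case). The full probability vector is propagated with
#' no truncation (`O(n^2)` work), so normalisation holds to machine
#' precision.
#'
#' @param n Number of new entrants (`>= 0`).
#' @param B Initial number of deciders (`>= 0`).
#' @param B_i Initial focal-colour deciders, `0 <= B_i <= B`.
#' @inheritParams baseline_probability
#' @return An `analytic_distribution` with field `probs` (`probs[j + 1]` is
#'   the probability of `j` focal choices among the entrants).
#' @export
#' @examples
#' d <- distribution_recursion(1, 0, 0, analytic_params(0.5, 0.5, 0.5, 1))
#' d$probs  # c(0.25, 0.75)
distribution_recursion <- function(n, B, B_i, params) {
  n <- check_count(n, "n"); B <- check_count(B, "B")
  B_i <- check_count(B_i, "B_i")
  if (B_i > B)
    abort("`B_i` cannot exceed `B`.", class = "hyperurn_invalid_config")
  alpha <- baseline_probability(params)
  ps <- params$ps
  probs <- c(1, numeric(n))
  for (t in seq_len(n)) {
    T_prior <- B + t - 1L
    j <- 0:(t - 1L)
    p_pick <- if (T_prior > 0L) ps * (B_i + j) / T_prior + (1 - ps) * alpha
              else rep.int(alpha, t)
    nxt <- numeric(n + 1L)
    nxt[1:t] <- probs[1:t] * (1 - p_pick)
    nxt[2:(t + 1L)] <- nxt[2:(t + 1L)] + probs[1:t] * p_pick
    probs <- nxt
  }
  structure(list(n = n, B = B, B_i = B_i, params = params, probs = probs),
            class = "analytic_distribution")
}

#' @export
print.analytic_distribution <- function(x, ...) {
  cat(sprintf(
    "<analytic_distribution> n=%d entrants, B=%d (B_i=%d); E[share]=%.4f\n",
    x$n, x$B, x$B_i, distribution_mean_share(x)))
  invisible(x)
}

#' Expected final market share implied by an analytic distribution
#'
#' @param dist An `analytic_distribution`.
#' @return `sum(probs * (j + B_i)) / (n + B)`.
#' @export
distribution_mean_share <- function(dist) {
  j <- 0:dist$n
  sum(dist$probs * (j + dist$B_i)) / (dist$n + dist$B)
}

#' Expected market-share recursion
#'
#' The expected focal-colour share after each entrant, by the exact
#' recursion
#' `E[M(T+1)] = (1 - (1 - ps) / (T + 1)) * E[M(T)] + (1 - ps) * alpha / (T + 1)`
#' starting from `M(B) = B_i / B`. Because the next-entrant choice
#' probability is linear in the share, this recursion is exact (not an
#' approximation) and agrees with the mean of [distribution_recursion()] to
#' machine precision.
#'
#' @inheritParams distribution_recursion
#' @param B Initial deciders; must be `>= 1` (an initial share is needed).
#' @return A tibble with columns `entrants` (0..n), `total` (`B + entrants`)
#'   and `expected_share`.
#' @export
expected_share_recursion <- function(n, B, B_i, params) {
  n <- check_count(n, "n")
  B <- check_count(B, "B")
  if (B < 1L)
    abort("`B` must be >= 1: the initial share B_i/B must be defined.",
          class = "hyperurn_invalid_config")
  B_i <- check_count(B_i, "B_i")
  if (B_i > B)
    abort("`B_i` cannot exceed `B`.", class = "hyperurn_invalid_config")
  alpha <- baseline_probability(params)
  ps <- params$ps
  share <- numeric(n + 1L)
  share[1] <- B_i / B
  for (t in seq_len(n)) {
    tot <- B + t
    share[t + 1L] <- (1 - (1 - ps) / tot) * share[t] + (1 - ps) * alpha / tot
  }
  tibble(entrants = 0:n, total = B + 0:n, expected_share = share)
}

#' Long-run market share
#'
#' For `ps < 1` the expected share converges to
#' `alpha = delta * pc + (1 - pc) * q`, equivalently
#' `(delta - q) * pc + q`: linear in `pc` with slope `delta - q`, so group
#' norms pull the market toward `delta` while preference anchors it at `q`.
#' At `ps = 1` the process is a pure Polya urn whose share is a martingale
#' converging to a run-specific random limit, so no unique value exists and
#' an error of class `hyperurn_no_unique_limit` is signalled.
#'
#' @inheritParams baseline_probability
#' @return A single share in `[0, 1]`.
#' @export
convergence_value <- function(params) {
  if (params$ps >= 1)
    abort(paste("At ps = 1 the share converges to an arbitrary",
                "(run-specific) value; no unique limit exists."),
          class = "hyperurn_no_unique_limit")
  (params$delta - params$q) * params$pc + params$q
}

#' Export an analytic distribution or expected-share table to CSV
#'
#' @param x An `analytic_distribution` or the tibble returned by
#'   [expected_share_recursion()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_analytic_csv <- function(x, path) {
  df <- if (inherits(x, "analytic_distribution")) tidy(x) else x
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
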