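# Independent oracles used across the suite.

# Brute-force final-count distribution: enumerate all 2^n choice sequences,
# weighting each step by the same rule the recursion claims to implement,
# but without any recursion — pure sequence enumeration.
enum_distribution <- function(n, B, B_i, params) {
  alpha <- params$delta * params$pc + (1 - params$pc) * params$q
  probs <- numeric(n + 1)
  if (n == 0) return(1)
  for (bits in 0:(2^n - 1)) {
    choice <- as.integer(intToBits(bits))[seq_len(n)]
    pr <- 1
    c_red <- B_i
    for (t in seq_len(n)) {
      T_prior <- B + t - 1
      p_red <- if (T_prior > 0)
        params$ps * c_red / T_prior + (1 - params$ps) * alpha else alpha
      if (choice[t] == 1L) {
        pr <- pr * p_red
        c_red <- c_red + 1
      } else {
        pr <- pr * (1 - p_red)
      }
    }
    j <- sum(choice)
    probs[j + 1] <- probs[j + 1] + pr
  }
  probs
}

# A tiny deterministic two-edge fixture: node 5 sits in both hyperedges.
two_edge_fixture <- function() {
  hypernetwork(9, list(c(1, 2, 3, 4, 5), c(5, 6, 7, 8, 9)),
               purposes = c("RED", "BLUE"))
}

# Chi-square goodness of fit of observed counts against analytic probs,
# pooling cells with tiny expectation to keep the test valid.
gof_pvalue <- function(observed_counts, probs, min_expected = 5) {
  W <- sum(observed_counts)
  expected <- probs * W
  ord <- order(expected)
  keep <- expected >= min_expected
  obs <- observed_counts[keep]
  exp <- expected[keep]
  if (any(!keep)) {
    obs <- c(obs, sum(observed_counts[!keep]))
    exp <- c(exp, sum(expected[!keep]))
  }
  stat <- sum((obs - exp)^2 / exp)
  stats::pchisq(stat, df = length(obs) - 1, lower.tail = FALSE)
}
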